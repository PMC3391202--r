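# ---------------------------------------------------------------------------
# Size adjustment (Mosimann shape variables) and PCA morphospace.
# ---------------------------------------------------------------------------

#' Geometric mean of positive measurements
#'
#' The kth root of the product of k values, computed in log space for
#' numerical stability. Same unit as the inputs.
#'
#' @param x numeric vector, all entries > 0.
#' @return scalar geometric mean.
#' @export
geometric_mean <- function(x) {
  if (!length(x) || any(!is.finite(x)) || any(x <= 0))
    stop("geometric mean requires finite, strictly positive values")
  exp(mean(log(x)))
}

#' @noRd
measurement_columns <- function(x) {
  if (is.matrix(x)) return(list(meas = x, extra = NULL))
  if (!is.data.frame(x)) stop("expected a numeric matrix or data frame")
  num <- vapply(x, is.numeric, TRUE)
  if (sum(num) < 2) stop("need at least 2 numeric measurement columns")
  list(meas = as.matrix(x[, num, drop = FALSE]),
       extra = x[, !num, drop = FALSE])
}

#' Mosimann shape variables: divide each specimen by its geometric mean
#'
#' Removes isometric size: each row of measurements is divided by that row's
#' geometric mean, giving dimensionless ratios whose per-row product is 1 and
#' which are invariant to multiplying a specimen's measurements by any
#' positive constant. Non-numeric columns of a data frame (specimen, species,
#' lineage labels) are passed through unchanged.
#'
#' @param x numeric matrix (specimens x measurements, all > 0) or a data
#'   frame mixing label columns with numeric measurement columns.
#' @return object of the same shape as `x` with measurements transformed.
#' @export
mosimann_transform <- function(x) {
  parts <- measurement_columns(x)
  meas <- parts$meas
  if (any(!is.finite(meas)) || any(meas <= 0))
    stop("all measurements must be finite and strictly positive")
  gm <- exp(rowMeans(log(meas)))
  shape <- meas / gm
  if (is.matrix(x)) return(shape)
  out <- x
  out[, colnames(meas)] <- shape
  out
}

#' Principal components morphospace
#'
#' PCA of the (typically Mosimann-transformed) measurement matrix via
#' singular value decomposition, with variables centred and, by default,
#' scaled to unit variance (a correlation-matrix PCA). Axes are ordered by
#' decreasing eigenvalue with a deterministic sign convention: the loading
#' largest in absolute value on each axis is made positive.
#'
#' @param x numeric matrix or data frame (non-numeric columns dropped, used
#'   as row labels where a `specimen` column exists).
#' @param standardize scale variables to unit variance (default `TRUE`).
#' @return object of class `ordination`: `scores` (n x p), `loadings`
#'   (k x p), `eigenvalues`, `variance_fraction`, `cumulative_variance`,
#'   `center`, `scale`.
#' @export
pca_morphospace <- function(x, standardize = TRUE) {
  parts <- measurement_columns(x)
  meas <- parts$meas
  if (standardize) {
    sds <- apply(meas, 2, sd)
    if (any(sds < .Machine$double.eps))
      stop("constant column(s) cannot be scaled to unit variance: ",
           paste(colnames(meas)[sds < .Machine$double.eps], collapse = ", "))
  }
  pc <- stats::prcomp(meas, center = TRUE, scale. = standardize)
  # deterministic sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  if (!is.null(parts$extra) && "specimen" %in% names(parts$extra))
    rownames(pc$x) <- as.character(parts$extra$specimen)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 cumulative_variance = cumsum(ev) / sum(ev),
                 center = pc$center, scale = pc$scale),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("Ordination:", nrow(x$scores), "specimens x", ncol(x$scores), "axes\n")
  k <- min(4, length(x$variance_fraction))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Smallest leading set of axes reaching a cumulative variance target
#'
#' @param ord an `ordination` (or `pco_axes`) object, or a numeric vector of
#'   variance fractions.
#' @param target cumulative variance fraction to reach (default 0.90).
#' @return integer: number of leading axes.
#' @export
axes_for_cumulative_variance <- function(ord, target = 0.90) {
  fr <- if (is.numeric(ord)) ord else ord$variance_fraction
  if (target <= 0 || target > 1) stop("'target' must be in (0, 1]")
  cum <- cumsum(fr) / sum(fr)
  which(cum >= target - 1e-12)[1]
}

#' Species centroids in morphospace
#'
#' Arithmetic mean of specimen scores per species: the tip data for all
#' downstream comparative analyses.
#'
#' @param scores numeric matrix of specimen scores, or an `ordination`.
#' @param species character vector of species labels, one per specimen.
#' @return matrix (species x axes) with species as row names.
#' @export
species_centroids <- function(scores, species) {
  if (inherits(scores, "ordination")) scores <- scores$scores
  species <- as.character(species)
  if (length(species) != nrow(scores))
    stop("one species label per specimen row is required")
  if (any(!nzchar(species)) || anyNA(species))
    stop("empty or missing species label(s)")
  sums <- rowsum(scores, species)
  counts <- as.vector(table(species)[rownames(sums)])
  sums / counts
}
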