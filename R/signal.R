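# ---------------------------------------------------------------------------
# Phylogenetic signal: PCO eigenvectors of patristic distances, independent
# contrasts, Blomberg's K with permutation significance, and (M)PVR.
# ---------------------------------------------------------------------------

#' Phylogenetic eigenvectors by principal coordinates analysis
#'
#' Pairwise patristic (path-sum) distances among tips are double-centred
#' (Gower) and eigendecomposed; variance fractions are taken over the
#' positive eigenvalues and the smallest leading set of axes reaching the
#' cumulative-variance cutoff is retained. Set `sqrt_dist = TRUE` to use the
#' square root of the patristic distance instead.
#'
#' @param tree a `phylo` with branch lengths or a `timetree` (positive
#'   durations required).
#' @param cutoff cumulative variance fraction for axis retention
#'   (default 0.95).
#' @param sqrt_dist use square-root patristic distances.
#' @return object of class `pco_axes`: `scores` (tips x positive axes),
#'   `eigenvalues`, `variance_fraction`, `cumulative_variance`, `retained`
#'   (axis count), `cutoff`.
#' @export
pco_eigenvectors <- function(tree, cutoff = 0.95, sqrt_dist = FALSE) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length <= 0))
    stop("tree must have strictly positive branch durations")
  if (cutoff <= 0 || cutoff > 1) stop("'cutoff' must be in (0, 1]")
  D <- cophenetic(phy)
  if (sqrt_dist) D <- sqrt(D)
  n <- nrow(D)
  cmd <- suppressWarnings(cmdscale(as.dist(D), k = n - 1, eig = TRUE))
  eig <- cmd$eig
  tol <- max(abs(eig)) * 1e-10
  npos <- sum(eig > tol)
  scores <- cmd$points[, seq_len(npos), drop = FALSE]
  colnames(scores) <- paste0("PCO", seq_len(npos))
  ev <- eig[seq_len(npos)]
  fr <- ev / sum(ev)
  cum <- cumsum(fr)
  retained <- which(cum >= cutoff - 1e-12)[1]
  structure(list(scores = scores, eigenvalues = ev, variance_fraction = fr,
                 cumulative_variance = cum, retained = retained,
                 cutoff = cutoff),
            class = "pco_axes")
}

#' @export
print.pco_axes <- function(x, ...) {
  cat("PCO of patristic distances:", nrow(x$scores), "taxa,",
      ncol(x$scores), "positive axes;", x$retained,
      sprintf("axes retained at %.0f%% cumulative variance\n", 100 * x$cutoff))
  invisible(x)
}

#' @noRd
retained_scores <- function(axes) {
  if (inherits(axes, "pco_axes"))
    axes$scores[, seq_len(axes$retained), drop = FALSE]
  else as.matrix(axes)
}

#' @noRd
align_tip_values <- function(phy, x) {
  x <- if (is.matrix(x) || is.data.frame(x)) as.matrix(x) else
    matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  if (!is.null(rownames(x))) {
    idx <- match(phy$tip.label, rownames(x))
    if (anyNA(idx))
      stop("missing trait value(s) for tip(s): ",
           paste(phy$tip.label[is.na(idx)], collapse = ", "))
    x <- x[idx, , drop = FALSE]
  } else if (nrow(x) != ape::Ntip(phy)) {
    stop("trait values must be named by tip or match the tip count")
  }
  if (anyNA(x)) stop("missing trait value(s)")
  x
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's recursion on a fully bifurcating tree: each internal node
#' contributes the contrast `(x_i - x_j)/sqrt(v_i + v_j)` between its
#' daughter working values, takes the precision-weighted mean as its own
#' working value, and has its parent branch lengthened by
#' `v_i v_j / (v_i + v_j)`.
#'
#' @param tree a bifurcating `phylo` with branch lengths, or `timetree`.
#' @param x tip values: named vector, or a matrix with one column per
#'   trait/permutation (rows named by tip, or in tip order).
#' @return list with `contrasts` (Nnode x p matrix of standardized
#'   contrasts), `node_values` (working values at internal nodes), and
#'   `contrast_variance` (the `v_i + v_j` of each contrast).
#' @export
pic_contrasts <- function(tree, x) {
  phy <- as_phylo(tree)
  n <- ape::Ntip(phy)
  if (phy$Nnode != n - 1)
    stop("tree has polytomies; independent contrasts require a binary tree")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  x <- align_tip_values(phy, x)
  p <- ncol(x)
  N <- n + phy$Nnode
  val <- matrix(NA_real_, N, p)
  val[seq_len(n), ] <- x
  blen <- rep(NA_real_, N)
  blen[phy$edge[, 2]] <- phy$edge.length
  contrasts <- matrix(NA_real_, phy$Nnode, p)
  cvar <- rep(NA_real_, phy$Nnode)
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  kids <- split(eo[, 2], eo[, 1])
  node_order <- unique(eo[, 1])  # parents in postorder
  for (nd in node_order) {
    ch <- kids[[as.character(nd)]]
    if (length(ch) != 2)
      stop("tree has polytomies; independent contrasts require a binary tree")
    c1 <- ch[1]; c2 <- ch[2]
    v1 <- blen[c1]; v2 <- blen[c2]
    vsum <- v1 + v2
    if (!is.finite(vsum) || vsum <= 0)
      stop("zero combined branch variance at node ", nd)
    row <- nd - n
    contrasts[row, ] <- (val[c1, ] - val[c2, ]) / sqrt(vsum)
    cvar[row] <- vsum
    val[nd, ] <- (val[c1, ] / v1 + val[c2, ] / v2) / (1 / v1 + 1 / v2)
    if (!is.na(blen[nd])) blen[nd] <- blen[nd] + v1 * v2 / vsum
  }
  list(contrasts = contrasts,
       node_values = val[(n + 1):N, , drop = FALSE],
       contrast_variance = cvar)
}

#' Blomberg's K with permutation significance
#'
#' K compares the observed ratio of the tip variance around the phylogenetic
#' (GLS) mean to the GLS mean squared error against the ratio expected under
#' Brownian motion on the same tree: with V the BM tip covariance matrix,
#' `MSE0 = (x - a)'(x - a)/(n-1)`, `MSE = (x - a)'V^-1(x - a)/(n-1)` where
#' `a` is the GLS mean, and `E[MSE0/MSE] = (tr V - n/sum(V^-1))/(n-1)`;
#' `K = (MSE0/MSE) / E[MSE0/MSE]`. K = 1 under pure Brownian motion; K < 1
#' means less resemblance among relatives than Brownian expectation.
#' Significance: tip values are permuted across the tree and the observed
#' mean squared independent contrast is compared with the permuted ones
#' (`p = (#{perm var <= obs var} + 1)/(perms + 1)`).
#'
#' @param tree `phylo` with branch lengths or `timetree`. K is defined for
#'   any tree; the contrast-based permutation test runs only on bifurcating
#'   trees (otherwise `p` is `NA`).
#' @param x named numeric vector of tip values (n >= 4).
#' @param perms permutation count (default 999).
#' @param seed optional RNG seed.
#' @return object of class `k_result`: `K`, `observed_ratio`,
#'   `expected_ratio`, `p`, `perms`, `seed`.
#' @export
blomberg_k <- function(tree, x, perms = 999, seed = NULL) {
  phy <- as_phylo(tree)
  n <- ape::Ntip(phy)
  if (n < 4) stop("Blomberg's K needs at least 4 tips")
  x <- align_tip_values(phy, x)
  if (ncol(x) != 1) stop("'x' must be a single trait")
  if (!is.null(seed)) set.seed(seed)
  V <- ape::vcv(phy)
  Vinv <- solve(V)
  ones <- rep(1, n)
  denom <- sum(Vinv)
  ahat <- sum(Vinv %*% x) / denom
  r <- x[, 1] - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(crossprod(r, Vinv %*% r)) / (n - 1)
  expected <- (sum(diag(V)) - n / denom) / (n - 1)
  K <- (mse0 / mse) / expected
  if (phy$Nnode == n - 1 && perms >= 1) {
    obs_var <- mean(pic_contrasts(phy, x)$contrasts^2)
    perm_x <- vapply(seq_len(perms), function(b) x[sample.int(n), 1],
                     numeric(n))
    rownames(perm_x) <- phy$tip.label
    perm_var <- colMeans(pic_contrasts(phy, perm_x)$contrasts^2)
    p <- (sum(perm_var <= obs_var) + 1) / (perms + 1)
  } else {
    # the permutation test standardizes by independent contrasts and so
    # needs a binary tree; K itself is defined for any tree
    if (phy$Nnode != n - 1)
      message("tree has polytomies: K computed, permutation test skipped")
    obs_var <- NA_real_
    p <- NA_real_
  }
  structure(list(K = K, observed_ratio = mse0 / mse,
                 expected_ratio = expected, pic_variance = obs_var,
                 p = p, perms = perms, seed = seed),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4g (p = %.4g, %d permutations)\n",
              x$K, x$p, x$perms))
  invisible(x)
}

#' Phylogenetic eigenvector regression (PVR)
#'
#' Ordinary least squares of one response on the retained phylogenetic
#' eigenvectors plus an intercept; the R-squared is the fraction of trait
#' variance attributable to phylogeny.
#'
#' @param axes a `pco_axes` object (retained axes are used) or a numeric
#'   predictor matrix, rows aligned with `y` (by name where both are named).
#' @param y numeric response over taxa.
#' @return object of class `pvr_result`: `r2`, `F`, `df`, `p`,
#'   `coefficients`.
#' @export
pvr <- function(axes, y) {
  X <- retained_scores(axes)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    idx <- match(rownames(X), names(y))
    if (anyNA(idx)) stop("response is missing taxa present in the axes")
    y <- y[idx]
  }
  if (length(y) != nrow(X)) stop("taxa mismatch between axes and response")
  if (ncol(X) >= length(y)) stop("more predictors than residual degrees of freedom")
  if (var(y) < .Machine$double.eps) {
    return(structure(list(r2 = 0, F = NA_real_, df = c(ncol(X), length(y) - ncol(X) - 1),
                          p = NA_real_, coefficients = NULL),
                     class = "pvr_result"))
  }
  fit <- lm(y ~ X)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(r2 = sm$r.squared, F = unname(fs[1]),
                 df = unname(fs[2:3]),
                 p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
                 coefficients = stats::coef(fit)),
            class = "pvr_result")
}

#' @export
print.pvr_result <- function(x, ...) {
  cat(sprintf("PVR: R^2 = %.4f", x$r2))
  if (!is.na(x$F))
    cat(sprintf(", F(%g, %g) = %.4g, p = %.4g", x$df[1], x$df[2], x$F, x$p))
  cat("\n")
  invisible(x)
}

#' Multivariate phylogenetic eigenvector regression (MPVR)
#'
#' Each response column is regressed on the same retained eigenvectors; the
#' pooled variance-explained fraction is trace-based,
#' `1 - sum_j RSS_j / sum_j SST_j`. Overall significance comes from Wilks'
#' lambda with Rao's F approximation; the determinant-based lambda is
#' reported alongside the trace-based fraction.
#'
#' @param axes as in [pvr()].
#' @param Y numeric matrix of responses (taxa x q, q >= 2), rows aligned
#'   with the axes (by rowname where both are named).
#' @return object of class `mpvr_result`: `r2_total`, `r2_per_response`,
#'   `wilks`, `F`, `df`, `p`.
#' @export
mpvr <- function(axes, Y) {
  X <- retained_scores(axes)
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("MPVR needs at least 2 response columns; use pvr()")
  if (!is.null(rownames(Y)) && !is.null(rownames(X))) {
    idx <- match(rownames(X), rownames(Y))
    if (anyNA(idx)) stop("responses are missing taxa present in the axes")
    Y <- Y[idx, , drop = FALSE]
  }
  if (nrow(Y) != nrow(X)) stop("taxa mismatch between axes and responses")
  fit <- lm(Y ~ X)
  res <- stats::residuals(fit)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  rss <- colSums(res^2)
  sst <- colSums(Yc^2)
  r2_total <- 1 - sum(rss) / sum(sst)
  a <- anova(fit, test = "Wilks")
  row <- grep("^X$", rownames(a))
  structure(list(r2_total = r2_total,
                 r2_per_response = 1 - rss / sst,
                 wilks = a[row, "Wilks"], F = a[row, "approx F"],
                 df = unname(unlist(a[row, c("num Df", "den Df")])),
                 p = a[row, "Pr(>F)"]),
            class = "mpvr_result")
}

#' @export
print.mpvr_result <- function(x, ...) {
  cat(sprintf(
    "MPVR: total variance explained = %.1f%%; Wilks = %.4g, F(%g, %g) = %.4g, p = %.3g\n",
    100 * x$r2_total, x$wilks, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
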