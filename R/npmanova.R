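# ---------------------------------------------------------------------------
# Permutational MANOVA (NPMANOVA) on Euclidean distances, with pairwise
# tests under sequential Bonferroni (Holm) correction.
# ---------------------------------------------------------------------------

#' @noRd
ss_partition <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' One-way permutational MANOVA on Euclidean distances
#'
#' Distance-based pseudo-F: with squared pairwise distances d2 and a groups
#' of sizes n_g, `SS_total = sum_{i<j} d2_ij / n`, `SS_within = sum_g
#' sum_{i<j in g} d2_ij / n_g`, and `F = (SS_among/(a-1)) / (SS_within/(n-a))`.
#' Significance comes from random permutations of the group labels with the
#' `+1` convention: `p = (#{F_perm >= F_obs} + 1) / (perms + 1)`, so the
#' smallest attainable p is `1/(perms+1)`.
#'
#' Distances are computed on exactly the axes supplied; pass the score
#' columns you want tested (e.g. the leading PCs of a morphospace).
#'
#' @param points numeric matrix, observations x axes.
#' @param groups group labels (>= 2 groups, each with >= 2 members).
#' @param perms number of label permutations (default 9999).
#' @param seed optional RNG seed for reproducible permutations.
#' @return object of class `npmanova_result` with `F`, `p`, the sum-of-
#'   squares partition, `perms`, and `seed`.
#' @export
npmanova <- function(points, groups, perms = 9999, seed = NULL) {
  points <- as.matrix(points)
  groups <- droplevels(factor(groups))
  n <- nrow(points)
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  if (perms < 1) stop("'perms' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  d2 <- as.matrix(dist(points))^2
  ss <- ss_partition(d2, groups)
  f_stat <- function(ss) (ss["among"] / (a - 1)) / (ss["within"] / (n - a))
  f_obs <- f_stat(ss)
  exceed <- 0L
  for (b in seq_len(perms)) {
    gp <- groups[sample.int(n)]
    if (f_stat(ss_partition(d2, gp)) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(F = unname(f_obs), p = (exceed + 1) / (perms + 1),
                 ss_total = unname(ss["total"]),
                 ss_within = unname(ss["within"]),
                 ss_among = unname(ss["among"]),
                 df_among = a - 1, df_within = n - a,
                 perms = perms, seed = seed),
            class = "npmanova_result")
}

#' @export
print.npmanova_result <- function(x, ...) {
  cat(sprintf("NPMANOVA: F = %.4g, p = %.4g (%d permutations)\n",
              x$F, x$p, x$perms))
  invisible(x)
}

#' Pairwise NPMANOVA with sequential Bonferroni (Holm) correction
#'
#' Every pair of groups is tested with its own set of permutations; raw
#' p-values are adjusted by the Holm step-down procedure (sorted ascending,
#' `p_adj_i = max_{j<=i} (m-j+1) p_j`, capped at 1).
#'
#' @inheritParams npmanova
#' @return object of class `pairwise_npmanova`: matrices `F`, `p_raw`,
#'   `p_adj` (upper triangles filled symmetrically).
#' @export
pairwise_npmanova <- function(points, groups, perms = 9999, seed = NULL) {
  points <- as.matrix(points)
  groups <- droplevels(factor(groups))
  levs <- levels(groups)
  if (length(levs) < 2) stop("need at least 2 groups")
  pairs <- combn(levs, 2)
  m <- ncol(pairs)
  Fm <- pm <- matrix(NA_real_, length(levs), length(levs),
                     dimnames = list(levs, levs))
  raw <- numeric(m)
  for (i in seq_len(m)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    sel <- groups %in% c(g1, g2)
    res <- npmanova(points[sel, , drop = FALSE], groups[sel], perms = perms,
                    seed = if (is.null(seed)) NULL else seed + i)
    raw[i] <- res$p
    Fm[g1, g2] <- Fm[g2, g1] <- res$F
    pm[g1, g2] <- pm[g2, g1] <- res$p
  }
  adj <- p.adjust(raw, method = "holm")
  am <- matrix(NA_real_, length(levs), length(levs),
               dimnames = list(levs, levs))
  for (i in seq_len(m)) {
    am[pairs[1, i], pairs[2, i]] <- adj[i]
    am[pairs[2, i], pairs[1, i]] <- adj[i]
  }
  structure(list(F = Fm, p_raw = pm, p_adj = am, perms = perms, seed = seed),
            class = "pairwise_npmanova")
}

#' @export
print.pairwise_npmanova <- function(x, ...) {
  m <- sum(!is.na(x$p_adj[upper.tri(x$p_adj)]))
  cat("Pairwise NPMANOVA:", m, "pairs,", x$perms,
      "permutations each, Holm-adjusted\n")
  cat("  significant at 0.05:",
      sum(x$p_adj[upper.tri(x$p_adj)] < 0.05, na.rm = TRUE), "pair(s)\n")
  invisible(x)
}
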