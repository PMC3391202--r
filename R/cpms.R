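# ---------------------------------------------------------------------------
# Maximum-likelihood ancestral states under Brownian motion, and the
# phylomorphospace / chronophylomorphospace graph builders.
# ---------------------------------------------------------------------------

#' Maximum-likelihood ancestral state estimation under Brownian motion
#'
#' With tips fixed at their observed values, the internal states that
#' minimize `sum_edges (delta x)^2 / duration` are the Brownian-motion ML
#' estimates. They solve the linear system `L_II x_int = -L_IT x_tip`, where
#' L is the graph Laplacian of the tree weighted by 1/duration, partitioned
#' into internal (I) and tip (T) blocks. Traits are estimated independently
#' per column.
#'
#' The Brownian rate per trait is estimated from the GLS quadratic form
#' `(x - a1)' V^-1 (x - a1)` divided by `n - 1` (REML, the default; equals
#' the mean squared independent contrast on binary trees) or by `n` (ML).
#' Per-node estimation variances are `sigma2 * diag(L_II^-1)`; 95% intervals
#' use the normal multiplier 1.96.
#'
#' @param tree a `timetree` or `phylo` with strictly positive branch
#'   lengths.
#' @param x tip values: named vector or matrix (tips x traits).
#' @param sigma_method `"REML"` (default) or `"ML"`.
#' @param conf confidence level for the intervals (default 0.95).
#' @return object of class `ancestral_states`: `estimates` (all nodes x
#'   traits; tip rows equal the data), `variance`, `ci_lower`, `ci_upper`
#'   (zero-width at tips), `sigma2` (per trait), `sigma_method`.
#' @export
ancestral_ml <- function(tree, x, sigma_method = c("REML", "ML"),
                         conf = 0.95) {
  sigma_method <- match.arg(sigma_method)
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length <= 0))
    stop("zero or negative branch duration; resolve before estimating")
  n <- ape::Ntip(phy)
  N <- n + phy$Nnode
  x <- align_tip_values(phy, x)
  p <- ncol(x)

  w <- 1 / phy$edge.length
  L <- matrix(0, N, N)
  for (k in seq_len(nrow(phy$edge))) {
    i <- phy$edge[k, 1]; j <- phy$edge[k, 2]
    L[i, j] <- L[i, j] - w[k]
    L[j, i] <- L[j, i] - w[k]
    L[i, i] <- L[i, i] + w[k]
    L[j, j] <- L[j, j] + w[k]
  }
  tip_idx <- seq_len(n)
  int_idx <- (n + 1):N
  LII_inv <- solve(L[int_idx, int_idx])
  est_int <- LII_inv %*% (-L[int_idx, tip_idx, drop = FALSE] %*% x)

  V <- ape::vcv(phy)
  Vinv <- solve(V)
  denom <- sum(Vinv)
  sigma2 <- vapply(seq_len(p), function(j) {
    ahat <- sum(Vinv %*% x[, j]) / denom
    r <- x[, j] - ahat
    qf <- drop(crossprod(r, Vinv %*% r))
    qf / if (sigma_method == "REML") n - 1 else n
  }, 0)

  base_var <- diag(LII_inv)
  variance <- matrix(0, N, p)
  variance[int_idx, ] <- outer(base_var, sigma2)
  estimates <- rbind(x, est_int)
  zmult <- qnorm(1 - (1 - conf) / 2)
  half <- zmult * sqrt(variance)
  rn <- c(phy$tip.label, paste0("node", int_idx))
  dimnames(estimates) <- list(rn, colnames(x))
  dimnames(variance) <- dimnames(estimates)
  structure(list(estimates = estimates, variance = variance,
                 ci_lower = estimates - half, ci_upper = estimates + half,
                 sigma2 = sigma2, sigma_method = sigma_method, conf = conf,
                 n_tips = n),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("Brownian-motion ancestral estimates:",
      nrow(x$estimates) - x$n_tips, "internal nodes,",
      ncol(x$estimates), "trait(s);",
      sprintf("sigma^2 (%s) = %s\n", x$sigma_method,
              paste(format(x$sigma2, digits = 4), collapse = ", ")))
  invisible(x)
}

#' @noRd
cpms_graph_skeleton <- function(phy, lineage = NULL) {
  n <- ape::Ntip(phy)
  N <- n + phy$Nnode
  label <- c(phy$tip.label,
             if (!is.null(phy$node.label)) phy$node.label
             else rep("", phy$Nnode))
  nodes <- data.frame(id = seq_len(N), label = label,
                      type = rep(c("tip", "internal"), c(n, phy$Nnode)),
                      stringsAsFactors = FALSE)
  if (!is.null(lineage)) {
    nodes$lineage <- NA_character_
    nodes$lineage[seq_len(n)] <- as.character(lineage[phy$tip.label])
  }
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2])
  list(nodes = nodes, edges = edges)
}

#' Project a phylogeny into a two-dimensional morphospace
#'
#' Tips sit at their observed scores; internal nodes at their Brownian-motion
#' ML ancestral estimates; edges are the tree edges. No temporal axis.
#'
#' @param tree `phylo` or `timetree` with positive branch lengths.
#' @param scores species x 2 matrix of trait-space coordinates, rows named
#'   by tip label.
#' @param lineage optional named vector of lineage labels per tip.
#' @param ... passed to [ancestral_ml()].
#' @return object of class `cpms_graph` with `nodes` (id, label, type, x, y,
#'   age = NA) and `edges` (parent, child).
#' @export
build_phylomorphospace <- function(tree, scores, lineage = NULL, ...) {
  phy <- as_phylo(tree)
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("'scores' must have exactly 2 columns")
  anc <- ancestral_ml(tree, scores, ...)
  g <- cpms_graph_skeleton(phy, lineage)
  g$nodes$x <- unname(anc$estimates[, 1])
  g$nodes$y <- unname(anc$estimates[, 2])
  g$nodes$age <- NA_real_
  g$ancestral <- anc
  class(g) <- "cpms_graph"
  g
}

#' Build a chronophylomorphospace graph
#'
#' A phylomorphospace whose nodes also carry a temporal coordinate: each
#' node's age (Ma before present) from the time-scaled tree. Extant tips sit
#' at 0 Ma, fossil tips at their assigned (e.g. stratigraphic-midpoint) ages,
#' and every edge runs from an older parent to a younger child.
#'
#' @param tree a `timetree` (ages required).
#' @param scores species x 2 matrix of morphospace coordinates, rows named
#'   by tip label.
#' @param lineage optional named vector of lineage labels per tip.
#' @param ... passed to [ancestral_ml()].
#' @return a `cpms_graph`; dropping the `age` column reproduces
#'   [build_phylomorphospace()] exactly.
#' @export
build_cpms <- function(tree, scores, lineage = NULL, ...) {
  if (!is_timetree(tree))
    stop("'tree' must be a time-scaled 'timetree' (see time_scale())")
  g <- build_phylomorphospace(tree, scores, lineage, ...)
  g$nodes$age <- tree$ages
  g
}

#' One-dimensional chronophylomorphospace (trait versus time)
#'
#' Single-trait variant: node coordinates are (trait, age), with 95%
#' confidence bounds on the ancestral estimates carried per internal node.
#'
#' @param tree a `timetree`.
#' @param trait named numeric vector of one trait per tip.
#' @param lineage optional named vector of lineage labels per tip.
#' @param ... passed to [ancestral_ml()].
#' @return a `cpms_graph` whose nodes have `trait`, `age`, `ci_lower`,
#'   `ci_upper`.
#' @export
build_cpms_1d <- function(tree, trait, lineage = NULL, ...) {
  if (!is_timetree(tree))
    stop("'tree' must be a time-scaled 'timetree' (see time_scale())")
  phy <- tree$phy
  anc <- ancestral_ml(tree, trait, ...)
  g <- cpms_graph_skeleton(phy, lineage)
  g$nodes$trait <- unname(anc$estimates[, 1])
  g$nodes$age <- tree$ages
  g$nodes$ci_lower <- unname(anc$ci_lower[, 1])
  g$nodes$ci_upper <- unname(anc$ci_upper[, 1])
  g$ancestral <- anc
  class(g) <- "cpms_graph"
  g
}

#' @export
print.cpms_graph <- function(x, ...) {
  cat("CPMS graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (all(is.na(x$nodes$age))) "(no temporal axis)" else
        sprintf("(ages %.3g-%.3g Ma)", min(x$nodes$age), max(x$nodes$age)),
      "\n")
  invisible(x)
}

#' Export or import a CPMS graph
#'
#' `format = "json"` writes a single JSON file with `nodes`, `edges`, and
#' metadata; `"csv"` writes a `<path>_nodes.csv` / `<path>_edges.csv` pair;
#' `"plot"` renders a static figure (PNG or PDF by file extension).
#'
#' @param g a `cpms_graph`.
#' @param path output file (json/plot) or file stem (csv).
#' @param format `"json"`, `"csv"`, or `"plot"`.
#' @return the path(s) written, invisibly.
#' @export
export_graph <- function(g, path, format = c("json", "csv", "plot")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "cpms_graph"))
  if (format == "json") {
    payload <- list(nodes = g$nodes, edges = g$edges,
                    meta = list(n_tips = sum(g$nodes$type == "tip"),
                                coordinates = setdiff(names(g$nodes),
                                                      c("id", "label", "type",
                                                        "lineage"))))
    jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                         na = "null", auto_unbox = TRUE)
    return(invisible(path))
  }
  if (format == "csv") {
    paths <- paste0(path, c("_nodes.csv", "_edges.csv"))
    write.csv(g$nodes, paths[1], row.names = FALSE)
    write.csv(g$edges, paths[2], row.names = FALSE)
    return(invisible(paths))
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "pdf") grDevices::pdf(path, width = 7, height = 6)
  else grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  plot(g)
  invisible(path)
}

#' Import a CPMS graph written by [export_graph()]
#'
#' @param path JSON file path.
#' @return a `cpms_graph`.
#' @export
import_graph <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- list(nodes = as.data.frame(payload$nodes),
            edges = as.data.frame(payload$edges))
  class(g) <- "cpms_graph"
  g
}

#' Plot a CPMS graph
#'
#' Two-dimensional graphs are drawn in trait space with edges as segments;
#' when ages are present they are shown by point shading (older = darker)
#' and an oblique pseudo-3D offset. One-dimensional graphs are drawn as
#' trait versus age with confidence bars on internal nodes; the time axis
#' runs from past (left) to present.
#'
#' @param x a `cpms_graph`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpms_graph <- function(x, ...) {
  nd <- x$nodes
  ed <- x$edges
  if ("trait" %in% names(nd)) {
    graphics::plot(-nd$age, nd$trait, xlab = "age (Ma, past to present)",
                   ylab = "trait",
                   pch = ifelse(nd$type == "tip", 19, 21), ...)
    graphics::segments(-nd$age[ed$parent], nd$trait[ed$parent],
                       -nd$age[ed$child], nd$trait[ed$child], col = "grey40")
    int <- nd$type == "internal"
    graphics::arrows(-nd$age[int], nd$ci_lower[int], -nd$age[int],
                     nd$ci_upper[int], angle = 90, code = 3, length = 0.02,
                     col = "grey60")
    return(invisible(x))
  }
  has_age <- !all(is.na(nd$age))
  px <- nd$x; py <- nd$y
  if (has_age) {
    sc <- 0.25 * (max(px) - min(px)) / max(nd$age, 1e-9)
    px <- px + sc * nd$age
    py <- py + 0.5 * sc * nd$age
  }
  graphics::plot(px, py, xlab = "axis 1", ylab = "axis 2",
                 pch = ifelse(nd$type == "tip", 19, 21),
                 col = if (has_age)
                   grDevices::grey(0.7 * nd$age / max(nd$age, 1e-9))
                 else "black", ...)
  graphics::segments(px[ed$parent], py[ed$parent], px[ed$child], py[ed$child],
                     col = "grey50")
  invisible(x)
}
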