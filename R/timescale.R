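# ---------------------------------------------------------------------------
# Fossil / molecular time-scaling of a composite topology.
# ---------------------------------------------------------------------------

#' Read a calibration table
#'
#' Expected CSV columns: `taxon`, `fo_ma` (first occurrence, Ma), `lo_ma`
#' (last occurrence, Ma), and optionally `mrca_of` + `node_date_ma` for
#' molecular node dates. A molecular date row attaches to the most recent
#' common ancestor of the two tip labels in `mrca_of`, separated by `|`.
#'
#' @param path CSV file path, or a data frame already in this layout.
#' @return a validated data frame.
#' @export
read_calibrations <- function(path) {
  cal <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "fo_ma", "lo_ma")
  miss <- setdiff(need, names(cal))
  if (length(miss))
    stop("calibration table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"mrca_of" %in% names(cal)) cal$mrca_of <- NA_character_
  if (!"node_date_ma" %in% names(cal)) cal$node_date_ma <- NA_real_
  tip_rows <- is.na(cal$node_date_ma)
  bad <- tip_rows & (!is.finite(cal$fo_ma) | !is.finite(cal$lo_ma) |
                       cal$lo_ma < 0 | cal$fo_ma < cal$lo_ma)
  if (any(bad))
    stop("invalid occurrence ages (need fo_ma >= lo_ma >= 0) for: ",
         paste(cal$taxon[bad], collapse = ", "))
  cal
}

#' Time-scale a tree from occurrence dates and molecular node dates
#'
#' Assigns an age (Ma) to every node of `tree`. Terminal ages come from the
#' calibration table according to `mode`; each internal node then takes the
#' maximum of its molecular date (if one is attached) and the ages of its
#' children, enforced by a post-order pass so `age(parent) >= age(child)`
#' holds on every edge. A taxon is treated as extant when its last occurrence
#' is 0 Ma.
#'
#' Modes:
#' * `"main"` — fossil tips sit at the midpoint of their stratigraphic range
#'   (arithmetic mean of first and last occurrence); extant tips are dated
#'   (for internal-node purposes) by first occurrence and then extended to
#'   the present (0 Ma) when `extend_extant = TRUE`.
#' * `"range"` — all nodes are dated by first occurrences and every terminal
#'   branch is extended to its last occurrence (fossil ranges treated as
#'   known temporal durations).
#' * `"midpoint"` — midpoint dates for all taxa, with the present as the
#'   upper margin for extant tips when `extend_extant = TRUE`.
#'
#' Zero-duration branches (e.g. a node dated by its oldest descendant fossil)
#' are then resolved with [resolve_zero_branches()].
#'
#' @param tree a `phylo` topology (branch lengths, if any, are ignored).
#' @param cal calibration table or CSV path, see [read_calibrations()].
#' @param mode one of `"main"`, `"range"`, `"midpoint"`.
#' @param extend_extant extend extant terminal branches to 0 Ma.
#' @param zero_policy,epsilon passed to [resolve_zero_branches()].
#' @return a `timetree`.
#' @export
time_scale <- function(tree, cal, mode = c("main", "range", "midpoint"),
                       extend_extant = TRUE,
                       zero_policy = c("share", "epsilon"), epsilon = 0.1) {
  mode <- match.arg(mode)
  zero_policy <- match.arg(zero_policy)
  phy <- as_phylo(tree)
  cal <- read_calibrations(cal)
  tips <- phy$tip.label
  n <- ape::Ntip(phy)

  tip_cal <- cal[is.na(cal$node_date_ma), , drop = FALSE]
  idx <- match(tips, tip_cal$taxon)
  if (anyNA(idx))
    stop("missing calibration row for tip(s): ",
         paste(tips[is.na(idx)], collapse = ", "))
  fo <- tip_cal$fo_ma[idx]
  lo <- tip_cal$lo_ma[idx]
  mid <- (fo + lo) / 2
  extant <- lo <= 1e-9

  dating <- switch(mode,
    main     = ifelse(extant, fo, mid),
    range    = fo,
    midpoint = mid)
  final <- switch(mode,
    main     = ifelse(extant, if (extend_extant) 0 else fo, mid),
    range    = lo,
    midpoint = ifelse(extant & extend_extant, 0, mid))

  # molecular node dates keyed by MRCA of a tip pair
  mol <- rep(NA_real_, n + phy$Nnode)
  node_rows <- cal[!is.na(cal$node_date_ma), , drop = FALSE]
  for (r in seq_len(nrow(node_rows))) {
    pair <- strsplit(node_rows$mrca_of[r], "|", fixed = TRUE)[[1]]
    pair <- trimws(pair)
    if (length(pair) != 2 || !all(pair %in% tips))
      stop("mrca_of must name two tips separated by '|' (row for '",
           node_rows$taxon[r], "')")
    nd <- ape::getMRCA(phy, pair)
    mol[nd] <- max(mol[nd], node_rows$node_date_ma[r], na.rm = TRUE)
  }

  ages <- rep(NA_real_, n + phy$Nnode)
  ages[seq_len(n)] <- dating
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    ages[p] <- max(ages[p], ages[ch], na.rm = TRUE)
  }
  for (nd in which(!is.na(mol))) {
    if (mol[nd] < ages[nd])
      message("molecular date for node ", nd, " (", mol[nd],
              " Ma) is younger than its oldest descendant (", ages[nd],
              " Ma); fossil constraint retained")
    ages[nd] <- max(ages[nd], mol[nd])
  }
  # re-run the post-order pass in case a molecular date pushed a node above
  # an already-assigned ancestor
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    ages[p] <- max(ages[p], ages[ch])
  }
  ages[seq_len(n)] <- final

  tt <- timetree(phy, ages)
  tt <- resolve_zero_branches(tt, policy = zero_policy, epsilon = epsilon)
  if (any(branch_durations(tt) < 0))
    stop("negative branch duration remained after zero-branch resolution")
  tt
}

#' Resolve zero-length branches in a time-scaled tree
#'
#' Identical first-occurrence dates of a terminal taxon and its subtending
#' node produce zero-duration branches. Two resolution policies:
#' * `"share"` — the duration of the nearest ancestral positive branch is
#'   redistributed equally along the whole zero-length chain (node ages along
#'   the chain are re-spaced linearly between the positive ancestor's parent
#'   and the bottom of the chain); ages of all nodes outside the chain, and
#'   hence root-to-tip ages of unaffected tips, are unchanged.
#' * `"epsilon"` — each zero-duration branch is given a minimum duration by
#'   pushing its child `epsilon` Myr younger, cascading towards the tips.
#'
#' @param tree a `timetree`.
#' @param policy `"share"` (default) or `"epsilon"`.
#' @param epsilon minimum branch duration (Myr) for the epsilon policy.
#' @param tol durations at or below this are treated as zero.
#' @return a `timetree` with all branch durations > 0.
#' @export
resolve_zero_branches <- function(tree, policy = c("share", "epsilon"),
                                  epsilon = 0.1, tol = 1e-9) {
  policy <- match.arg(policy)
  stopifnot(is_timetree(tree))
  phy <- tree$phy
  ages <- tree$ages
  N <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, N)
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  if (policy == "epsilon") {
    if (epsilon <= 0) stop("'epsilon' must be positive")
    # preorder: parents before children
    pre <- ape::reorder.phylo(phy, "cladewise")$edge
    for (k in seq_len(nrow(pre))) {
      p <- pre[k, 1]; ch <- pre[k, 2]
      if (ages[p] - ages[ch] <= tol) {
        ages[ch] <- ages[p] - epsilon
        if (ages[ch] < -tol)
          stop("epsilon policy pushed node ", ch, " below the present; ",
               "negative branch duration cannot be resolved")
        ages[ch] <- max(ages[ch], 0)
      }
    }
    return(timetree(phy, ages))
  }

  repeat {
    dur <- ages[parent] - ages
    zero <- which(!is.na(parent) & dur <= tol)
    if (!length(zero)) break
    ch <- zero[1]
    chain <- ch
    p <- parent[ch]
    while (!is.na(parent[p]) && ages[parent[p]] - ages[p] <= tol) {
      chain <- c(p, chain)
      p <- parent[p]
    }
    if (is.na(parent[p]))
      stop("zero-length chain reaches the root with no positive ancestral ",
           "branch to share")
    chain <- c(p, chain)
    top <- ages[parent[p]]
    bottom <- ages[ch]
    step <- (top - bottom) / length(chain)
    if (step <= tol)
      stop("no positive duration available above a zero-length chain")
    ages[chain] <- top - step * seq_along(chain)
  }
  timetree(phy, ages)
}
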