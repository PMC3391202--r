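#' @keywords internal
"_PACKAGE"

#' @importFrom stats cmdscale cophenetic dist lm pf qnorm rnorm rpois runif
#'   sd setNames var anova p.adjust predict quantile
#' @importFrom utils combn read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# timetree: a rooted ape::phylo plus node ages in Ma before present.
# Ages are the primary store; branch durations are always derived from them
# (duration = age(parent) - age(child)), so the two can never disagree.
# ---------------------------------------------------------------------------

#' Construct a time tree from a topology and node ages
#'
#' A `timetree` couples a rooted `ape::phylo` topology with an age (Ma before
#' present, larger = older) for every node. Branch durations are derived as
#' `age(parent) - age(child)` and written into `phy$edge.length`; they are
#' never stored independently.
#'
#' @param phy a rooted `phylo` object.
#' @param ages numeric vector of node ages in Ma, ordered by ape node number
#'   (tips `1..n`, then internal nodes).
#' @return an object of class `timetree` with elements `phy` and `ages`.
#' @export
timetree <- function(phy, ages) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  n <- ape::Ntip(phy)
  if (length(ages) != n + phy$Nnode)
    stop("'ages' must have one entry per node (", n + phy$Nnode, ")")
  if (any(!is.finite(ages)) || any(ages < -1e-9))
    stop("node ages must be finite and non-negative")
  ages[abs(ages) < 1e-12] <- 0
  e <- phy$edge
  dur <- ages[e[, 1]] - ages[e[, 2]]
  if (any(dur < -1e-9))
    stop("negative branch duration: a parent is younger than its child")
  phy$edge.length <- pmax(dur, 0)
  structure(list(phy = phy, ages = unname(ages)), class = "timetree")
}

#' @rdname timetree
#' @param x object to test or convert.
#' @export
is_timetree <- function(x) inherits(x, "timetree")

#' Convert a phylogram with branch lengths into a time tree
#'
#' Node ages are assigned by anchoring the deepest tip(s) at 0 Ma and reading
#' every other age off the root-to-node path lengths. For an ultrametric
#' chronogram this places all tips at the present; tips on shorter paths
#' (fossils) receive positive ages.
#'
#' @param phy a rooted `phylo` with branch lengths, or a `timetree`
#'   (returned unchanged).
#' @return a `timetree`.
#' @export
as_timetree <- function(phy) {
  if (is_timetree(phy)) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be a 'phylo' or 'timetree'")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; cannot assign ages")
  depth <- ape::node.depth.edgelength(phy)
  timetree(phy, max(depth) - depth)
}

#' Extract the phylo topology from a tree argument
#' @noRd
as_phylo <- function(tree) {
  if (is_timetree(tree)) tree$phy else tree
}

#' Node ages and branch durations of a time tree
#'
#' @param tree a `timetree`.
#' @return `node_ages()`: numeric vector of ages (Ma) named by tip/node label
#'   where labels exist; `branch_durations()`: durations (Myr) in
#'   `phy$edge` order.
#' @export
node_ages <- function(tree) {
  stopifnot(is_timetree(tree))
  ages <- tree$ages
  n <- ape::Ntip(tree$phy)
  lab <- c(tree$phy$tip.label,
           if (!is.null(tree$phy$node.label)) tree$phy$node.label
           else rep("", tree$phy$Nnode))
  names(ages) <- lab
  ages
}

#' @rdname node_ages
#' @export
branch_durations <- function(tree) {
  stopifnot(is_timetree(tree))
  e <- tree$phy$edge
  tree$ages[e[, 1]] - tree$ages[e[, 2]]
}

#' @export
print.timetree <- function(x, ...) {
  n <- ape::Ntip(x$phy)
  cat("Time-scaled tree:", n, "tips,", x$phy$Nnode, "internal nodes\n")
  cat("  root age:", format(max(x$ages), digits = 6), "Ma;",
      sum(x$ages[seq_len(n)] <= 1e-9), "extant tip(s),",
      sum(x$ages[seq_len(n)] > 1e-9), "fossil tip(s)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Newick / NEXUS I/O
# ---------------------------------------------------------------------------

#' Read a rooted tree from Newick text or file
#'
#' Thin validating wrapper around [ape::read.tree()]: checks parenthesis
#' balance before parsing and rejects duplicate tip labels, naming the
#' offending token.
#'
#' @param source a Newick string (containing `(`) or a file path.
#' @return a `phylo` object.
#' @export
read_newick <- function(source) {
  txt <- if (length(source) == 1 && !grepl("(", source, fixed = TRUE) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(source, collapse = "")
  }
  opens <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closes <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opens != closes)
    stop("unbalanced parentheses in Newick input: ", opens, " '(' vs ",
         closes, "')'")
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  phy
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` or `timetree`.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  phy <- as_phylo(tree)
  txt <- ape::write.tree(phy, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read trees from a NEXUS trees block
#'
#' @param file path to a NEXUS file.
#' @return a `phylo` (single tree) or `multiPhylo`.
#' @export
read_nexus_trees <- function(file) {
  ape::read.nexus(file)
}

# ---------------------------------------------------------------------------
# Composite-tree surgery
# ---------------------------------------------------------------------------

#' Replace a terminal OTU with an entire donor subtree
#'
#' Used to build composite phylogenies in which a supraspecific terminal
#' (e.g. a subfamily coded as one OTU in a cladistic analysis) is replaced by
#' a fully resolved species-level tree for that clade.
#'
#' @param host a `phylo`; `otu_label` must be one of its tips.
#' @param otu_label tip label to replace.
#' @param donor a rooted `phylo` grafted in place of the tip.
#' @return a `phylo` with `Ntip(host) + Ntip(donor) - 1` tips; all other host
#'   structure is unchanged.
#' @export
graft_subtree <- function(host, otu_label, donor) {
  stopifnot(inherits(host, "phylo"), inherits(donor, "phylo"))
  i <- match(otu_label, host$tip.label)
  if (is.na(i)) {
    if (!is.null(host$node.label) && otu_label %in% host$node.label)
      stop("'", otu_label, "' is an internal node, not a tip")
    stop("tip label '", otu_label, "' not found in host tree")
  }
  if (ape::Ntip(donor) == 1) {
    host$tip.label[i] <- donor$tip.label
    return(host)
  }
  clash <- intersect(host$tip.label[-i], donor$tip.label)
  if (length(clash))
    stop("donor tips already present in host: ", paste(clash, collapse = ", "))
  ape::bind.tree(host, donor, where = i, position = 0)
}

# ---------------------------------------------------------------------------
# Pruning
# ---------------------------------------------------------------------------

#' Prune a tree to a set of retained tips
#'
#' Unary internal nodes created by the pruning are collapsed with their
#' durations summed, so patristic distances (and, for a `timetree`, absolute
#' node ages) among retained tips are preserved exactly.
#'
#' @param tree a `phylo` or `timetree`.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return object of the same class as `tree`.
#' @export
prune_tree <- function(tree, keep) {
  phy <- as_phylo(tree)
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  if (!is_timetree(tree)) return(ape::keep.tip(phy, keep))
  anchor_age <- tree$ages[match(keep[1], phy$tip.label)]
  new_phy <- ape::keep.tip(phy, keep)
  depth <- ape::node.depth.edgelength(new_phy)
  anchor_depth <- depth[match(keep[1], new_phy$tip.label)]
  timetree(new_phy, anchor_age + anchor_depth - depth)
}
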