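# Fixture builders and independent oracles shared across the test files.

# random bifurcating tree with exponential branch lengths
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n)
  phy$edge.length <- phy$edge.length + 0.05  # keep durations well positive
  phy
}

# random ultrametric (pure-birth) tree as a timetree
random_chronogram <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_timetree(ape::rphylo(n, birth = 0.2, death = 0))
}

# simulate plain Brownian tips on a phylo (independent of sim_bm_traits)
bm_tips <- function(phy, sigma2 = 1, root = 0) {
  V <- ape::vcv(phy)
  x <- root + drop(crossprod(chol(sigma2 * V), rnorm(nrow(V))))
  names(x) <- rownames(V)
  x
}

# exhaustive parsimony oracle: minimize changes over all internal-state
# assignments; polymorphic tips may take any state of their set
brute_force_parsimony <- function(phy, tip_sets, states) {
  n <- ape::Ntip(phy)
  grid <- as.matrix(expand.grid(rep(list(states), phy$Nnode)))
  cost <- numeric(nrow(grid))
  for (k in seq_len(nrow(phy$edge))) {
    ps <- grid[, phy$edge[k, 1] - n]
    ch <- phy$edge[k, 2]
    cost <- cost + if (ch <= n) {
      member <- states %in% tip_sets[[ch]]
      as.numeric(!member[match(ps, states)])
    } else {
      as.numeric(ps != grid[, ch - n])
    }
  }
  min(cost)
}

# build a char_matrix programmatically from a list of integer state sets
char_matrix_from_sets <- function(taxa, sets_by_char) {
  fmt <- function(s) {
    if (length(s) == 0) "?"
    else if (length(s) == 1) as.character(s)
    else paste0("[", paste(s, collapse = ""), "]")
  }
  rows <- vapply(seq_along(taxa), function(i) {
    paste0(taxa[i], " ", paste(vapply(sets_by_char, function(ch)
      fmt(ch[[i]]), ""), collapse = ""))
  }, "")
  read_char_matrix(paste0("xread\n", length(sets_by_char), " ",
                          length(taxa), "\n",
                          paste(rows, collapse = "\n"), "\n;"))
}

# patristic distances by explicit path summation (oracle for pruning)
path_sum_distances <- function(phy) {
  n <- ape::Ntip(phy)
  parent <- rep(NA_integer_, n + phy$Nnode)
  blen <- rep(NA_real_, n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  path_to_root <- function(i) {
    nodes <- i
    while (!is.na(parent[i])) {
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    nodes
  }
  D <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_ <- path_to_root(i)
    pj <- path_to_root(j)
    shared <- intersect(pi_, pj)
    mrca <- shared[1]
    seg <- c(pi_[seq_len(which(pi_ == mrca) - 1)],
             pj[seq_len(which(pj == mrca) - 1)])
    D[i, j] <- D[j, i] <- sum(blen[seg])
  }
  D
}

# two-group / multi-group Gaussian blobs for the classifier tests
gaussian_blobs <- function(n_per, centers, sd = 1) {
  g <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(g), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[i, ], `+`)))
  list(x = x, groups = rep(sprintf("g%d", seq_len(g)), each = n_per))
}
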