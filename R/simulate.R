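# ---------------------------------------------------------------------------
# Seeded simulators: pure-birth trees with optional fossilized tips,
# Brownian traits with a Pagel-lambda signal dial, and specimen-level
# measurement tables with group structure, within-species noise, and a
# multiplicative per-specimen size factor.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults emulate a felid-like study system: 52 species (about a third
#' fossil), 29 positive linear measurements, 11 lineages, and roughly 330
#' specimens in total.
#'
#' @param seed mandatory RNG seed (integer).
#' @param n_species tip count of the simulated tree.
#' @param birth pure-birth speciation rate (events/Myr).
#' @param sigma2 Brownian rate per trait (variance/Myr).
#' @param root root state (recycled over traits).
#' @param n_traits number of Brownian traits for [sim_bm_traits()].
#' @param lambda Pagel-lambda signal dial in `[0, 1]`: 1 is pure Brownian
#'   motion, 0 removes all shared-branch covariance (star-equivalent).
#' @param n_groups number of lineage labels (clades) for specimen tables.
#' @param within_sd within-species log-scale noise sd.
#' @param size_sd per-specimen size-factor log-scale sd.
#' @param fossil_fraction fraction of tips truncated into fossils.
#' @param range_halfwidth half-width (Myr) of simulated stratigraphic ranges.
#' @param n_vars number of measurement variables for specimen tables.
#' @param specimens_mean mean specimens per species (min 2).
#' @param root_log_mean,root_log_sd distribution of per-variable root
#'   log-measurements (log-mm scale).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_species = 52, birth = 0.18, sigma2 = 0.01,
                       root = 0, n_traits = 2, lambda = 1, n_groups = 11,
                       within_sd = 0.05, size_sd = 0.12,
                       fossil_fraction = 18 / 52, range_halfwidth = 0.5,
                       n_vars = 29, specimens_mean = 6.3,
                       root_log_mean = 3.5, root_log_sd = 0.6) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  stopifnot(n_species >= 2, birth > 0, all(sigma2 >= 0),
            lambda >= 0, lambda <= 1, n_groups >= 1, within_sd >= 0,
            size_sd >= 0, fossil_fraction >= 0, fossil_fraction < 1,
            range_halfwidth >= 0, n_vars >= 2, specimens_mean >= 2)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth time tree with optional fossil tips
#'
#' An ultrametric pure-birth tree is simulated, then a configured fraction
#' of tips is converted to fossils by truncating their terminal branches at
#' a uniformly drawn point. The matching calibration table (taxon, first and
#' last occurrence) is attached as `attr(, "calibration")`: fossil ranges
#' are drawn symmetrically around the true truncation age (so their midpoint
#' recovers it exactly), extant taxa get a first occurrence inside their
#' terminal branch and a last occurrence of 0 Ma.
#'
#' @param cfg a [sim_config()].
#' @return a `timetree` with a `calibration` attribute (data frame).
#' @export
sim_birth_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  phy <- ape::rphylo(cfg$n_species, birth = cfg$birth, death = 0)
  phy$tip.label <- sprintf("sp%02d", seq_len(cfg$n_species))
  tt <- as_timetree(phy)
  ages <- tt$ages
  n <- cfg$n_species
  parent <- rep(NA_integer_, length(ages))
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  n_fossil <- round(cfg$fossil_fraction * n)
  fossil <- sort(sample.int(n, n_fossil))
  for (i in fossil) {
    ages[i] <- ages[parent[i]] * (1 - runif(1, 0.15, 0.85))
  }
  tt <- timetree(phy, ages)

  fo <- lo <- numeric(n)
  for (i in seq_len(n)) {
    if (i %in% fossil) {
      d <- min(runif(1, 0, cfg$range_halfwidth), 0.95 * ages[i])
      fo[i] <- ages[i] + d
      lo[i] <- ages[i] - d
    } else {
      fo[i] <- runif(1, 0.2, 0.8) * ages[parent[i]]
      lo[i] <- 0
    }
  }
  cal <- data.frame(
    taxon = phy$tip.label, fo_ma = fo, lo_ma = lo,
    mrca_of = NA_character_, node_date_ma = NA_real_,
    stringsAsFactors = FALSE)
  # molecular root date (true root age), keyed by a tip pair spanning the root
  first_tip <- function(nd) {
    kids <- phy$edge[, 2][phy$edge[, 1] == nd]
    while (length(kids)) {
      nd <- kids[1]
      kids <- phy$edge[, 2][phy$edge[, 1] == nd]
    }
    phy$tip.label[nd]
  }
  root_kids <- phy$edge[, 2][phy$edge[, 1] == n + 1L]
  cal <- rbind(cal, data.frame(
    taxon = "root", fo_ma = NA_real_, lo_ma = NA_real_,
    mrca_of = paste(first_tip(root_kids[1]), first_tip(root_kids[2]),
                    sep = "|"),
    node_date_ma = max(ages), stringsAsFactors = FALSE))
  attr(tt, "calibration") <- cal
  tt
}

#' Simulate Brownian traits on a time-scaled tree
#'
#' Tip values are drawn from the multivariate normal implied by Brownian
#' motion: covariance `sigma2 * shared path length`, scaled off-diagonally by
#' the Pagel-lambda dial (`lambda = 1` pure Brownian, `lambda = 0`
#' star-equivalent: independent tips).
#'
#' @param tree a `timetree` or `phylo` with branch durations.
#' @param cfg a [sim_config()]; `sigma2` is recycled to `n_traits`, as is
#'   `root`.
#' @param n_traits,seed overrides for the config values.
#' @return matrix (tips x traits) with tip-label row names.
#' @export
sim_bm_traits <- function(tree, cfg, n_traits = cfg$n_traits,
                          seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must carry branch durations")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(phy)
  sigma2 <- rep_len(cfg$sigma2, n_traits)
  root <- rep_len(cfg$root, n_traits)
  V <- ape::vcv(phy)
  V_off <- cfg$lambda * V
  diag(V_off) <- diag(V)
  X <- matrix(NA_real_, n, n_traits,
              dimnames = list(phy$tip.label,
                              paste0("trait", seq_len(n_traits))))
  for (j in seq_len(n_traits)) {
    if (sigma2[j] == 0) {
      X[, j] <- root[j]
    } else {
      R <- chol(sigma2[j] * V_off)
      X[, j] <- root[j] + drop(crossprod(R, rnorm(n)))
    }
  }
  X
}

#' @noRd
clade_groups <- function(tree, k) {
  tt <- as_timetree(tree)
  phy <- tt$phy
  n <- ape::Ntip(phy)
  if (k > n) stop("cannot form more groups than tips")
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  descend_tips <- function(nd) {
    if (nd <= n) return(nd)
    unlist(lapply(kids[[as.character(nd)]], descend_tips))
  }
  groups <- list(n + 1L)  # start from the root clade
  while (length(groups) < k) {
    roots <- unlist(groups)
    splittable <- roots[roots > n]
    if (!length(splittable)) break
    oldest <- splittable[which.max(tt$ages[splittable])]
    i <- which(roots == oldest)
    groups <- c(groups[-i], as.list(kids[[as.character(oldest)]]))
  }
  lineage <- character(n)
  for (gi in seq_along(groups)) {
    lineage[descend_tips(groups[[gi]])] <- sprintf("lineage%02d", gi)
  }
  names(lineage) <- phy$tip.label
  lineage
}

#' Simulate a specimen-level measurement table
#'
#' Species log-mean measurement vectors evolve by Brownian motion on the
#' tree (one trait per variable, root values drawn per variable); each
#' specimen's measurements are `exp(species mean + within-species noise) *
#' size factor`, with a per-specimen multiplicative size factor
#' `exp(N(0, size_sd^2))` shared across its variables, guaranteeing
#' positivity. Lineage labels are clade memberships from the `n_groups - 1`
#' oldest splits of the tree.
#'
#' @param tree a `timetree` (e.g. from [sim_birth_tree()]).
#' @param cfg a [sim_config()].
#' @param means optional species x variables log-mean matrix; simulated with
#'   [sim_bm_traits()] when `NULL`.
#' @param seed RNG seed (defaults to `cfg$seed + 1` so the table differs
#'   from the tree draw).
#' @return data frame: `specimen`, `species`, `lineage`, and `n_vars`
#'   measurement columns `V1..Vk` (all positive).
#' @export
sim_specimen_table <- function(tree, cfg, means = NULL, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "sim_config"))
  phy <- as_phylo(tree)
  n <- ape::Ntip(phy)
  set.seed(seed)
  if (is.null(means)) {
    roots <- rnorm(cfg$n_vars, cfg$root_log_mean, cfg$root_log_sd)
    cfg_means <- cfg
    cfg_means$root <- 0
    means <- sim_bm_traits(tree, cfg_means, n_traits = cfg$n_vars, seed = NULL)
    means <- sweep(means, 2, roots, `+`)
  }
  lineage <- clade_groups(tree, cfg$n_groups)
  n_spec <- 2L + rpois(n, cfg$specimens_mean - 2)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    sp <- phy$tip.label[s]
    size <- rnorm(n_spec[s], 0, cfg$size_sd)
    noise <- matrix(rnorm(n_spec[s] * cfg$n_vars, 0, cfg$within_sd),
                    n_spec[s], cfg$n_vars)
    meas <- exp(sweep(noise, 2, means[sp, ], `+`) + size)
    colnames(meas) <- paste0("V", seq_len(cfg$n_vars))
    rows[[s]] <- data.frame(
      specimen = sprintf("%s_%02d", sp, seq_len(n_spec[s])),
      species = sp, lineage = unname(lineage[sp]), meas,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a complete felid-like synthetic dataset
#'
#' One seeded call producing everything the pipeline consumes: a pure-birth
#' tree with fossilized tips, its calibration table, and a specimen-level
#' measurement table with lineage labels.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return list with `tree` (`timetree`), `calibration` (data frame),
#'   `measurements` (data frame), and `config`.
#' @export
sim_felid_like <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  tt <- sim_birth_tree(cfg)
  meas <- sim_specimen_table(tt, cfg)
  list(tree = tt, calibration = attr(tt, "calibration"),
       measurements = meas, config = cfg)
}
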