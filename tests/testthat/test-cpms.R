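test_that("two-tip ancestral estimates are precision-weighted means", {
  phy <- read_newick("(A:1,B:1);")
  anc <- ancestral_ml(phy, c(A = 0, B = 4))
  expect_equal(unname(anc$estimates["node3", 1]), 2)
  phy2 <- read_newick("(A:1,B:3);")
  anc2 <- ancestral_ml(phy2, c(A = 0, B = 4))
  expect_equal(unname(anc2$estimates["node3", 1]), (0 / 1 + 4 / 3) / (1 + 1 / 3))
})

test_that("the linear system matches direct numerical minimization", {
  set.seed(1)
  for (rep in 1:10) {
    phy <- random_tree(20)
    x <- bm_tips(phy)
    anc <- ancestral_ml(phy, x)
    n <- ape::Ntip(phy)
    est <- unname(anc$estimates[(n + 1):(2 * n - 1), 1])
    objective <- function(theta) {
      vals <- c(x[phy$tip.label], theta)
      sum((vals[phy$edge[, 1]] - vals[phy$edge[, 2]])^2 / phy$edge.length)
    }
    opt <- optim(est + rnorm(n - 1, 0, 0.5), objective, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    expect_lt(max(abs(est - opt$par)), 1e-4)
    expect_lte(objective(est), opt$value + 1e-8)
  }
})

test_that("the root estimate equals the GLS phylogenetic mean", {
  set.seed(2)
  for (rep in 1:5) {
    phy <- random_tree(15)
    x <- bm_tips(phy)
    anc <- ancestral_ml(phy, x)
    V <- ape::vcv(phy)
    Vinv <- solve(V)
    gls_mean <- sum(Vinv %*% x[phy$tip.label]) / sum(Vinv)
    expect_equal(unname(anc$estimates[ape::Ntip(phy) + 1, 1]), gls_mean,
                 tolerance = 1e-9)
  }
})

test_that("ancestral estimates agree with ape::ace maximum likelihood", {
  set.seed(3)
  phy <- random_tree(25)
  x <- bm_tips(phy)
  anc <- ancestral_ml(phy, x, sigma_method = "ML")
  ref <- ape::ace(x[phy$tip.label], phy, method = "ML", model = "BM")
  n <- ape::Ntip(phy)
  expect_equal(unname(anc$estimates[(n + 1):(2 * n - 1), 1]),
               unname(ref$ace), tolerance = 1e-4)
})

test_that("confidence intervals follow the 1.96-sigma construction", {
  phy <- random_tree(12, seed = 4)
  x <- bm_tips(phy)
  anc <- ancestral_ml(phy, x)
  half <- anc$ci_upper - anc$estimates
  expect_equal(half, qnorm(0.975) * sqrt(anc$variance), tolerance = 1e-12)
  # tips are observed: zero variance, degenerate intervals
  expect_equal(unname(anc$variance[seq_len(12), 1]), rep(0, 12))
  expect_true(all(anc$variance >= 0))
  expect_error(ancestral_ml(ape::read.tree(text = "(A:0,B:1);"),
                            c(A = 1, B = 2)), "zero or negative")
})

test_that("phylomorphospace places tips at data and edges along the tree", {
  tt <- random_chronogram(10, seed = 5)
  set.seed(5)
  scores <- cbind(bm_tips(tt$phy), bm_tips(tt$phy))
  g <- build_phylomorphospace(tt$phy, scores)
  expect_equal(nrow(g$edges), 2 * 10 - 2)
  expect_equal(g$nodes$x[1:10], unname(scores[tt$phy$tip.label, 1]))
  expect_true(all(is.na(g$nodes$age)))
  # two-tip tree: root at the weighted mean of the tip points
  phy2 <- read_newick("(A:2,B:2);")
  g2 <- build_phylomorphospace(phy2, rbind(A = c(0, 1), B = c(4, 3)))
  expect_equal(g2$nodes$x[3], 2)
  expect_equal(g2$nodes$y[3], 2)
})

test_that("the CPMS temporal axis equals the tree ages exactly", {
  sim <- sim_felid_like(7, n_species = 20)
  tt <- time_scale(sim$tree$phy, sim$calibration, mode = "main")
  shape <- mosimann_transform(sim$measurements)
  ord <- pca_morphospace(shape)
  cent <- species_centroids(ord, shape$species)
  g <- build_cpms(tt, cent[tt$phy$tip.label, 1:2])
  expect_identical(g$nodes$age, tt$ages)
  # every edge runs old -> young
  expect_true(all(g$nodes$age[g$edges$parent] >= g$nodes$age[g$edges$child]))
  # extant tips at the present, fossil tips at their midpoint dates
  extant <- sim$calibration$lo_ma <= 0 & is.na(sim$calibration$node_date_ma)
  tip_ages <- g$nodes$age[match(sim$calibration$taxon[extant],
                                tt$phy$tip.label)]
  expect_true(all(tip_ages == 0))
  # dropping the age column reproduces the 2-D phylomorphospace bit-for-bit
  g2d <- build_phylomorphospace(tt, cent[tt$phy$tip.label, 1:2])
  expect_identical(g$nodes$x, g2d$nodes$x)
  expect_identical(g$nodes$y, g2d$nodes$y)
  expect_identical(g$edges, g2d$edges)
  expect_error(build_cpms(tt$phy, cent[tt$phy$tip.label, 1:2]), "timetree")
})

test_that("the CPMS graph is invariant under tip reordering of the inputs", {
  tt <- random_chronogram(12, seed = 6)
  set.seed(6)
  scores <- cbind(bm_tips(tt$phy), bm_tips(tt$phy))
  g1 <- build_cpms(tt, scores)
  g2 <- build_cpms(tt, scores[rev(rownames(scores)), ])
  expect_equal(g1$nodes, g2$nodes, tolerance = 1e-12)
  expect_identical(g1$edges, g2$edges)
})

test_that("the 1-D variant carries intervals and handles constants", {
  tt <- random_chronogram(8, seed = 7)
  const <- setNames(rep(1.5, 8), tt$phy$tip.label)
  g <- build_cpms_1d(tt, const)
  expect_equal(g$nodes$trait, rep(1.5, nrow(g$nodes)))
  int <- g$nodes$type == "internal"
  expect_equal((g$nodes$ci_lower[int] + g$nodes$ci_upper[int]) / 2,
               g$nodes$trait[int], tolerance = 1e-12)
  # the 2-tip precision-weighted example lands at (1, root age)
  phy2 <- read_newick("(A:1,B:3);")
  tt2 <- as_timetree(phy2)
  g2 <- build_cpms_1d(tt2, c(A = 0, B = 4))
  expect_equal(g2$nodes$trait[3], 1)
  expect_equal(g2$nodes$age[3], max(tt2$ages))
})

test_that("graph export round-trips through JSON and CSV", {
  tt <- random_chronogram(9, seed = 8)
  set.seed(8)
  g <- build_cpms(tt, cbind(bm_tips(tt$phy), bm_tips(tt$phy)))
  jf <- tempfile(fileext = ".json")
  export_graph(g, jf, format = "json")
  back <- import_graph(jf)
  expect_equal(back$nodes$x, g$nodes$x, tolerance = 1e-12)
  expect_equal(back$nodes$age, g$nodes$age, tolerance = 1e-12)
  expect_equal(back$edges$parent, g$edges$parent)
  stem <- tempfile()
  paths <- export_graph(g, stem, format = "csv")
  nodes <- read.csv(paste0(stem, "_nodes.csv"))
  edges <- read.csv(paste0(stem, "_edges.csv"))
  expect_equal(nrow(nodes), nrow(g$nodes))
  expect_equal(nrow(edges), nrow(g$nodes) - 1)
  expect_equal(nodes$age, g$nodes$age, tolerance = 1e-12)
  pf <- tempfile(fileext = ".png")
  export_graph(g, pf, format = "plot")
  expect_true(file.exists(pf) && file.size(pf) > 0)
})
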