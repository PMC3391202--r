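make_cal <- function(taxon, fo, lo, mrca = NULL, date = NULL) {
  cal <- data.frame(taxon = taxon, fo_ma = fo, lo_ma = lo,
                    mrca_of = NA_character_, node_date_ma = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(mrca)) {
    cal <- rbind(cal, data.frame(taxon = "node", fo_ma = NA, lo_ma = NA,
                                 mrca_of = mrca, node_date_ma = date))
  }
  cal
}

test_that("fossil tips are dated at the midpoint of their range", {
  phy <- read_newick("((fossil,extant1),extant2);")
  cal <- make_cal(c("fossil", "extant1", "extant2"),
                  fo = c(1.81, 3.8, 4.2), lo = c(0.0117, 0, 0),
                  mrca = "extant1|extant2", date = 10)
  tt <- time_scale(phy, cal, mode = "main")
  ages <- node_ages(tt)
  expect_equal(unname(ages["fossil"]), (1.81 + 0.0117) / 2)  # 0.91085
  expect_equal(unname(ages["fossil"]), 0.91085)
  expect_equal(unname(ages[c("extant1", "extant2")]), c(0, 0))
  expect_equal(max(ages), 10)
})

test_that("internal nodes take the max of molecular and fossil dates", {
  phy <- read_newick("(((old_fossil,ext1),ext2),old_out);")
  base <- make_cal(c("old_fossil", "ext1", "ext2", "old_out"),
                   fo = c(13, 2, 2, 16), lo = c(11, 0, 0, 14))
  root_row <- data.frame(taxon = "root", fo_ma = NA, lo_ma = NA,
                         mrca_of = "ext1|old_out", node_date_ma = 18)
  # oldest descendant fossil (12 Ma midpoint) beats the molecular date (10)
  node_row <- data.frame(taxon = "node", fo_ma = NA, lo_ma = NA,
                         mrca_of = "old_fossil|ext2", node_date_ma = 10)
  expect_message(tt <- time_scale(phy, rbind(base, root_row, node_row),
                                  mode = "main"),
                 "younger than its oldest descendant")
  inner <- ape::getMRCA(tt$phy, c("old_fossil", "ext2"))
  expect_gte(tt$ages[inner], 12)
  expect_equal(max(node_ages(tt)), 18)  # root from its molecular date

  # molecular date older than all descendant fossils wins
  node_row$node_date_ma <- 17
  tt2 <- time_scale(phy, rbind(base, root_row, node_row), mode = "main")
  expect_equal(unname(node_ages(tt2)[ape::getMRCA(tt2$phy,
                                                  c("old_fossil", "ext2"))]),
               17)
  expect_equal(max(node_ages(tt2)), 18)

  # without any constraint older than the deepest taxon, the zero chain
  # reaches the root and is a hard error
  expect_error(time_scale(phy, base, mode = "main"), "root")
})

test_that("extend_extant pins extant tips to the present", {
  phy <- read_newick("((ext1,ext2),out);")
  cal <- make_cal(c("ext1", "ext2", "out"), fo = c(3.8, 2, 2),
                  lo = c(0, 0, 0), mrca = "ext1|out", date = 6)
  tt <- time_scale(phy, cal, mode = "main", extend_extant = TRUE)
  ages <- node_ages(tt)
  expect_equal(unname(ages["ext1"]), 0)
  expect_equal(max(ages), 6)
  # duration of ext1 terminal branch: parent dated by fo=3.8 of ext1
  e <- tt$phy$edge
  i <- which(e[, 2] == match("ext1", tt$phy$tip.label))
  expect_equal(tt$phy$edge.length[i], 3.8)

  tt2 <- time_scale(phy, cal, mode = "main", extend_extant = FALSE)
  expect_equal(unname(node_ages(tt2)["ext1"]), 3.8)
})

test_that("range and midpoint modes date terminals as documented", {
  phy <- read_newick("((fossil,ext),out);")
  cal <- make_cal(c("fossil", "ext", "out"), fo = c(8, 3, 2),
                  lo = c(6, 0, 0), mrca = "fossil|out", date = 12)
  # range: internal nodes from first occurrences, tips extended to last
  tr <- time_scale(phy, cal, mode = "range")
  ages <- node_ages(tr)
  expect_equal(unname(ages["fossil"]), 6)
  expect_equal(unname(ages["ext"]), 0)
  expect_equal(sort(unname(ages[4:5])), c(8, 12))
  # midpoint: all taxa at midpoints, extant extended to the present
  tm <- time_scale(phy, cal, mode = "midpoint")
  ages_m <- node_ages(tm)
  expect_equal(unname(ages_m["fossil"]), 7)
  expect_equal(unname(ages_m["ext"]), 0)
})

test_that("main mode with all-extant tips and molecular dates reproduces the chronogram", {
  tt <- random_chronogram(12, seed = 8)
  phy <- tt$phy
  # molecular date for every internal node via a spanning tip pair
  n <- ape::Ntip(phy)
  first_tip <- function(nd) {
    repeat {
      kids <- phy$edge[phy$edge[, 1] == nd, 2]
      if (!length(kids)) return(phy$tip.label[nd])
      nd <- kids[1]
    }
  }
  rows <- lapply((n + 1):(n + phy$Nnode), function(nd) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    data.frame(taxon = paste0("node", nd), fo_ma = NA, lo_ma = NA,
               mrca_of = paste(first_tip(kids[1]), first_tip(kids[2]),
                               sep = "|"),
               node_date_ma = tt$ages[nd], stringsAsFactors = FALSE)
  })
  cal <- rbind(data.frame(taxon = phy$tip.label, fo_ma = 1e-4, lo_ma = 0,
                          mrca_of = NA_character_, node_date_ma = NA_real_),
               do.call(rbind, rows))
  out <- time_scale(phy, cal, mode = "main", extend_extant = TRUE)
  expect_equal(out$ages, tt$ages, tolerance = 1e-9)
})

test_that("missing calibration rows are a hard error", {
  phy <- read_newick("((a,b),c);")
  cal <- make_cal(c("a", "b"), fo = c(1, 1), lo = c(0, 0))
  expect_error(time_scale(phy, cal), "missing calibration.*c")
})

test_that("share policy redistributes duration along the zero chain", {
  # grandparent 7 Ma -> parent 5 Ma -> child tip 5 Ma (zero terminal branch)
  phy <- read_newick("((fossil,ext1),ext2);")
  ages <- c(5, 0, 0, 7, 5)  # tips fossil, ext1, ext2; root 7; inner node 5
  tt <- suppressWarnings(timetree(phy, ages))
  fixed <- resolve_zero_branches(tt, policy = "share")
  inner <- ape::getMRCA(phy, c("fossil", "ext1"))
  expect_equal(fixed$ages[inner], 6)           # 2 Myr shared equally
  expect_equal(fixed$ages[match("fossil", phy$tip.label)], 5)  # tip fixed
  expect_true(all(branch_durations(fixed) > 0))
})

test_that("epsilon policy pushes the child by the floor amount", {
  phy <- read_newick("((fossil,ext1),ext2);")
  tt <- timetree(phy, c(5, 0, 0, 7, 5))
  fixed <- resolve_zero_branches(tt, policy = "epsilon", epsilon = 0.1)
  expect_equal(fixed$ages[match("fossil", phy$tip.label)], 4.9)
  expect_true(all(branch_durations(fixed) > 0))
})

test_that("trees without zero branches pass through unchanged", {
  tt <- random_chronogram(10, seed = 2)
  expect_equal(resolve_zero_branches(tt, "share")$ages, tt$ages)
  expect_equal(resolve_zero_branches(tt, "epsilon")$ages, tt$ages)
})

test_that("a zero chain reaching the root is an error under share", {
  phy <- read_newick("((a,b),c);")
  tt <- timetree(phy, c(5, 0, 0, 5, 5))
  expect_error(resolve_zero_branches(tt, "share"), "root")
})

test_that("time_scale output always satisfies the age ordering invariant", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_species = 25)
    tt <- sim_birth_tree(cfg)
    cal <- attr(tt, "calibration")
    for (mode in c("main", "range", "midpoint")) {
      out <- time_scale(tt$phy, cal, mode = mode)
      expect_true(all(branch_durations(out) > 0),
                  label = sprintf("positive durations (seed %d, %s)", seed, mode))
      e <- out$phy$edge
      expect_true(all(out$ages[e[, 1]] >= out$ages[e[, 2]]),
                  label = sprintf("parent older (seed %d, %s)", seed, mode))
    }
  }
})
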