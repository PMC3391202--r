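test_that("TNT cells parse with the stated symbol semantics", {
  m <- read_char_matrix("xread\n4 2\ntaxA 01?[01]\ntaxB 0110\n;")
  expect_equal(m$taxa, c("taxA", "taxB"))
  expect_equal(m$nchar, 4)
  expect_equal(m$cells[[1, 1]], 0L)
  expect_equal(m$cells[[1, 2]], 1L)
  expect_true(m$missing[1, 3])
  expect_equal(m$cells[[1, 4]], c(0L, 1L))
  # '?' expands to all observed states of its character
  eff <- chronomorph:::effective_cells(m)
  expect_equal(eff[[1, 3]], 1L)   # only state 1 observed in character 3
  expect_equal(eff[[1, 4]], c(0L, 1L))
  m2 <- read_char_matrix("xread\n1 3\na 0\nb ?\nc 1\n;")
  expect_equal(chronomorph:::effective_cells(m2)[[2, 1]], c(0L, 1L))

  expect_error(read_char_matrix("xread\n4 2\na 01\nb 0110\n;"),
               "length mismatch")
  expect_error(read_char_matrix("xread\n2 2\na 0x\nb 01\n;"),
               "unknown symbol")
})

test_that("NEXUS matrices parse and dimensions are honoured", {
  nex <- paste(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=4;",
    "FORMAT SYMBOLS=\"01\" MISSING=? ;", "MATRIX",
    "t1 0101", "t2 01(01)1", "t3 1?10", ";", "END;", sep = "\n")
  m <- read_char_matrix(nex)
  expect_equal(length(m$taxa), 3)
  expect_equal(m$nchar, 4)
  expect_equal(m$cells[[2, 3]], c(0L, 1L))
  expect_true(m$missing[3, 2])
})

test_that("write/read round-trips a matrix exactly", {
  set.seed(14)
  taxa <- sprintf("t%02d", 1:15)
  sets <- lapply(1:44, function(j) {
    lapply(1:15, function(i) {
      r <- runif(1)
      if (r < 0.05) integer(0)            # missing
      else if (r < 0.12) c(0L, 1L)        # polymorphic
      else sample(0:1, 1)
    })
  })
  m <- char_matrix_from_sets(taxa, sets)
  expect_equal(length(m$taxa), 15)
  expect_equal(m$nchar, 44)
  m2 <- read_char_matrix(write_char_matrix(m))
  expect_equal(m2$taxa, m$taxa)
  expect_equal(m2$cells, m$cells)
  expect_equal(m2$missing, m$missing)
})

test_that("supraspecific OTU scoring follows the five-member sum rule", {
  expect_equal(score_supraspecific_otu(c(0, 0, 0, 0, 0)), 0L)
  expect_equal(score_supraspecific_otu(c(1, 0, 0, 0, 0)), 0L)
  expect_equal(score_supraspecific_otu(c(0, 1, 1, 0, 0)), c(0L, 1L))
  expect_equal(score_supraspecific_otu(c(1, 1, 1, 0, 0)), c(0L, 1L))
  expect_equal(score_supraspecific_otu(c(1, 1, 1, 1, 0)), 1L)
  expect_equal(score_supraspecific_otu(c(1, 1, 1, 1, 1)), 1L)
  # the documented non-binary exception: 4/5 agreement passes through
  expect_equal(score_supraspecific_otu(c(2, 2, 2, 2, 0)), 2L)
  expect_error(score_supraspecific_otu(c(2, 2, 0, 0, 1)), "majority")
  expect_error(score_supraspecific_otu(c(0, 1, 1)), "5")
})

test_that("Fitch length matches hand-worked four-tip cases", {
  tr <- read_newick("((A,B),(C,D));")
  m1 <- char_matrix_from_sets(LETTERS[1:4], list(list(0L, 0L, 1L, 1L)))
  expect_equal(fitch_length(tr, m1)$total, 1)
  m2 <- char_matrix_from_sets(LETTERS[1:4], list(list(0L, 1L, 0L, 1L)))
  expect_equal(fitch_length(tr, m2)$total, 2)
  # polymorphic tip can absorb a change
  m3 <- char_matrix_from_sets(LETTERS[1:4], list(list(0L, c(0L, 1L), 1L, 1L)))
  expect_equal(fitch_length(tr, m3)$total, 1)
})

test_that("Fitch equals exhaustive minimization on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    phy <- ape::rtree(6, br = NULL)
    n_states <- sample(2:3, 1)
    sets <- lapply(1:4, function(j) {
      lapply(1:6, function(i) {
        s <- sort(sample(0:(n_states - 1), sample(1:2, 1)))
        unique(s)
      })
    })
    m <- char_matrix_from_sets(phy$tip.label, sets)
    got <- fitch_length(phy, m)$per_character
    want <- vapply(1:4, function(j) {
      brute_force_parsimony(phy, lapply(1:6, function(i) sets[[j]][[i]]),
                            0:(n_states - 1))
    }, 0)
    expect_equal(got, want, label = sprintf("replicate %d", rep))
  }
})

test_that("Fitch length agrees with phangorn on fixed-state matrices", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  phy <- ape::rtree(12, br = NULL)
  states <- matrix(sample(0:2, 12 * 10, replace = TRUE), 12,
                   dimnames = list(phy$tip.label, NULL))
  sets <- lapply(1:10, function(j) lapply(1:12, function(i)
    states[i, j]))
  m <- char_matrix_from_sets(phy$tip.label, sets)
  chr <- states
  mode(chr) <- "character"
  pd <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1", "2"))
  expect_equal(fitch_length(phy, m)$total,
               phangorn::parsimony(phy, pd, method = "fitch"))
})

test_that("ensemble index components behave as defined", {
  tr <- read_newick("((A,B),(C,D));")
  # homoplasy-free character: s = m -> per-character ci = 1
  clean <- char_matrix_from_sets(LETTERS[1:4], list(list(0L, 0L, 1L, 1L)))
  idx <- ensemble_indices(tr, clean)
  expect_equal(idx$per_character$ci, 1)
  expect_equal(idx$ri, 1)
  # maximally homoplastic: s = g -> per-character ri = 0
  worst <- char_matrix_from_sets(LETTERS[1:4], list(list(0L, 1L, 0L, 1L)))
  idx2 <- ensemble_indices(tr, worst)
  expect_equal(idx2$per_character$ri, 0)
  expect_equal(idx2$ri, 0)
  # rc follows the chosen convention
  both <- char_matrix_from_sets(LETTERS[1:4],
                                list(list(0L, 0L, 1L, 1L),
                                     list(0L, 1L, 0L, 1L),
                                     list(0L, 0L, 0L, 1L)))  # uninformative
  i_all <- ensemble_indices(tr, both, rc_convention = "all")
  i_excl <- ensemble_indices(tr, both, rc_convention = "excl")
  expect_equal(i_all$rc, i_all$ci_all * i_all$ri)
  expect_equal(i_excl$rc, i_excl$ci_excl * i_excl$ri)
  expect_false(isTRUE(all.equal(i_all$rc, i_excl$rc)))
})

test_that("adding an uninformative character shifts length by m_i only", {
  set.seed(31)
  phy <- ape::rtree(8, br = NULL)
  sets <- lapply(1:6, function(j) lapply(1:8, function(i) sample(0:1, 1)))
  m <- char_matrix_from_sets(phy$tip.label, sets)
  base <- ensemble_indices(phy, m)
  # autapomorphy: one taxon scored 1, the rest 0 (min steps = 1 on any tree)
  aut <- lapply(1:8, function(i) if (i == 3) 1L else 0L)
  m_plus <- char_matrix_from_sets(phy$tip.label, c(sets, list(aut)))
  plus <- ensemble_indices(phy, m_plus)
  expect_equal(plus$tree_length, base$tree_length + 1)
  expect_equal(plus$ci_excl, base$ci_excl)
  expect_false(plus$per_character$informative[7])
})
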