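test_that("fitch_length matches simple hand-checked cases", {
  # identical taxa -> 0 steps
  m0 <- character_matrix(letters[1:4],
                         matrix(1L, 4, 5))
  t0 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(fitch_length(t0, m0), 0)
  # one binary character 0,0,1,1 on ((a,b),(c,d)) -> 1 step
  m1 <- character_matrix(letters[1:4], matrix(c(1L, 1L, 2L, 2L), 4, 1))
  expect_equal(fitch_length(t0, m1), 1)
  # same character on the conflicting topology -> 2 steps
  t1 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(fitch_length(t1, m1), 2)
  # leaf mismatch is an error
  expect_error(fitch_length(t0, drop_taxa(m1, "a")), "differ")
})

test_that("fitch_length equals the exhaustive-assignment oracle (property)", {
  set.seed(21)
  for (r in 1:25) {
    n <- sample(4:6, 1)
    m <- random_matrix(n, sample(3:8, 1), n_states = sample(2:3, 1),
                       random_meta = r %% 3 == 0)
    nl <- cladomorph:::nl_random_tree(n)
    expect_equal(cladomorph:::nl_score(nl, cladomorph:::score_context(m)),
                 brute_fitch(nl, m), label = paste("rep", r))
  }
})

test_that("fitch_length agrees with phangorn on clean binary data", {
  set.seed(22)
  for (r in 1:10) {
    n <- sample(5:8, 1)
    cells <- matrix(bitwShiftL(1L, sample(0:1, n * 12, replace = TRUE)), n, 12)
    m <- character_matrix(paste0("t", 1:n), cells)
    phy <- ape::rtree(n, tip.label = m$taxa)
    states <- matrix(ifelse(cells == 1L, "0", "1"), n,
                     dimnames = list(m$taxa, NULL))
    pd <- phangorn::phyDat(states, type = "USER", levels = c("0", "1"))
    expect_equal(fitch_length(phy, m),
                 as.numeric(phangorn::parsimony(phy, pd)))
  }
})

test_that("polytomies are scored as given, not resolved", {
  # star tree over 4 taxa with character 0,0,1,1: star length is 1... no:
  # star scores n_obs - max_freq = 2 here; any resolved tree scores 1
  m <- character_matrix(letters[1:4], matrix(c(1L, 1L, 2L, 2L), 4, 1))
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(fitch_length(star, m), 2)
})

test_that("min_steps and max_steps follow the stated conventions", {
  # constant, binary-variable, three-state characters
  cells <- cbind(
    rep(1L, 6),                       # constant -> M 0, G 0
    c(1L, 1L, 1L, 2L, 2L, 2L),       # binary 3/3 -> M 1, G 3
    c(1L, 2L, 4L, 1L, 1L, 1L),       # states {0,1,2} -> M 2, G 2
    c(1L, 1L, 1L, 1L, 1L, 2L)        # one deviant taxon -> M 1, G 1
  )
  m <- character_matrix(paste0("t", 1:6), cells)
  expect_equal(min_steps(m), 0 + 1 + 2 + 1)
  expect_equal(max_steps(m), 0 + 3 + 2 + 1)
  # missing cells are ignored; polymorphic cells count toward each state
  cells2 <- cbind(c(NA, 1L, 2L, 3L)) # ?, 0, 1, {0,1}
  m2 <- character_matrix(paste0("t", 1:4), cells2)
  expect_equal(min_steps(m2), 1)
  expect_equal(max_steps(m2), 1) # 3 scored - max count 2 (state 0 or 1)
  # inactive characters contribute nothing
  meta <- cladomorph:::default_char_meta(4)
  meta$active[2] <- FALSE
  m3 <- character_matrix(paste0("t", 1:6), cells, meta)
  expect_equal(min_steps(m3), 0 + 2 + 1)
})

test_that("M <= L <= G on random matrix/tree pairs (property)", {
  set.seed(23)
  for (r in 1:30) {
    n <- sample(4:7, 1)
    m <- random_matrix(n, sample(4:10, 1))
    nl <- cladomorph:::nl_random_tree(n)
    L <- cladomorph:::nl_score(nl, cladomorph:::score_context(m))
    expect_true(min_steps(m) <= L + 1e-9)
    expect_true(L <= max_steps(m) + 1e-9)
  }
})

test_that("ensemble_indices covers the defined and degenerate cases", {
  s <- ensemble_indices(10, 10, 25)  # homoplasy-free
  expect_equal(s$CI, 1)
  expect_equal(s$RI, 1)
  s2 <- ensemble_indices(25, 10, 25) # star-tree-bad fit
  expect_equal(s2$RI, 0)
  expect_equal(s2$CI, 0.4)
  s3 <- ensemble_indices(0, 0, 0)    # all constant
  expect_true(is.na(s3$CI) && is.na(s3$RI))
  expect_match(s3$note, "constant")
  s4 <- ensemble_indices(5, 5, 5)    # G == M
  expect_equal(s4$CI, 1)
  expect_true(is.na(s4$RI))
  expect_error(ensemble_indices(3, 5, 10), "M <= L <= G")
  # rounding convention: 3 decimals alongside full precision
  s5 <- ensemble_indices(1035, round(0.568 * 1035), 2000)
  expect_equal(s5$CI_3, round(s5$CI, 3))
})

test_that("parsimony_stats supports the informative-only variant", {
  set.seed(24)
  m <- random_matrix(6, 12, p_missing = 0)
  nl <- cladomorph:::nl_random_tree(6)
  phy <- cladomorph:::nl_to_phylo(nl, m$taxa)
  s_all <- parsimony_stats(phy, m)
  s_inf <- parsimony_stats(phy, m, informative_only = TRUE)
  expect_true(s_inf$L <= s_all$L)
  expect_true(s_inf$M <= s_all$M)
})
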