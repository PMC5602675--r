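test_that("trivial step counts", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m1 <- character_matrix(list(list(0L), list(0L), list(1L), list(1L)),
                         c("A", "B", "C", "D"))
  expect_equal(char_steps(tr, m1, 1), 1L)
  m2 <- character_matrix(list(list(0L), list(0L), list(2L), list(2L)),
                         c("A", "B", "C", "D"))
  expect_equal(char_steps(tr, m2, 1), 1L)                  # unordered
  expect_equal(char_steps(tr, m2, 1, ordered = TRUE), 2L)  # additive |0-2|
  # leaf missing from matrix
  m3 <- character_matrix(list(list(0L), list(0L), list(1L)), c("A", "B", "C"))
  expect_error(char_steps(tr, m3, 1), "absent")
})

test_that("Fitch and Sankoff match brute-force assignment enumeration", {
  set.seed(11)
  for (rep in 1:12) {
    n <- 6L
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    tr$edge.length <- NULL
    states <- stats::setNames(sample(0:2, n, replace = TRUE), tr$tip.label)
    m <- character_matrix(lapply(states, function(s) list(s)), tr$tip.label)
    expect_equal(char_steps(tr, m, 1),
                 brute_force_steps(tr, states, 3L, ordered = FALSE))
    expect_equal(char_steps(tr, m, 1, ordered = TRUE),
                 brute_force_steps(tr, states, 3L, ordered = TRUE))
  }
})

test_that("scores agree with phangorn on random matrices incl. ambiguity", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  lev <- c("0", "1", "2")
  for (rep in 1:8) {
    n <- 7L
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    tr$edge.length <- NULL
    chr <- matrix(sample(lev, n * 5, replace = TRUE), n, 5,
                  dimnames = list(tr$tip.label, NULL))
    chr[sample(length(chr), 4)] <- "?"
    cells <- lapply(seq_len(n), function(i) lapply(seq_len(5), function(j)
      if (chr[i, j] == "?") NA else as.integer(chr[i, j])))
    m <- character_matrix(cells, tr$tip.label)
    m$state_count <- rep(3L, 5)   # align the state space with phangorn levels
    pd <- phangorn::phyDat(chr, type = "USER", levels = lev, ambiguity = "?")
    expect_equal(sum(parsimony_steps(tr, m)),
                 as.integer(phangorn::parsimony(tr, pd)))
    cost <- abs(outer(0:2, 0:2, "-"))
    dimnames(cost) <- list(lev, lev)
    expect_equal(sum(parsimony_steps(tr, m, parsimony_settings(ordered = 1:5))),
                 as.integer(phangorn::parsimony(tr, pd, method = "sankoff", cost = cost)))
  }
})

test_that("ordered cost never undercuts unordered; length is rooting-invariant", {
  set.seed(31)
  m <- random_matrix(7, 20, k = 4L, seed = 31)
  tr <- ape::rtree(7, tip.label = paste0("t", 1:7)); tr$edge.length <- NULL
  su <- parsimony_steps(tr, m)
  so <- parsimony_steps(tr, m, parsimony_settings(ordered = 1:20))
  expect_true(all(so >= su))
  for (og in c("t2", "t5")) {
    rr <- root_on_taxon(tr, og)
    expect_equal(sum(parsimony_steps(rr, m)), sum(su))
    expect_equal(sum(parsimony_steps(rr, m, parsimony_settings(ordered = 1:20))), sum(so))
  }
})

test_that("score breakdown bounds and implied weighting arithmetic", {
  set.seed(41)
  m <- random_matrix(6, 15, k = 3L, seed = 41)
  tr <- ape::rtree(6, tip.label = paste0("t", 1:6)); tr$edge.length <- NULL
  bk <- tree_length(tr, m, parsimony_settings(K = 3))
  expect_true(all(bk$per_char_min <= bk$per_char_steps))
  expect_true(all(bk$per_char_steps <= bk$per_char_max))
  expect_equal(bk$total_length, sum(bk$per_char_steps))
  expect_equal(bk$iw_distortion,
               sum(bk$homoplasy / (bk$homoplasy + 3)))
  # D = 0 iff no homoplasy
  expect_equal(bk$iw_distortion == 0, sum(bk$homoplasy) == 0)
  # one character with h = 3 at K = 3 contributes 0.5
  expect_equal(3 / (3 + 3), 0.5)
  cm <- clean_signal_matrix(6)
  cat_tree <- ape::read.tree(text = "(((((t1,t2),t3),t4),t5),t6);")
  bk2 <- tree_length(cat_tree, cm)
  expect_equal(sum(bk2$homoplasy), 0)
  expect_equal(iw_score(cat_tree, cm, parsimony_settings(weighting = "implied", K = 3)), 0)
})

test_that("all-constant matrix scores zero on every tree", {
  m <- character_matrix(lapply(1:5, function(i) list(1L, 0L)), paste0("t", 1:5))
  for (s in 1:3) {
    tr <- ape::rtree(5, tip.label = paste0("t", 1:5)); tr$edge.length <- NULL
    expect_equal(tree_length(tr, m)$total_length, 0)
  }
})

test_that("ensemble indices: clean matrix gives CI = RI = 1; degenerate RI signals", {
  cm <- clean_signal_matrix(6)
  cat_tree <- ape::read.tree(text = "(((((t1,t2),t3),t4),t5),t6);")
  L <- tree_length(cat_tree, cm)$total_length
  ei <- ensemble_indices(L, cm)
  expect_equal(ei$CI, 1)
  expect_equal(ei$RI, 1)
  expect_error(ensemble_indices(0, cm), "positive")
  # two-taxon-variable character: m = g, no potential homoplasy anywhere
  m2 <- character_matrix(list(list(0L), list(1L), list(0L), list(0L)),
                         paste0("t", 1:4))
  expect_error(ensemble_indices(1, m2), "RI undefined")
})

test_that("fully ambiguous cells contribute nothing to the step bounds", {
  cells <- list(list(0L), list(1L), list(NA), list(NA), list(2L))
  m <- character_matrix(cells, paste0("t", 1:5))
  bk <- tree_length(ape::read.tree(text = "(((t1,t2),t3),(t4,t5));"), m)
  expect_equal(unname(bk$per_char_min), 2L)   # three states, two changes
  expect_equal(unname(bk$per_char_max), 2L)   # star bound over 3 scored taxa
})
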