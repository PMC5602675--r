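test_that("FBD simulator: rejection logic, determinism and validity", {
  expect_error(simulate_fbd_tree(sim_config(psi = 0)), "psi = 0")
  cfg <- sim_config(seed = 5, min_samples = 4, max_samples = 20)
  a <- simulate_fbd_tree(cfg)
  b <- simulate_fbd_tree(cfg)
  expect_identical(a, b)                        # fully seed-determined
  expect_true(validate_dated_tree(a))
  expect_true(a$n_tip >= 4 && a$n_tip <= 20)
  expect_true(all(a$age[seq_len(a$n_tip)] > 0))
  # every SA tip attaches at its own age (zero-length convention)
  for (i in which(a$sa)) expect_equal(a$age[i], a$age[a$parent[i]])
  # impossible parameters exhaust the rejection budget
  expect_error(simulate_fbd_tree(sim_config(psi = 1e-6, origin = 1, min_samples = 5),
                                 max_tries = 50L), "rejections")
})

test_that("FBD simulator: expected sample count tracks psi x E[tree length]", {
  lam <- 0.05; mu <- 0.03; psi <- 0.04; TT <- 30
  cfg <- sim_config(seed = 1, origin = TT, lambda = lam, mu = mu, psi = psi,
                    min_samples = 0)
  set.seed(77)
  N <- 1000L
  n_samples <- numeric(N)
  count_samples <- function(lin) {
    k <- length(lin$samples)
    if (identical(lin$fate, "split")) k <- k + count_samples(lin$left) + count_samples(lin$right)
    k
  }
  for (i in seq_len(N)) {
    lin <- mosaweak:::sim_fbd_lineage(TT, cfg)
    n_samples[i] <- count_samples(lin)
  }
  # E[n] = psi * E[total branch length]; for birth-death from the origin,
  # E[L] = (exp((lam - mu) * T) - 1) / (lam - mu)
  expected <- psi * (exp((lam - mu) * TT) - 1) / (lam - mu)
  se <- stats::sd(n_samples) / sqrt(N)
  expect_lt(abs(mean(n_samples) - expected), 3.5 * se + 0.02 * expected)
})

test_that("Mk matrix simulator: degenerate rates and one-branch transition law", {
  dt <- toy_dated_chain()
  cfg0 <- sim_config(seed = 2, n_char = 10, rate = 0, variable_only = FALSE,
                     ordered_fraction = 0)
  m0 <- simulate_mk_matrix(dt, cfg0)
  expect_true(all(apply(m0$mask, 2, function(x) length(unique(x))) == 1))
  expect_error(simulate_mk_matrix(dt, sim_config(seed = 2, n_char = 3, rate = 0,
                                                 variable_only = TRUE,
                                                 ordered_fraction = 0)),
               "variable")
  # single long branch: empirical transitions match the analytic symmetric chain
  dt2 <- dated_tree(parent = c(3L, 3L, 0L), age = c(1, 1, 11), labels = c("a", "b"))
  cfg2 <- sim_config(seed = 9, n_char = 4000, rate = 0.05, gamma_shape = 1e9,
                     state_counts = 2L, state_probs = 1, ordered_fraction = 0,
                     variable_only = FALSE)
  m2 <- simulate_mk_matrix(dt2, cfg2)
  # both branches have duration 10, so nu = 0.5 each; P(tips differ) =
  # sum_s pi_s P_s0 P_s1 * 2 = (1/2)(1 - exp(-2 * 1.0))... via the 2-tip form
  p_diff_theory <- (1 / 2) * (1 - exp(-2 * (0.5 + 0.5)))
  p_diff_hat <- mean(m2$mask[1, ] != m2$mask[2, ])
  se <- sqrt(p_diff_theory * (1 - p_diff_theory) / cfg2$n_char)
  expect_lt(abs(p_diff_hat - p_diff_theory), 4 * se)
})

test_that("homoplasy on the true tree rises with the evolutionary rate", {
  cfg <- sim_config(seed = 31, min_samples = 8, max_samples = 12)
  dt <- simulate_fbd_tree(cfg)
  phy <- dated_to_phylo(dt)
  rates <- seq(0.005, 0.2, length.out = 12)
  hom <- vapply(seq_along(rates), function(i) {
    m <- simulate_mk_matrix(dt, sim_config(seed = 100 + i, n_char = 40, rate = rates[i],
                                           ordered_fraction = 0, variable_only = FALSE))
    sum(tree_length(phy, m)$homoplasy)
  }, 1)
  expect_gt(stats::cor(rates, hom, method = "spearman"), 0.8)
})

test_that("weak-spot fixture is deterministic and matches its design", {
  f1 <- make_weakspot_fixture(4)
  f2 <- make_weakspot_fixture(4)
  expect_identical(f1$matrix$mask, f2$matrix$mask)
  expect_identical(f1$ordered, f2$ordered)
  f3 <- make_weakspot_fixture(5)
  expect_false(identical(f1$matrix$mask, f3$matrix$mask))  # permutation moved
  expect_length(f1$ordered, 3L)
  expect_equal(vapply(f1$definitions, `[[`, "", "name"), c("Fragilia", "Stabilia"))
})

test_that("fixture statuses across all eight parsimony regimes", {
  fx <- make_weakspot_fixture(1)
  m <- fx$matrix
  cfg <- search_config(n_replicates = 2L, seed = 2, root = "OUT1")
  regimes <- list()
  for (ord in c(FALSE, TRUE)) {
    regimes[[length(regimes) + 1L]] <-
      list(ord = ord, s = parsimony_settings(ordered = if (ord) fx$ordered else integer(0)))
    for (K in c(3, 6, 9))
      regimes[[length(regimes) + 1L]] <-
        list(ord = ord, s = parsimony_settings(ordered = if (ord) fx$ordered else integer(0),
                                               weighting = "implied", K = K))
  }
  for (rg in regimes) {
    ts <- search_battery(m, rg$s, cfg)
    cons <- strict_consensus(ts, "OUT1")
    frag <- evaluate_definition(fx$definitions[[1]], cons)$status
    stab <- evaluate_definition(fx$definitions[[2]], cons)$status
    expect_equal(frag, if (rg$ord) "SELF_DESTRUCTS" else "APPLIES",
                 info = paste("ordered =", rg$ord))
    expect_equal(stab, "APPLIES", info = paste("ordered =", rg$ord))
  }
})
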