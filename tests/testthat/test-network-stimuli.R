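# Network construction statistics and stimulus generation.

test_that("spaces have the 4:1 ratio and tabulated wiring statistics", {
  p <- model_params()
  net <- build_network(1, neural_spaces = character(0), params = p)
  expect_equal(net$pops$C_I$n, p$n_content / 4)
  binom_ok <- function(n_edges, n_pairs, prob) {
    abs(n_edges - n_pairs * prob) < 4 * sqrt(n_pairs * prob * (1 - prob))
  }
  nE <- p$n_content; nI <- nE / 4
  expect_true(binom_ok(length(net$groups$C_EE$pre), nE * (nE - 1), 0.1))
  expect_true(binom_ok(length(net$groups$C_EI$pre), nE * nI, 0.575))
  expect_true(binom_ok(length(net$groups$C_IE$pre), nI * nE, 0.6))
  expect_true(binom_ok(length(net$groups$C_II$pre), nI * (nI - 1), 0.55))
  # static weights and delays exactly as tabulated
  expect_true(all(net$groups$C_EI$w == 17.39))
  expect_true(all(net$groups$C_IE$w == -4.76))
  expect_true(all(net$groups$C_II$w == -16.67))
  expect_true(all(net$groups$C_EI$delay_ms == 0.5))
  # no self-connections in recurrent groups
  expect_false(any(net$groups$C_EE$pre == net$groups$C_EE$post))
  expect_false(any(net$groups$C_II$pre == net$groups$C_II$post))
  expect_error(build_space(net, "bad", 10, FALSE, p, 1), "divisible")
})

test_that("input projection is all-to-all; between-space wiring is sparse", {
  p <- model_params()
  net <- build_network(2, neural_spaces = "S1", params = p)
  expect_equal(length(net$groups$X_C$pre), p$n_in * p$n_content)
  exp_edges <- p$n_content * p$n_neural * 0.1
  expect_lt(abs(length(net$groups$C_S1$pre) - exp_edges),
            4 * sqrt(exp_edges * 0.9))
  # delays uniform within tabulated bounds; init weights within bounds
  expect_true(all(net$groups$C_S1$delay_ms >= 1 & net$groups$C_S1$delay_ms <= 10))
  expect_true(all(net$groups$C_S1$w >= 0.48 & net$groups$C_S1$w <= 0.86))
  expect_true(all(net$groups$X_C$w >= 0 & net$groups$X_C$w <= 0.8))
  # wiring is direction-asymmetric: feedback is an independent draw
  expect_false(length(net$groups$S1_C$pre) == length(net$groups$C_S1$pre))
})

test_that("neuron roles carry the right bias and excitability parameters", {
  net <- build_network(3, neural_spaces = "S1")
  expect_equal(net$pops$C_E$I_e, 0.2)
  expect_equal(net$pops$C_I$I_e, 0)
  expect_equal(net$pops$C_E$q_sfa, 0)   # excitability traces only in S
  expect_equal(net$pops$S1_E$q_sfa, 0.02)
  expect_equal(net$pops$S1_E$b_max, 0.5)
  expect_equal(net$pops$S1_I$q_sfa, 0)
})

test_that("wiring seeds are modular: adding a space preserves the content space", {
  a <- build_network(5, neural_spaces = character(0))
  b <- build_network(5, neural_spaces = "S1")
  expect_identical(a$groups$C_EE$pre, b$groups$C_EE$pre)
  expect_identical(a$groups$C_EE$w, b$groups$C_EE$w)
  expect_identical(a$groups$X_C$w, b$groups$X_C$w)
  # different neural seed changes only the neural-space realization
  c1 <- build_network(5, neural_spaces = "S1", neural_seed = 99)
  expect_identical(c1$groups$C_EE$w, b$groups$C_EE$w)
  expect_false(identical(c1$groups$C_S1$pre, b$groups$C_S1$pre))
})

test_that("pattern sets are disjoint up to capacity and overlap beyond", {
  p <- model_params()
  ps5 <- make_patterns(5, p, 1)
  sets <- lapply(ps5$patterns, `[[`, "active")
  expect_true(all(lengths(sets) == 25))
  expect_equal(length(unique(unlist(sets))), 125) # pairwise disjoint
  ps8 <- make_patterns(8, p, 1)
  expect_equal(sort(unlist(lapply(ps8$patterns, `[[`, "active"))), 1:200)
  ps30 <- make_patterns(30, p, 1)
  expect_true(all(lengths(lapply(ps30$patterns, `[[`, "active")) == 25))
  expect_gt(max(table(unlist(lapply(ps30$patterns, `[[`, "active")))), 1)
})

test_that("pattern and idle rate vectors keep the population input rate level", {
  p <- model_params()
  ps <- make_patterns(5, p, 1)
  r <- pattern_rates(ps, 1)
  expect_equal(sum(r), 25 * 100 + 175 * 0.1)
  idle <- pattern_rates(ps, "idle")
  expect_equal(sum(idle), 200 * 12.5)
  expect_equal(sum(r), sum(idle), tolerance = 0.01)
})

test_that("poisson realization matches its law and handles zero duration", {
  expect_equal(nrow(realize_poisson(c(100, 50), 0)), 0)
  sp <- realize_poisson(rep(100, 20), 10000, seed = 3)
  counts <- table(factor(sp$neuron, levels = 1:20))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 20))
  # background neuron at 0.1 Hz over 200 ms: usually no spike
  n0 <- vapply(1:200, function(s)
    nrow(realize_poisson(0.1, 200, seed = s)), 1L)
  expect_gt(mean(n0 == 0), 0.9) # P(0) ~ 0.98
})

test_that("pattern sets round-trip through their text serialization", {
  ps <- make_patterns(4, model_params(), 7)
  f <- tempfile(fileext = ".tsv")
  write_patterns(ps, f)
  back <- read_patterns(f)
  expect_equal(lapply(back$patterns, `[[`, "active"),
               lapply(ps$patterns, `[[`, "active"))
  expect_equal(back$idle_rate, ps$idle_rate)
  unlink(f)
})
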