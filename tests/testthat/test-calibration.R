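# Gradient-free parameter search and the robustness perturbation harness.

test_that("the optimized parameter set has 23 entries and 20 are perturbed", {
  specs <- param_specs()
  expect_length(specs, 23)
  expect_length(robustness_param_names(), 20)
  expect_false(any(grepl("alpha", robustness_param_names())))
  for (s in specs) expect_lt(s$lower, s$upper)
  # round trip through apply_param_vector
  p <- model_params()
  x <- vapply(specs, `[[`, 1.0, "value")
  p2 <- apply_param_vector(p, specs, x * 0 + 1)
  expect_equal(p2$plastic$EE_S$eta, 1)
})

test_that("latin hypercube initialization stratifies and returns the argmin", {
  spec1 <- list(param_spec("EE_C", "eta", 0.5, 0, 1))
  ev <- function(x) (x - 0.37)^2
  out <- lhs_init(spec1, n = 20, evaluator = function(x) ev(x[1]), seed = 4)
  # one sample in each of 20 equal strata
  expect_equal(sort(floor(out$X[, 1] * 20)), 0:19)
  expect_equal(out$cost, min(out$costs))
  # the winner lies in the stratum containing the optimum most of the time
  hits <- vapply(1:20, function(s) {
    o <- lhs_init(spec1, n = 20, evaluator = function(x) ev(x[1]), seed = s)
    abs(o$x - 0.37) < 1 / 20
  }, TRUE)
  expect_gt(mean(hits), 0.8)
  # constant evaluator: ties broken by first index
  oc <- lhs_init(spec1, n = 5, evaluator = function(x) 1, seed = 1)
  expect_equal(oc$x, oc$X[1, ])
})

test_that("hill climbing accepts only strict improvements and converges", {
  specs <- list(param_spec("EE_C", "eta", 0.5, 0, 1),
                param_spec("EE_C", "A_minus", 0.5, 0, 1))
  ev <- function(x) sum((x - c(0.3, 0.7))^2)
  out <- hillclimb(c(0.9, 0.1), specs, ev, n_iter = 300, seed = 5)
  acc <- out$trace$cost[out$trace$accepted]
  expect_true(all(diff(acc) < 0))
  expect_lt(out$cost, ev(c(0.9, 0.1)))
  # recovery of a known optimum within 1% of the range in most seeds
  hit <- vapply(1:10, function(s) {
    o <- hillclimb(c(0.9, 0.1), specs, ev, n_iter = 500, seed = s)
    all(abs(o$x - c(0.3, 0.7)) < 0.01)
  }, TRUE)
  expect_gte(mean(hit), 0.9)
  # an evaluator already at its optimum never moves
  o0 <- hillclimb(c(0.3, 0.7), specs, function(x) 0, n_iter = 50, seed = 1)
  expect_equal(o0$x, c(0.3, 0.7))
  # early stopping returns the holdout argmin among visited sets
  oh <- hillclimb(c(0.9, 0.1), specs, ev, n_iter = 100, seed = 2,
                  holdout_evaluator = function(x) sum((x - c(0.5, 0.5))^2))
  expect_true(!is.null(oh$x_early))
  expect_lte(min(oh$holdout_costs),
             sum((c(0.9, 0.1) - c(0.5, 0.5))^2) + 1e-12)
})

test_that("perturbation scales with sigma and applies the clipping rules", {
  p <- model_params()
  expect_equal(perturb_params(p, 0, seed = 1), p) # sigma 0: unchanged
  draws <- vapply(1:3000, function(s)
    perturb_params(p, 0.2, seed = s)$plastic$EE_S$tau_plus, 1.0)
  v <- p$plastic$EE_S$tau_plus
  expect_lt(abs(sd(draws) - 0.2 * v) / (0.2 * v), 0.1)
  expect_lt(abs(mean(draws) - v) / v, 0.05)
  # time constants never negative even at huge sigma
  taus <- vapply(1:200, function(s)
    perturb_params(p, 3, seed = s)$plastic$EE_C$tau_minus, 1.0)
  expect_true(all(taus >= 0))
  # weight-init interval stays valid
  ok <- vapply(1:200, function(s) {
    pp <- perturb_params(p, 1, seed = s)
    all(vapply(pp$plastic, function(r) r$w_init_hi >= r$w_init_lo, TRUE))
  }, TRUE)
  expect_true(all(ok))
  # alphas never touched
  pa <- perturb_params(p, 0.5, seed = 9)
  expect_equal(pa$plastic$EE_S$alpha, p$plastic$EE_S$alpha)
})

test_that("the shipped connection tables load and validate", {
  p <- load_connection_config()
  expect_equal(p$static$EI$w, 17.39)
  expect_equal(p$plastic$EE_S$A_minus, 0.52)
  expect_equal(p$plastic$X_C$p, 1)
  expect_equal(p$readout$tm$tau_rec, 700)
  # incomplete configs are rejected
  bad <- tempfile(fileext = ".yaml")
  cfg <- yaml::read_yaml(system.file("extdata", "connection_params.yaml",
                                     package = "apnet"))
  cfg$plastic$EE_S$eta <- NULL
  yaml::write_yaml(cfg, bad)
  expect_error(load_connection_config(bad), "incomplete")
  unlink(bad)
})
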