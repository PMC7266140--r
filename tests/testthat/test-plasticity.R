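# STDP rule, pairing bookkeeping, gating, and short-term depression.

test_that("stdp_delta matches hand-evaluated values of the update rule", {
  ee <- model_params()$plastic$EE_C # eta 0.0025, A- 0.5, tau+ 25
  expect_equal(stdp_delta(0, ee), 0.0025 * 0.5) # dt = 0 uses first branch
  expect_equal(stdp_delta(25, ee), 0.0025 * (exp(-1) - 0.5))
  # dt -> +inf: pure offset depression
  expect_equal(stdp_delta(1e6, ee), -0.0025 * 0.5)
  # dt < 0 branch carries alpha and tau_minus
  expect_equal(stdp_delta(-40, ee), 0.0025 * (-1) * (exp(-1) - 0.5))
  # groups without a depression branch ignore post-before-pre pairings
  xc <- model_params()$plastic$X_C
  expect_equal(stdp_delta(-5, xc), 0)
  expect_error(stdp_delta(Inf, ee))
})

test_that("no spikes leave apply_pairings untouched; one pairing accumulates", {
  g <- toy_group()
  none <- data.frame(neuron = integer(0), time_ms = numeric(0))
  expect_equal(apply_pairings(none, none, g)$w, g$w)
  # single pre at 10 ms, single post at 10 ms: dt = 0 pairing on edges of pre 1
  pre <- data.frame(neuron = 1L, time_ms = 10)
  post <- data.frame(neuron = 1L, time_ms = 10)
  out <- apply_pairings(pre, post, g)
  expect_equal(out$w[1], g$w[1] + g$eta * (1 - g$A_minus))
  expect_equal(out$w[2:3], g$w[2:3]) # other edges' posts silent
})

test_that("engine plasticity equals the brute-force pairing oracle", {
  # two Poisson populations joined by a plastic group; the engine's
  # incremental bookkeeping must reproduce the quadratic reference
  p <- model_params()
  net <- structure(list(params = p, dt = 0.1, seed = 1, input_pop = 1L,
                        spaces = list(), groups = list(), pops = list()),
                   class = "apnet")
  net$pops$A <- pop_template("A", 1L, 2L, 0L)
  net$pops$B <- pop_template("B", 1L, 2L, 0L)
  for (alpha in c(0, -1)) {
    g <- toy_group(alpha = alpha, w0 = 0.5)
    g$pre_pop <- 1L; g$post_pop <- 2L
    net$groups <- list(toy = g)
    ph <- sim_phase(net, 2000, record = TRUE)
    ph$rates[[1]] <- rep(40, 2)
    ph$rates[[2]] <- rep(25, 2)
    run <- run_network(net, list(ph), seed = 77 + alpha)
    pre_sp <- run$spikes[run$spikes$pop == "A", c("neuron", "time_ms")]
    post_sp <- run$spikes[run$spikes$pop == "B", c("neuron", "time_ms")]
    expect_gt(nrow(pre_sp), 50)
    oracle <- apply_pairings(pre_sp, post_sp, g)
    # tolerance admits float jitter of a single window-boundary pairing
    expect_equal(run$net$groups$toy$w, oracle$w, tolerance = 1e-7)
  }
})

test_that("weights stay inside their clipping bounds through a plastic run", {
  p <- tiny_params()
  ps <- make_patterns(2, p, 1)
  net <- tiny_net(seed = 2, params = p)
  phases <- list(sim_phase(net, 300, input = pattern_rates(ps, 1)),
                 sim_phase(net, 300, input = pattern_rates(ps, 2)))
  run <- run_network(net, phases, seed = 5)
  for (g in run$net$groups) {
    if (!isTRUE(g$plastic)) next
    expect_gte(min(g$w), g$w_min)
    expect_lte(max(g$w), g$w_max)
  }
})

test_that("plasticity gates follow disinhibition and freezing", {
  net <- tiny_net(seed = 4, neural = c("S1", "S2"))
  # default: neural spaces locked -> only content-space groups open
  gs <- gate_states(net)
  expect_true(gs[["C_EE"]] && gs[["X_C"]])
  expect_false(any(gs[c("S1_EE", "C_S1", "S1_C", "S2_EE", "C_S2", "S2_C")]))
  # disinhibiting S1 opens exactly the groups touching S1
  gs1 <- gate_states(net, inhibited = c(C = FALSE, S1 = FALSE, S2 = TRUE))
  expect_true(all(gs1[c("S1_EE", "C_S1", "S1_C")]))
  expect_false(any(gs1[c("S2_EE", "C_S2", "S2_C")]))
  # content-space lock does not gate plasticity; freezing does
  gs2 <- gate_states(net, inhibited = c(C = TRUE, S1 = FALSE, S2 = TRUE))
  expect_true(gs2[["C_EE"]])
  netf <- freeze_content_plasticity(net)
  expect_false(any(gate_states(netf)[c("C_EE", "X_C")]))
})

test_that("gate closure leaves weights bit-identical through a run", {
  net <- tiny_net(seed = 6, neural = "S1") # S1 locked by default
  ps <- make_patterns(2, tiny_params(), 1)
  net <- freeze_content_plasticity(net)
  w_before <- lapply(net$groups, `[[`, "w")
  run <- run_network(net, list(sim_phase(net, 400,
    input = pattern_rates(ps, 1))), seed = 8)
  expect_identical(lapply(run$net$groups, `[[`, "w"), w_before)
})

test_that("short-term depression recursion matches its closed form", {
  tm <- tm_params(U = 0.25, tau_rec = 700, tau_fac = 20)
  expect_equal(tm_efficacy(5, tm), 0.25) # isolated first spike: U * 1
  # two spikes far apart recover fully (facilitation also decayed)
  e2 <- tm_efficacy(c(0, 1e6), tm)
  expect_equal(e2[1], e2[2], tolerance = 1e-9)
  # sustained 100 Hz drive: strictly decreasing toward the fixed point
  eff <- tm_efficacy(seq(0, by = 10, length.out = 200), tm)
  expect_lt(eff[200], eff[2])
  expect_equal(eff[200], tm_steady_state(10, tm), tolerance = 1e-6)
  expect_error(tm_efficacy(c(3, 2), tm), "increasing")
})
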