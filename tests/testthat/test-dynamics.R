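# Closed-form pieces of the neuron model and engine-level dynamics.

test_that("instantaneous rate follows the hazard expression and clips at zero", {
  exc <- neuron_params() # c1 = 0, c2 = 1000, c3 = 1
  inh <- neuron_params(c1 = 10, c2 = 0, c3 = 0, I_e = 0)
  expect_equal(instantaneous_rate(0, exc), 0)
  expect_equal(instantaneous_rate(2, inh), 20)
  expect_equal(instantaneous_rate(1, exc), 1000 * (exp(1) - 1))
  # hyperpolarized potentials would give a negative expression: clipped
  expect_equal(instantaneous_rate(-1.9, exc), 0)
  expect_equal(instantaneous_rate(-3, inh), 0)
  expect_error(instantaneous_rate(NaN, exc), "non-finite")
})

test_that("membrane step has the exact exponential-Euler fixed points", {
  exc <- neuron_params() # R_m = 0.5, I_e = 0.2
  # repeated stepping converges to R_m * I_e with no synaptic input
  V <- 0
  for (i in 1:2000) V <- membrane_step(V, 0, 0, exc, dt = 0.1)
  expect_equal(V, 0.5 * 0.2, tolerance = 1e-8)
  # inhibitory lock: fixed point R_m * (I_e + I_inh) = 0.5 * (0.2 - 4)
  V <- 0
  for (i in 1:2000) V <- membrane_step(V, 0, -4, exc, dt = 0.1)
  expect_equal(V, -1.9, tolerance = 1e-8)
  # the locked fixed point yields zero excitatory hazard
  expect_equal(instantaneous_rate(V, exc), 0)
  # dt -> 0 leaves V unchanged to first order
  expect_equal(membrane_step(1, 0, 0, exc, dt = 1e-7), 1, tolerance = 1e-6)
  # refractory neurons hold the reset value
  expect_equal(membrane_step(c(1, 1), 5, 0, exc, dt = 0.1,
                             refractory = c(TRUE, FALSE))[1], 0)
})

test_that("spike sampling follows the exact per-step probability law", {
  expect_equal(spike_probability(0), 0)
  expect_equal(spike_probability(100, dt = 0.1), 1 - exp(-0.01))
  # never exceeds 1 even at absurd rates
  expect_lt(spike_probability(1e9, dt = 0.1), 1 + 1e-12)
  # Monte-Carlo: constant 100 Hz hazard over 10 s within 3 SE of Poisson
  st <- list(V = rep(log(1.1), 1000), b_sfa = numeric(1000),
             refr_rem = numeric(1000), refr_dur = rep(1, 1000))
  p100 <- neuron_params(c1 = 0, c2 = 1000, c3 = 1, q_sfa = 0)
  # V chosen so 1000*(e^V - 1) = 100 Hz; no reset effects: count one step
  nspk <- 0
  nstep <- 1000
  with_local_seed(42, for (i in seq_len(nstep)) {
    out <- sample_spikes(st, p100, dt = 0.1)
    nspk <- nspk + sum(out$spiked)
  })
  # each draw is over 1000 fresh-state neurons; expected p per draw
  p <- spike_probability(100, 0.1)
  expect_lt(abs(nspk - nstep * 1000 * p) / sqrt(nstep * 1000 * p), 4)
})

test_that("excitability bias accumulates per spike and is capped", {
  p <- neuron_params(q_sfa = 0.02, tau_sfa = 5, b_sfa_max = 0.5)
  st <- list(V = 10, b_sfa = 0, refr_rem = 0, refr_dur = 0.1)
  b <- c()
  with_local_seed(1, for (i in 1:20) {
    out <- sample_spikes(st, p, dt = 0.1)
    st <- out$state
    st$refr_rem <- 0 # force availability; decay negligible over 2 ms
    b <- c(b, st$b_sfa)
  })
  nspikes <- sum(diff(c(0, b)) > 1e-9)
  expect_equal(tail(b, 1), min(nspikes * 0.02, 0.5), tolerance = 1e-6)
  # a long spike train saturates exactly at the cap
  for (i in 1:100) {
    out <- sample_spikes(st, p, dt = 0.1); st <- out$state; st$refr_rem <- 0
  }
  expect_lte(st$b_sfa, 0.5 + 1e-12)
})

test_that("engine runs are deterministic and respect locks and zero duration", {
  net <- tiny_net(seed = 3)
  ps <- make_patterns(2, tiny_params(), 1)
  r1 <- run_network(net, list(sim_phase(net, 150, record = TRUE)), seed = 11)
  r2 <- run_network(net, list(sim_phase(net, 150, record = TRUE)), seed = 11)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$net$groups$C_EE$w, r2$net$groups$C_EE$w)
  # different seed gives a different realization
  r3 <- run_network(net, list(sim_phase(net, 150, record = TRUE)), seed = 12)
  expect_false(identical(r1$spikes, r3$spikes))
  # zero-duration run: no events, weights unchanged
  r0 <- run_network(net, list(sim_phase(net, 0, record = TRUE)), seed = 11)
  expect_equal(nrow(r0$spikes), 0)
  expect_identical(r0$net$groups$C_EE$w, net$groups$C_EE$w)
  # fully locked network is silent in the excitatory pools
  netl <- set_inhibition(net, "C", TRUE)
  rl <- run_network(netl, list(sim_phase(netl, 500,
    input = pattern_rates(ps, "idle"))), seed = 13)
  expect_equal(sum(rl$counts$C_E), 0)
})

test_that("refractory durations are sampled once and held fixed", {
  net <- tiny_net(seed = 5)
  before <- net$pops$C_E$refr_dur
  run <- run_network(net, list(sim_phase(net, 200)), seed = 1)
  expect_identical(run$net$pops$C_E$refr_dur, before)
  # gamma parameterization: shape 4, scale 3.5 -> mean 14 ms
  p <- model_params()
  big <- with_local_seed(9, stats::rgamma(2e4, shape = 4, scale = 3.5))
  expect_equal(mean(big), 14, tolerance = 0.05)
  netm <- build_network(1, neural_spaces = character(0),
                        params = model_params(refr_mode = "mean"))
  expect_equal(mean(netm$pops$C_E$refr_dur), 3.5, tolerance = 0.5)
})

test_that("poisson input neurons realize their programmed rates", {
  net <- tiny_net(seed = 7)
  rates <- rep(c(100, 0), length.out = net$pops$X$n)
  run <- run_network(net, list(sim_phase(net, 10000, input = rates)), seed = 21)
  counts <- run$counts$X[, 1]
  on <- which(rates == 100)
  expect_equal(sum(counts[rates == 0]), 0)
  # 3 SE band around 1000 expected spikes per active neuron
  expect_lt(abs(mean(counts[on]) - 1000), 3 * sqrt(1000 / length(on)))
})
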