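# Shared fixtures: tiny parameter sets and networks built once per test run.

tiny_params <- function(...) {
  p <- model_params()
  p$n_content <- 200
  p$n_in <- 50
  p$n_neural <- 400
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

tiny_net <- function(seed = 1, neural = character(0), params = tiny_params()) {
  build_network(seed, neural_spaces = neural, params = params)
}

# a toy 3-edge plastic group for plasticity oracle tests
toy_group <- function(eta = 0.01, alpha = -1, tau_plus = 20, tau_minus = 30,
                      A_minus = 0.4, w0 = 0.5, w_min = -1e6, w_max = 1e6) {
  list(name = "toy", kind = 1L, pre_pop = 1L, post_pop = 2L, w_unit = 1,
       pre = c(1L, 1L, 2L), post = c(1L, 2L, 2L),
       w = rep(w0, 3), delay_ms = rep(1, 3),
       plastic = TRUE, frozen = FALSE,
       eta = eta, alpha = alpha, tau_plus = tau_plus, tau_minus = tau_minus,
       A_minus = A_minus, w_min = w_min, w_max = w_max)
}

# random spike trains on the 0.1 ms grid
random_trains <- function(n_neurons, rate_hz, duration_ms, seed, dt = 0.1) {
  with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_neurons), function(i) {
      nstep <- round(duration_ms / dt)
      hit <- which(stats::runif(nstep) < rate_hz * dt / 1000)
      if (!length(hit)) return(NULL)
      data.frame(neuron = i, time_ms = hit * dt - dt)
    }))
  })
}
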