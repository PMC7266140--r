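# Dynamics: closed-form pieces of the neuron model (exposed for testing and
# documentation) and the phase-based wrapper around the compiled engine.

#' Instantaneous firing rate (hazard) of the stochastic neuron
#'
#' \eqn{\rho(V') = \max(0,\; c_1 V' + c_2 (e^{c_3 V'} - 1))}.  The expression
#' can turn negative for strongly hyperpolarized effective potentials; since
#' it is a hazard, negative values are clipped to zero.
#'
#' @param V_eff effective membrane potential in mV (vectorized).
#' @param params a [neuron_params()] object.
#' @return firing rate(s) in Hz.
#' @export
instantaneous_rate <- function(V_eff, params) {
  if (any(!is.finite(V_eff))) stop("non-finite effective potential")
  pmax(0, params$c1 * V_eff + params$c2 * (exp(params$c3 * V_eff) - 1))
}

#' One exact integration step of the membrane potential
#'
#' \eqn{V \leftarrow e^{-\Delta t/\tau_m} V + (1 - e^{-\Delta t/\tau_m})
#' R_m (I_{syn} + I_{inh} + I_e)}.  Refractory neurons hold \eqn{V = 0}
#' (the post-spike reset value) until their refractory clock expires.
#'
#' @param V membrane potential vector (mV).
#' @param I_syn,I_inh synaptic and lock currents (nA), recycled as needed.
#' @param params a [neuron_params()] object.
#' @param dt time step in ms.
#' @param refractory logical vector: which neurons are refractory.
#' @return updated potential vector.
#' @export
membrane_step <- function(V, I_syn = 0, I_inh = 0, params, dt = 0.1,
                          refractory = FALSE) {
  stopifnot(dt > 0)
  d <- exp(-dt / params$tau_m)
  out <- d * V + (1 - d) * params$R_m * (I_syn + I_inh + params$I_e)
  out[rep_len(refractory, length(out))] <- 0
  out
}

#' Per-step spike probability for a hazard constant within the step
#'
#' Uses the exact \eqn{p = 1 - e^{-\rho \Delta t}} rather than the linearized
#' \eqn{\rho \Delta t}, which would exceed 1 at high rates.
#'
#' @param rate hazard in Hz.
#' @param dt step in ms.
#' @export
spike_probability <- function(rate, dt = 0.1) {
  1 - exp(-pmax(rate, 0) * dt / 1000)
}

#' Sample spikes for one population step (reference implementation)
#'
#' Mirrors the engine's update for a single population without synapses:
#' non-refractory neurons spike independently with probability
#' `spike_probability(rate, dt)`; spiking neurons are reset to 0 mV, their
#' refractory clock restarts, and their excitability bias increments by
#' `q_sfa` (clipped at `b_sfa_max`).
#'
#' @param state list with `V`, `b_sfa`, `refr_rem`, `refr_dur`.
#' @param params a [neuron_params()] object.
#' @param dt step in ms.
#' @return list with updated `state` and logical `spiked`.
#' @export
sample_spikes <- function(state, params, dt = 0.1) {
  free <- state$refr_rem <= 0
  rho <- instantaneous_rate(state$V + state$b_sfa, params)
  p <- spike_probability(rho, dt)
  spiked <- free & (stats::runif(length(state$V)) < p)
  state$V[spiked] <- 0
  state$refr_rem[!free] <- state$refr_rem[!free] - dt
  state$refr_rem[spiked] <- state$refr_dur[spiked]
  state$b_sfa[spiked] <- pmin(state$b_sfa[spiked] + params$q_sfa,
                              params$b_sfa_max)
  list(state = state, spiked = spiked)
}

#' Construct one simulation phase
#'
#' A phase is a stretch of simulated time with a constant disinhibition
#' pattern and constant input rates.  Space inhibition defaults to each
#' space's stored state; `open` / `close` override it for this phase only.
#'
#' @param net an `apnet` network.
#' @param duration_ms phase duration.
#' @param input per-input-neuron rate vector in Hz, a single number applied
#'   to all input neurons, or `NULL` for silent input.
#' @param open,close character vectors of space names forced disinhibited /
#'   locked during the phase.
#' @param record logical: record spike events during this phase.
#' @param label optional phase label carried into the result table.
#' @export
sim_phase <- function(net, duration_ms, input = NULL, open = character(),
                      close = character(), record = FALSE, label = "") {
  sp_names <- names(net$spaces)
  bad <- setdiff(c(open, close), sp_names)
  if (length(bad)) stop("unknown space(s): ", paste(bad, collapse = ", "))
  inhibited <- vapply(net$spaces, function(s) s$inhibited, TRUE)
  inhibited[match(open, sp_names)] <- FALSE
  inhibited[match(close, sp_names)] <- TRUE
  rates <- vector("list", length(net$pops))
  if (!is.null(input))
    rates[[net$input_pop]] <- rep_len(as.numeric(input), net$pops[[net$input_pop]]$n)
  list(duration_ms = duration_ms, inhibited = unname(inhibited),
       rates = rates, record = record, label = label)
}

#' Run the network through a sequence of phases
#'
#' Executes the compiled engine for the given phases in one call (so that
#' in-flight delayed spikes and STDP pairing histories are continuous across
#' phase boundaries), then writes final weights and neuron states back into
#' the network object.
#'
#' @param net an `apnet` network.
#' @param phases list of [sim_phase()] phases.
#' @param seed integer seed for the dynamics of this run.
#' @return list with elements `net` (updated network), `spikes` (data frame
#'   `pop`, `neuron`, `time_ms` for recorded phases, with `pop` a population
#'   name), `counts` (per population: neurons x phases spike-count matrix),
#'   and `phases` (data frame of phase windows).
#' @export
run_network <- function(net, phases, seed) {
  stopifnot(inherits(net, "apnet"), length(phases) > 0)
  pops_in <- lapply(net$pops, function(p) p) # engine reads named fields
  groups_in <- net$groups
  spaces_in <- lapply(net$spaces, function(s)
    list(lock_nA = s$lock_nA, neural = s$neural, pops = s$pops))
  res <- cpp_simulate(unname(pops_in), unname(groups_in), unname(spaces_in),
                      phases, net$dt, 1.0, as.numeric(seed))
  for (i in seq_along(net$pops)) {
    st <- res$states[[i]]
    net$pops[[i]]$V <- st$V
    net$pops[[i]]$b_sfa <- st$b_sfa
    net$pops[[i]]$refr_rem <- st$refr_rem
  }
  for (i in seq_along(net$groups)) {
    net$groups[[i]]$w <- res$weights[[i]]
    if (!is.null(res$tm_state[[i]])) {
      net$groups[[i]]$tm_x <- res$tm_state[[i]]$x
      net$groups[[i]]$tm_u <- res$tm_state[[i]]$u
    }
  }
  pop_names <- vapply(net$pops, function(p) p$name, "")
  spikes <- res$spikes
  spikes$pop <- pop_names[spikes$pop]
  counts <- res$counts
  names(counts) <- pop_names
  labels <- vapply(phases, function(p) p$label %||% "", "")
  list(net = net, spikes = spikes, counts = counts,
       phases = data.frame(label = labels, start_ms = res$phase_start,
                           end_ms = res$phase_end))
}

#' Per-neuron firing rates over a phase window
#'
#' @param run a [run_network()] result.
#' @param pop population name.
#' @param phase_idx indices of phases to pool.
#' @return rates in Hz.
#' @export
phase_rates <- function(run, pop, phase_idx) {
  cts <- run$counts[[pop]][, phase_idx, drop = FALSE]
  dur <- sum(run$phases$end_ms[phase_idx] - run$phases$start_ms[phase_idx])
  rowSums(cts) / dur * 1000
}
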