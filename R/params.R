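# Model parameters: neuron model, static and plastic connection tables,
# stimulus statistics, readout configuration.

#' Neuron parameters for the stochastic point-neuron model
#'
#' The firing of a neuron is governed by an instantaneous hazard
#' \eqn{\rho(V') = c_1 V' + c_2 (e^{c_3 V'} - 1)} of its effective membrane
#' potential \eqn{V' = V + b_{sfa}}, where \eqn{b_{sfa}} is a per-neuron
#' excitability bias that increments by `q_sfa` at every spike (clipped at
#' `b_sfa_max`) and decays with time constant `tau_sfa`.  After a spike the
#' membrane potential is reset to zero and the neuron is refractory for a
#' per-neuron duration drawn once at construction from a Gamma distribution
#' with shape `refr_shape` and scale `refr_scale` (milliseconds).
#'
#' @param c1 linear rate gain in Hz/mV.
#' @param c2 exponential rate scale in Hz.
#' @param c3 inverse-voltage coefficient in 1/mV.
#' @param tau_m membrane time constant in ms.
#' @param R_m membrane resistance in MOhm.
#' @param I_e bias current in nA.
#' @param q_sfa per-spike excitability increment in mV.
#' @param tau_sfa excitability decay time constant in seconds.
#' @param b_sfa_max excitability cap in mV.
#' @param refr_shape Gamma shape of the refractory-duration distribution.
#' @param refr_scale Gamma scale of the refractory-duration distribution (ms).
#' @return a validated list of class `neuron_params`.
#' @examples
#' p <- neuron_params() # excitatory defaults
#' instantaneous_rate(1, p) # 1000 * (e - 1)
#' @export
neuron_params <- function(c1 = 0, c2 = 1000, c3 = 1, tau_m = 10, R_m = 0.5,
                          I_e = 0.2, q_sfa = 0, tau_sfa = 5, b_sfa_max = 0,
                          refr_shape = 4, refr_scale = 3.5) {
  p <- list(c1 = c1, c2 = c2, c3 = c3, tau_m = tau_m, R_m = R_m, I_e = I_e,
            q_sfa = q_sfa, tau_sfa = tau_sfa, b_sfa_max = b_sfa_max,
            refr_shape = refr_shape, refr_scale = refr_scale)
  stopifnot(all(vapply(p, is.numeric, TRUE)), all(is.finite(unlist(p))),
            tau_m > 0, tau_sfa > 0, q_sfa >= 0, b_sfa_max >= 0,
            refr_shape > 0, refr_scale > 0)
  class(p) <- "neuron_params"
  p
}

#' STDP parameters for one plastic connection type
#'
#' A pairing of a presynaptic spike (taken at its arrival at the synapse,
#' i.e. emission plus delay) and a postsynaptic spike with
#' \eqn{\Delta t = t_{post} - t_{pre}} changes the weight by
#' \eqn{\eta (e^{-|\Delta t|/\tau_+} - A_-)} for \eqn{\Delta t \ge 0} and
#' \eqn{\eta \alpha (e^{-|\Delta t|/\tau_-} - A_-)} otherwise.  Weights are
#' clipped to `[w_min, w_max]` after every update.
#'
#' @param eta learning rate in weight units.
#' @param alpha shape factor of the post-before-pre branch (0 disables it).
#' @param tau_plus,tau_minus learning-window time constants in ms
#'   (`tau_minus` may be `NA` when `alpha = 0`).
#' @param A_minus constant negative offset per counted pairing.
#' @param w_min,w_max clipping bounds in weight units.
#' @param w_init_lo,w_init_hi bounds of the uniform weight initialization.
#' @param delay_lo,delay_hi bounds of the uniform delay initialization in ms.
#' @param p connection probability.
#' @return a validated list of class `stdp_params`.
#' @export
stdp_params <- function(eta, alpha, tau_plus, tau_minus = NA, A_minus,
                        w_min = 0, w_max, w_init_lo, w_init_hi,
                        delay_lo, delay_hi = delay_lo, p = 0.1) {
  stopifnot(tau_plus > 0, is.na(tau_minus) || tau_minus > 0, w_min <= w_max,
            delay_lo <= delay_hi, p >= 0, p <= 1)
  structure(list(eta = eta, alpha = alpha, tau_plus = tau_plus,
                 tau_minus = tau_minus, A_minus = A_minus,
                 w_min = w_min, w_max = w_max,
                 w_init_lo = w_init_lo, w_init_hi = w_init_hi,
                 delay_lo = delay_lo, delay_hi = delay_hi, p = p),
            class = "stdp_params")
}

#' Short-term depression (Tsodyks-Markram) parameters
#'
#' The cited facilitating-depressing parameter set for the comparison readout
#' is not printed in the source tables; the defaults here are
#' literature-derived stand-ins for a strongly depressing cortical synapse
#' and are exposed in the configuration.
#'
#' @param U release fraction per spike.
#' @param tau_rec recovery time constant in ms.
#' @param tau_fac facilitation time constant in ms.
#' @param w static connection weight (weight units).
#' @export
tm_params <- function(U = 0.25, tau_rec = 700, tau_fac = 20, w = 50) {
  stopifnot(U > 0, U <= 1, tau_rec > 0, tau_fac > 0)
  structure(list(U = U, tau_rec = tau_rec, tau_fac = tau_fac, w = w),
            class = "tm_params")
}

#' Default model parameters
#'
#' Returns the full parameter set of the model: neuron parameters per role,
#' the static excitatory/inhibitory wiring table, the plastic-connection
#' table (one row per connection type, with the optimized values), stimulus
#' statistics and readout configuration.  All weights are in tabulated weight
#' units; one presynaptic spike through an edge of weight `w` causes an
#' instantaneous membrane-potential jump of `w_unit_mV * w` millivolts at the
#' target (delta-synapse convention).
#'
#' @param refr_mode `"scale"` interprets the Gamma refractory parameter 3.5 ms
#'   as the scale (mean 14 ms); `"mean"` as the mean (scale 0.875 ms).
#' @return a nested list of class `model_params`.
#' @export
model_params <- function(refr_mode = c("scale", "mean")) {
  refr_mode <- match.arg(refr_mode)
  refr_scale <- if (refr_mode == "scale") 3.5 else 3.5 / 4
  exc <- neuron_params(c1 = 0, c2 = 1000, c3 = 1, I_e = 0.2,
                       refr_scale = refr_scale)
  inh <- neuron_params(c1 = 10, c2 = 0, c3 = 0, I_e = 0,
                       refr_scale = refr_scale)
  # excitability traces only for excitatory neurons in neural spaces
  exc_neural <- neuron_params(c1 = 0, c2 = 1000, c3 = 1, I_e = 0.2,
                              q_sfa = 0.02, tau_sfa = 5, b_sfa_max = 0.5,
                              refr_scale = refr_scale)
  p <- list(
    dt = 0.1,            # ms
    # Delta-synapse conversion: one presynaptic spike through an edge of
    # tabulated weight w causes an instantaneous jump of w_unit * w mV at
    # the target.  The static (within-space E/I) and plastic
    # (between/recurrent excitatory) weight tables carry different
    # effective units; both scales are fixed once by calibrating the
    # network's spontaneous rates and assembly statistics to the model's
    # stated operating points (see the methods vignette).
    w_unit_static_mV = 0.022,
    w_unit_plastic_mV = 0.25,
    lock_nA = -4,        # inhibitory lock current
    n_in = 200, n_content = 1000, n_neural = 2000,
    neuron = list(exc = exc, inh = inh, exc_neural = exc_neural),
    static = list( # within-space wiring; weights static
      EI = list(p = 0.575, w = 17.39, delay = 0.5),
      IE = list(p = 0.6,   w = -4.76, delay = 0.5),
      II = list(p = 0.55,  w = -16.67, delay = 0.5)),
    plastic = list(
      X_C  = stdp_params(eta = 0.01,   alpha = 0,  tau_plus = 25,
                         A_minus = 0.4,  w_max = 0.8,
                         w_init_lo = 0,    w_init_hi = 0.8,
                         delay_lo = 1, delay_hi = 10, p = 1),
      S_C  = stdp_params(eta = 0.008,  alpha = 0,  tau_plus = 20,
                         A_minus = 0.47, w_max = 0.87,
                         w_init_lo = 0.19, w_init_hi = 0.39,
                         delay_lo = 1, delay_hi = 10, p = 0.1),
      EE_C = stdp_params(eta = 0.0025, alpha = -1, tau_plus = 25,
                         tau_minus = 40, A_minus = 0.5, w_max = 0.6,
                         w_init_lo = 0,    w_init_hi = 0,
                         delay_lo = 1, p = 0.1),
      C_S  = stdp_params(eta = 0.004,  alpha = 0,  tau_plus = 21,
                         A_minus = 0.28, w_max = 1.33,
                         w_init_lo = 0.48, w_init_hi = 0.86,
                         delay_lo = 1, delay_hi = 10, p = 0.1),
      EE_S = stdp_params(eta = 0.006,  alpha = -1, tau_plus = 37,
                         tau_minus = 49, A_minus = 0.52, w_max = 1.08,
                         w_init_lo = 0.44, w_init_hi = 0.87,
                         delay_lo = 1, p = 0.1)),
    stimulus = list(n_active = 25, rate_active = 100, rate_background = 0.1,
                    rate_idle = 12.5),
    assembly_rate_thresh = 50, # Hz, strict ">"
    similarity = list(retain = 0.8, excess = 0.2),
    readout = list(n = 50, tau_m = 20, v_rest = -60, v_thresh = -20,
                   refr = 5, p = 0.1, delay = 1, w_unit_mV = 1,
                   tm = tm_params()),
    decoder = list(lambda = 1e-3), # ridge penalty of the linear readout
    # inter-operation protocol timing: rest periods (idle input, neural
    # spaces locked) let the second-scale excitability traces decay between
    # operations, so that the trace left by the most recent operation is
    # unambiguous; the load-recall delay is part of the standard experiment
    # projections are established by `create_rounds` (default 3) passes of the 1000-ms
    # CREATE presentation per pattern; the later passes saturate the
    # bidirectional coupling between the content assembly and its projection
    protocol = list(create_rounds = 3, create_rest_ms = 15000,
                    trial_rest_ms = 20000, delay_ms = 5000)
  )
  class(p) <- "model_params"
  p
}
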