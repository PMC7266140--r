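# Plasticity rules at the level of single pairings and spike trains.  The
# compiled engine applies the same rules incrementally during simulation;
# the functions here are the closed-form / brute-force formulation used for
# analysis and as the independent cross-check in the test suite.

#' STDP weight change for a single spike pairing
#'
#' For \eqn{\Delta t = t_{post} - t_{pre}} (pre time at the synapse, i.e.
#' emission plus delay): \eqn{\eta (e^{-|\Delta t|/\tau_+} - A_-)} when
#' \eqn{\Delta t \ge 0}, and \eqn{\eta \alpha (e^{-|\Delta t|/\tau_-} - A_-)}
#' when \eqn{\Delta t < 0}.  The offset \eqn{-A_-} applies once per counted
#' pairing, so distant pairings are purely depressing.
#'
#' @param dt_pair \eqn{t_{post} - t_{pre}} in ms (vectorized).
#' @param params an [stdp_params()] object.
#' @return weight change(s), in weight units (not yet clipped).
#' @export
stdp_delta <- function(dt_pair, params) {
  stopifnot(all(is.finite(dt_pair)))
  pos <- dt_pair >= 0
  out <- numeric(length(dt_pair))
  out[pos] <- params$eta * (exp(-dt_pair[pos] / params$tau_plus) - params$A_minus)
  if (any(!pos)) {
    if (params$alpha == 0) {
      out[!pos] <- 0
    } else {
      out[!pos] <- params$eta * params$alpha *
        (exp(dt_pair[!pos] / params$tau_minus) - params$A_minus)
    }
  }
  out
}

#' Apply nearest-neighbor STDP pairings to a synapse group (brute force)
#'
#' Reference computation of the pairing scheme used by the simulation
#' engine, on spike emission times.  The \eqn{\Delta t \ge 0} branch is
#' applied once per postsynaptic spike: the exponential term accumulates
#' over every presynaptic spike inside the pairing window while the
#' constant `-A_minus` offset counts once, so each postsynaptic spike
#' compares the presynaptic activity trace (rate times `tau_plus`)
#' against `A_minus` -- potentiation above the presynaptic rate
#' `A_minus / tau_plus` kHz and active depression of edges whose
#' presynaptic partner is silent.  The \eqn{\Delta t < 0} branch is
#' applied per presynaptic spike to the most recent postsynaptic spike
#' that had no presynaptic spike within the window before it (each such
#' postsynaptic spike is claimed at most once).  Each applied update is
#' clipped to the group's bounds.
#'
#' @param pre_spikes,post_spikes data frames with `neuron` and `time_ms`
#'   (emission times).
#' @param group a synapse-group list (fields `pre`, `post`, `w`, and the
#'   STDP parameters), as stored in an `apnet` network.
#' @param pairing_window window in ms; defaults to
#'   `10 * max(tau_plus, tau_minus)`, beyond which a kernel value is below
#'   `e^-10`.
#' @return the group with updated weights.
#' @export
apply_pairings <- function(pre_spikes, post_spikes, group,
                           pairing_window = NULL) {
  if (is.null(pairing_window))
    pairing_window <- 10 * max(group$tau_plus, group$tau_minus %||% 0)
  sp <- stdp_params(eta = group$eta, alpha = group$alpha,
                    tau_plus = group$tau_plus,
                    tau_minus = group$tau_minus %||% NA,
                    A_minus = group$A_minus, w_min = group$w_min,
                    w_max = group$w_max, w_init_lo = 0, w_init_hi = 0,
                    delay_lo = 1)
  for (e in seq_along(group$pre)) {
    tp <- sort(pre_spikes$time_ms[pre_spikes$neuron == group$pre[e]])
    tq <- sort(post_spikes$time_ms[post_spikes$neuron == group$post[e]])
    if (!length(tp) && !length(tq)) next
    ev <- rbind(data.frame(t = tp, post = rep(FALSE, length(tp))),
                data.frame(t = tq, post = rep(TRUE, length(tq))))
    ev <- ev[order(ev$t, -as.integer(ev$post)), ] # post spikes first on ties
    w <- group$w[e]
    for (i in seq_len(nrow(ev))) {
      if (ev$post[i]) {
        dts <- ev$t[i] - tp[tp <= ev$t[i] & tp >= ev$t[i] - pairing_window]
        dw <- sp$eta * (sum(exp(-dts / sp$tau_plus)) - sp$A_minus)
        w <- clip(w + dw, group$w_min, group$w_max)
      } else if (sp$alpha != 0) {
        prev_post <- tq[tq < ev$t[i]]
        prev_pre <- tp[tp < ev$t[i]]
        if (length(prev_post)) {
          u <- max(prev_post)
          # the post spike must still be unpaired: no pre spike within the
          # window before it (pot pairing) and none between it and now
          # (earlier dep pairing)
          taken <- length(prev_pre) &&
            max(prev_pre) >= u - pairing_window
          if (!taken && ev$t[i] - u <= pairing_window)
            w <- clip(w + stdp_delta(u - ev$t[i], sp),
                      group$w_min, group$w_max)
        }
      }
    }
    group$w[e] <- w
  }
  group
}

#' Plasticity gate states for a given inhibition pattern
#'
#' A plastic group's gate is open iff the group is not frozen and every
#' endpoint population lying in a *neural* space belongs to a currently
#' disinhibited space.  Content-space inhibition does not gate plasticity;
#' the induction protocol instead freezes the input and content recurrent
#' groups permanently once assemblies are formed.
#'
#' @param net an `apnet` network.
#' @param inhibited named logical vector over spaces (defaults to the
#'   spaces' stored states).
#' @return named logical vector over plastic groups.
#' @export
gate_states <- function(net, inhibited = NULL) {
  if (is.null(inhibited))
    inhibited <- vapply(net$spaces, function(s) s$inhibited, TRUE)
  sp_of_pop <- integer(length(net$pops))
  for (i in seq_along(net$spaces)) sp_of_pop[net$spaces[[i]]$pops] <- i
  neural <- vapply(net$spaces, function(s) s$neural, TRUE)
  plast <- Filter(function(g) isTRUE(g$plastic), net$groups)
  out <- vapply(plast, function(g) {
    if (isTRUE(g$frozen)) return(FALSE)
    for (p in c(g$pre_pop, g$post_pop)) {
      s <- sp_of_pop[p]
      if (s > 0 && neural[s] && inhibited[s]) return(FALSE)
    }
    TRUE
  }, TRUE)
  names(out) <- vapply(plast, function(g) g$name, "")
  out
}

#' Per-spike efficacies of a short-term depressing synapse
#'
#' Two-variable release/recovery recursion (resources `x`, utilization `u`):
#' between spikes `x` recovers toward 1 with `tau_rec` and `u` decays toward
#' `U` with `tau_fac`; at a spike the efficacy is `u * x`, after which
#' `x <- x (1 - u)` and `u <- u + U (1 - u)`.  The first spike of a rested
#' synapse has efficacy `U`.
#'
#' @param spike_times strictly increasing spike times in ms.
#' @param params a [tm_params()] object.
#' @return numeric vector of per-spike efficacies.
#' @export
tm_efficacy <- function(spike_times, params) {
  if (length(spike_times) == 0) return(numeric(0))
  if (any(diff(spike_times) <= 0)) stop("spike times must be strictly increasing")
  x <- 1; u <- params$U
  eff <- numeric(length(spike_times))
  last <- NA_real_
  for (i in seq_along(spike_times)) {
    if (!is.na(last)) {
      gap <- spike_times[i] - last
      x <- 1 - (1 - x) * exp(-gap / params$tau_rec)
      u <- params$U + (u - params$U) * exp(-gap / params$tau_fac)
    }
    eff[i] <- u * x
    x <- x * (1 - u)
    u <- u + params$U * (1 - u)
    last <- spike_times[i]
  }
  eff
}

#' Steady-state efficacy of a periodically driven depressing synapse
#'
#' Closed-form fixed point of the [tm_efficacy()] recursion under regular
#' stimulation with inter-spike interval `isi_ms`.
#'
#' @param isi_ms inter-spike interval in ms.
#' @param params a [tm_params()] object.
#' @export
tm_steady_state <- function(isi_ms, params) {
  er <- exp(-isi_ms / params$tau_rec)
  ef <- exp(-isi_ms / params$tau_fac)
  u_star <- (params$U + (params$U - params$U^2) * ef / (1 - (1 - params$U) * ef))
  # fixed point of x_{n+1} = 1 - (1 - x_n (1 - u*)) er
  x_star <- (1 - er) / (1 - (1 - u_star) * er)
  u_star * x_star
}
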