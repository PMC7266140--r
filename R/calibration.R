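# Gradient-free calibration of the plasticity parameters (Latin hypercube
# initialization + decaying-proposal stochastic hill climbing against the
# assembly-match cost), and the robustness perturbation harness.

#' Assembly-match cost of a CREATE/RECALL pair
#'
#' \eqn{C = |A_C^{CREATE} \triangle A_C^{RECALL}| + \lambda
#' |A_S^{CREATE} \triangle A_S^{RECALL}|}, where \eqn{\triangle} is the
#' symmetric set difference.  Zero iff both active sets match exactly.
#'
#' @param create_C,recall_C content-space active sets.
#' @param create_S,recall_S neural-space active sets.
#' @param lambda trade-off weight of the neural-space term.
#' @return list of class `cost_value` with `cost` and the two component
#'   symmetric-difference sizes.
#' @export
assembly_cost <- function(create_C, recall_C, create_S, recall_S,
                          lambda = 1e-4) {
  sd_C <- length(setdiff(create_C, recall_C)) +
    length(setdiff(recall_C, create_C))
  sd_S <- length(setdiff(create_S, recall_S)) +
    length(setdiff(recall_S, create_S))
  structure(list(cost = sd_C + lambda * sd_S, sd_content = sd_C,
                 sd_space = sd_S, lambda = lambda),
            class = "cost_value")
}

#' Specification of one tunable plasticity parameter
#'
#' @param group plastic-connection type name (`"S_C"`, `"EE_C"`, `"C_S"`,
#'   `"EE_S"`).
#' @param field field of [stdp_params()] (`"eta"`, `"tau_plus"`, ...).
#' @param value current (tabulated) value.
#' @param lower,upper allowed range.
#' @export
param_spec <- function(group, field, value, lower, upper) {
  stopifnot(lower < upper, value >= lower, value <= upper)
  list(name = paste0(group, ".", field), group = group, field = field,
       value = value, lower = lower, upper = upper)
}

# range rule: time constants and learning rates [0.2v, 5v]; amplitudes and
# weight bounds [0, 2v]; STDP shape factors [-2, 0].
spec_bounds <- function(field, v) {
  if (field %in% c("tau_plus", "tau_minus", "eta")) c(0.2 * v, 5 * v)
  else if (field == "alpha") c(-2, 0)
  else c(0, 2 * max(v, 1e-6))
}

#' The 23 optimized plasticity parameters with their search ranges
#'
#' All marked entries of the plastic-connection table: 7 for the
#' space-to-content feedback, the depression time constant of the content
#' recurrent synapses, 7 for the content-to-space feedforward and 8 for the
#' neural-space recurrent synapses.  Ranges follow the shipped search-space
#' convention (documented in the methods vignette).
#'
#' @param params a [model_params()] object supplying the central values.
#' @return list of [param_spec()] entries.
#' @export
param_specs <- function(params = model_params()) {
  rows <- list(
    S_C  = c("w_init_lo", "w_init_hi", "w_max", "alpha", "tau_plus",
             "A_minus", "eta"),
    EE_C = "tau_minus",
    C_S  = c("w_init_lo", "w_init_hi", "w_max", "alpha", "tau_plus",
             "A_minus", "eta"),
    EE_S = c("w_init_lo", "w_init_hi", "w_max", "alpha", "tau_plus",
             "tau_minus", "A_minus", "eta"))
  out <- list()
  for (g in names(rows)) for (f in rows[[g]]) {
    v <- params$plastic[[g]][[f]]
    b <- spec_bounds(f, v)
    out[[paste0(g, ".", f)]] <- param_spec(g, f, v, b[1], b[2])
  }
  out
}

#' Names of the parameters varied in the robustness protocol
#'
#' All optimized parameters except the three STDP shape factors.
#' @param params a [model_params()] object.
#' @export
robustness_param_names <- function(params = model_params()) {
  setdiff(names(param_specs(params)),
          c("S_C.alpha", "C_S.alpha", "EE_S.alpha"))
}

#' Write a parameter vector back into a model-parameter object
#'
#' @param params a [model_params()] object.
#' @param specs list of [param_spec()]s.
#' @param x numeric vector parallel to `specs`.
#' @export
apply_param_vector <- function(params, specs, x) {
  stopifnot(length(specs) == length(x))
  for (i in seq_along(specs))
    params$plastic[[specs[[i]]$group]][[specs[[i]]$field]] <- unname(x[i])
  params
}

#' Latin-hypercube initialization of a parameter search
#'
#' Draws `n` stratified candidates over the box defined by the specs,
#' evaluates each, and returns the candidate with the lowest cost (first
#' index on ties).
#'
#' @param specs list of [param_spec()]s.
#' @param n number of candidates.
#' @param evaluator function(numeric vector) -> finite cost.
#' @param seed integer seed.
#' @return list with `x` (best vector), `cost`, and the evaluated `costs`.
#' @export
lhs_init <- function(specs, n = 230, evaluator, seed = 1) {
  k <- length(specs)
  lo <- vapply(specs, `[[`, 1.0, "lower")
  hi <- vapply(specs, `[[`, 1.0, "upper")
  u <- with_local_seed(derive_seed(seed, "lhs"), lhs::randomLHS(n, k))
  X <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  costs <- apply(X, 1, evaluator)
  if (any(!is.finite(costs))) stop("evaluator returned a non-finite cost")
  best <- which.min(costs)
  list(x = X[best, ], cost = costs[best], costs = costs, X = X)
}

#' Stochastic hill climbing with linearly decaying proposal width
#'
#' In each iteration a random subset of parameters (Bernoulli p = 0.5 each)
#' is perturbed by uniform proposals centered on the current value; the
#' half-width decays linearly from half the allowed range to 0.1% of it.
#' Proposals are clipped to the bounds, and a proposal is kept only if its
#' cost is strictly lower.  If a holdout evaluator is supplied, the visited
#' (accepted) parameter set minimizing the holdout cost is returned as
#' `x_early` (early stopping).
#'
#' @param start numeric start vector.
#' @param specs list of [param_spec()]s.
#' @param evaluator cost function (deterministic given its own seeding).
#' @param n_iter number of iterations.
#' @param seed integer seed.
#' @param holdout_evaluator optional second cost function for early stopping.
#' @return list with `x`, `cost`, `trace` (data frame), and optionally
#'   `x_early`, `holdout_costs`.
#' @export
hillclimb <- function(start, specs, evaluator, n_iter = 500, seed = 1,
                      holdout_evaluator = NULL) {
  lo <- vapply(specs, `[[`, 1.0, "lower")
  hi <- vapply(specs, `[[`, 1.0, "upper")
  rng <- hi - lo
  x <- clip(start, lo, hi)
  cost <- evaluator(x)
  visited <- list(x)
  trace <- data.frame(iter = 0, cost = cost, accepted = TRUE)
  with_local_seed(derive_seed(seed, "hillclimb"), {
    for (it in seq_len(n_iter)) {
      frac <- 0.5 + (0.001 - 0.5) * (it - 1) / max(1, n_iter - 1)
      pick <- stats::runif(length(x)) < 0.5
      prop <- x
      if (any(pick)) {
        w <- frac * rng[pick]
        prop[pick] <- clip(stats::runif(sum(pick), x[pick] - w, x[pick] + w),
                           lo[pick], hi[pick])
      }
      c_new <- evaluator(prop)
      acc <- c_new < cost
      if (acc) {
        x <- prop; cost <- c_new
        visited[[length(visited) + 1]] <- x
      }
      trace <- rbind(trace,
                     data.frame(iter = it, cost = c_new, accepted = acc))
    }
  })
  out <- list(x = x, cost = cost, trace = trace)
  if (!is.null(holdout_evaluator)) {
    hc <- vapply(visited, holdout_evaluator, 1.0)
    out$x_early <- visited[[which.min(hc)]]
    out$holdout_costs <- hc
  }
  out
}

#' Randomly perturb plasticity parameters (robustness protocol)
#'
#' Each selected parameter value `v` is replaced by a draw from
#' `Normal(v, (sigma * v)^2)`.  Time constants are then forced non-negative
#' and the upper bound of each initial-weight interval is raised to its
#' lower bound where necessary.
#'
#' @param params a [model_params()] object.
#' @param sigma relative standard deviation.
#' @param seed integer seed.
#' @param names parameters to vary (default: the 20-parameter robustness
#'   subset).
#' @return the perturbed `model_params` object.
#' @export
perturb_params <- function(params, sigma, seed = 1,
                           names = robustness_param_names(params)) {
  stopifnot(sigma >= 0)
  specs <- param_specs(params)[names]
  with_local_seed(derive_seed(seed, "perturb"), {
    for (s in specs) {
      v <- params$plastic[[s$group]][[s$field]]
      nv <- stats::rnorm(1, v, abs(sigma * v))
      # non-negative time constants (floored just above 0 so the learning
      # window stays well defined)
      if (s$field %in% c("tau_plus", "tau_minus")) nv <- max(nv, 1e-3)
      params$plastic[[s$group]][[s$field]] <- nv
    }
    for (g in names(params$plastic)) {
      row <- params$plastic[[g]]
      if (row$w_init_hi < row$w_init_lo)
        params$plastic[[g]]$w_init_hi <- row$w_init_lo
    }
  })
  params
}
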