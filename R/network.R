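# Network construction: content space, neural spaces, input population,
# within- and between-space wiring, inhibitory locks.

pop_template <- function(name, kind, n, space, params = NULL, dt = 0.1) {
  pop <- list(name = name, kind = kind, n = n, space = space,
              V = numeric(n), b_sfa = numeric(n),
              refr_rem = numeric(n), refr_dur = rep(1, n))
  if (!is.null(params)) {
    pop$c1 <- params$c1; pop$c2 <- params$c2; pop$c3 <- params$c3
    pop$tau_m <- params$tau_m; pop$R_m <- params$R_m; pop$I_e <- params$I_e
    pop$q_sfa <- params$q_sfa; pop$tau_sfa_ms <- params$tau_sfa * 1000
    pop$b_max <- params$b_sfa_max
  }
  pop
}

# Bernoulli(p) directed edges between populations of size n_pre and n_post.
# Self-connections are excluded when `recurrent` (standard convention; the
# connection statistics are otherwise independent per ordered pair).
random_edges <- function(n_pre, n_post, p, recurrent = FALSE) {
  if (p >= 1) {
    pre <- rep(seq_len(n_pre), times = n_post)
    post <- rep(seq_len(n_post), each = n_pre)
  } else {
    hit <- which(stats::runif(n_pre * n_post) < p)
    pre <- ((hit - 1L) %% n_pre) + 1L
    post <- ((hit - 1L) %/% n_pre) + 1L
  }
  if (recurrent) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  list(pre = pre, post = post)
}

make_static_group <- function(name, pre_pop, post_pop, n_pre, n_post, row,
                              w_unit, recurrent = FALSE) {
  e <- random_edges(n_pre, n_post, row$p, recurrent)
  list(name = name, kind = 0L, pre_pop = pre_pop, post_pop = post_pop,
       w_unit = w_unit, pre = e$pre, post = e$post,
       w = rep(row$w, length(e$pre)),
       delay_ms = rep(row$delay, length(e$pre)),
       plastic = FALSE, frozen = FALSE)
}

make_plastic_group <- function(name, pre_pop, post_pop, n_pre, n_post, sp,
                               w_unit, recurrent = FALSE) {
  e <- random_edges(n_pre, n_post, sp$p, recurrent)
  ne <- length(e$pre)
  w0 <- if (sp$w_init_lo == sp$w_init_hi) rep(sp$w_init_lo, ne) else
    stats::runif(ne, sp$w_init_lo, sp$w_init_hi)
  d0 <- if (sp$delay_lo == sp$delay_hi) rep(sp$delay_lo, ne) else
    stats::runif(ne, sp$delay_lo, sp$delay_hi)
  list(name = name, kind = 1L, pre_pop = pre_pop, post_pop = post_pop,
       w_unit = w_unit, pre = e$pre, post = e$post,
       w = clip(w0, sp$w_min, sp$w_max), delay_ms = d0,
       plastic = TRUE, frozen = FALSE,
       eta = sp$eta, alpha = sp$alpha, tau_plus = sp$tau_plus,
       tau_minus = if (is.na(sp$tau_minus)) NULL else sp$tau_minus,
       A_minus = sp$A_minus, w_min = sp$w_min, w_max = sp$w_max)
}

#' Build an excitatory/inhibitory space
#'
#' Creates the paired excitatory and inhibitory populations of one space
#' (4:1 size ratio) together with its internal wiring: plastic recurrent
#' E-to-E synapses and static E-to-I, I-to-E and I-to-I synapses with the
#' tabulated probabilities and weights.  Used internally by
#' [build_network()]; exposed for direct inspection of single spaces.
#'
#' @param net a network under construction (internal accumulator), or `NULL`
#'   to start a fresh one.
#' @param name space name, e.g. `"C"` or `"S1"`.
#' @param n_exc number of excitatory neurons (must be divisible by 4).
#' @param neural logical; `TRUE` for structural ("neural") spaces, which are
#'   locked by default, carry excitability traces, and gate the plasticity of
#'   synapses touching them.
#' @param params a [model_params()] object.
#' @param seed integer seed for the wiring of this space.
#' @return the updated network accumulator.
#' @export
build_space <- function(net, name, n_exc, neural, params, seed) {
  if (n_exc %% 4 != 0) stop("excitatory pool size must be divisible by 4")
  n_inh <- n_exc / 4
  np <- if (neural) params$neuron$exc_neural else params$neuron$exc
  with_local_seed(seed, {
    iE <- length(net$pops) + 1L
    iI <- iE + 1L
    space_id <- length(net$spaces) + 1L
    popE <- pop_template(paste0(name, "_E"), 0L, n_exc, space_id, np)
    popI <- pop_template(paste0(name, "_I"), 0L, n_inh, space_id, params$neuron$inh)
    # per-neuron refractory durations, sampled once
    popE$refr_dur <- stats::rgamma(n_exc, shape = np$refr_shape, scale = np$refr_scale)
    popI$refr_dur <- stats::rgamma(n_inh, shape = params$neuron$inh$refr_shape,
                                   scale = params$neuron$inh$refr_scale)
    net$pops[[popE$name]] <- popE
    net$pops[[popI$name]] <- popI
    net$spaces[[name]] <- list(name = name, neural = neural,
                               lock_nA = params$lock_nA,
                               pops = c(iE, iI), E = iE, I = iI,
                               inhibited = neural) # default: neural locked
    ee_row <- if (neural) params$plastic$EE_S else params$plastic$EE_C
    st <- params$static
    wu_s <- params$w_unit_static_mV
    wu_p <- params$w_unit_plastic_mV
    net$groups[[paste0(name, "_EE")]] <-
      make_plastic_group(paste0(name, "_EE"), iE, iE, n_exc, n_exc, ee_row,
                         wu_p, recurrent = TRUE)
    net$groups[[paste0(name, "_EI")]] <-
      make_static_group(paste0(name, "_EI"), iE, iI, n_exc, n_inh, st$EI, wu_s)
    net$groups[[paste0(name, "_IE")]] <-
      make_static_group(paste0(name, "_IE"), iI, iE, n_inh, n_exc, st$IE, wu_s)
    net$groups[[paste0(name, "_II")]] <-
      make_static_group(paste0(name, "_II"), iI, iI, n_inh, n_inh, st$II, wu_s,
                        recurrent = TRUE)
  })
  net
}

#' Connect two spaces (or the input population to a space) plastically
#'
#' Realizes the tabulated plastic connection type between the excitatory
#' pools of `pre` and `post`: Bernoulli(p) edges, uniform per-edge delays
#' and uniform initial weights within the tabulated bounds.
#'
#' @param net network accumulator.
#' @param pre,post space names (or `"X"` for the input population as `pre`).
#' @param row an [stdp_params()] table row.
#' @param seed wiring seed.
#' @return the updated network.
#' @export
connect_spaces <- function(net, pre, post, row, seed) {
  pre_idx <- if (pre == "X") net$input_pop else net$spaces[[pre]]$E
  post_idx <- net$spaces[[post]]$E
  n_pre <- net$pops[[pre_idx]]$n
  n_post <- net$pops[[post_idx]]$n
  name <- paste0(pre, "_", post)
  with_local_seed(seed, {
    net$groups[[name]] <- make_plastic_group(name, pre_idx, post_idx,
                                             n_pre, n_post, row,
                                             net$params$w_unit_plastic_mV)
  })
  net
}

#' Build the full network model
#'
#' Constructs the input population X, the content space C and any number of
#' neural spaces, with all within- and between-space wiring drawn from the
#' tabulated connection statistics.  Wiring seeds are derived per component
#' from the master seed, so adding a neural space never changes the content
#' space realization, and `neural_seed` can be varied to re-instantiate the
#' neural spaces over a fixed, trained content space.
#'
#' @param seed master integer seed.
#' @param neural_spaces character vector of neural-space names (may be empty).
#' @param params a [model_params()] object.
#' @param neural_seed optional separate seed for neural-space wiring
#'   (defaults to `seed`).
#' @return an object of class `apnet`.
#' @examples
#' net <- build_network(1, neural_spaces = character(0))
#' net
#' @export
build_network <- function(seed, neural_spaces = "S1", params = model_params(),
                          neural_seed = seed) {
  net <- structure(list(params = params, dt = params$dt, seed = seed,
                        pops = list(), spaces = list(), groups = list(),
                        input_pop = 1L),
                   class = "apnet")
  # input population: Poisson generators, no dynamics
  net$pops[["X"]] <- pop_template("X", 1L, params$n_in, 0L)
  net <- build_space(net, "C", params$n_content, neural = FALSE, params,
                     seed = derive_seed(seed, "wiring/C"))
  net <- connect_spaces(net, "X", "C", params$plastic$X_C,
                        seed = derive_seed(seed, "wiring/X_C"))
  for (s in neural_spaces) net <- add_neural_space(net, s, neural_seed)
  net
}

#' Add a neural space to an existing network
#'
#' @param net an `apnet` network.
#' @param name name of the new space.
#' @param seed seed for its wiring (both internal and to/from the content
#'   space).
#' @export
add_neural_space <- function(net, name, seed) {
  params <- net$params
  net <- build_space(net, name, params$n_neural, neural = TRUE, params,
                     seed = derive_seed(seed, paste0("wiring/", name)))
  net <- connect_spaces(net, "C", name, params$plastic$C_S,
                        seed = derive_seed(seed, paste0("wiring/C_", name)))
  net <- connect_spaces(net, name, "C", params$plastic$S_C,
                        seed = derive_seed(seed, paste0("wiring/", name, "_C")))
  net
}

#' Remove a neural space (and all groups touching it)
#'
#' Used by suite runners that re-instantiate neural spaces over a fixed
#' trained content space.
#' @param net an `apnet` network.
#' @param name space to drop.
#' @export
drop_neural_space <- function(net, name) {
  sp <- net$spaces[[name]]
  if (is.null(sp)) return(net)
  drop_pops <- sp$pops
  keep <- !vapply(net$groups, function(g)
    g$pre_pop %in% drop_pops || g$post_pop %in% drop_pops, TRUE)
  net$groups <- net$groups[keep]
  # relabel population indices after removal
  old_n <- length(net$pops)
  remap <- integer(old_n)
  remap[setdiff(seq_len(old_n), drop_pops)] <- seq_len(old_n - length(drop_pops))
  net$pops <- net$pops[-drop_pops]
  net$groups <- lapply(net$groups, function(g) {
    g$pre_pop <- remap[g$pre_pop]; g$post_pop <- remap[g$post_pop]; g
  })
  net$spaces[[name]] <- NULL
  net$spaces <- lapply(net$spaces, function(s) {
    s$pops <- remap[s$pops]; s$E <- remap[s$E]; s$I <- remap[s$I]; s
  })
  net$input_pop <- remap[net$input_pop]
  net
}

#' Attach a comparison readout population
#'
#' Adds `n` deterministic leaky integrate-and-fire neurons receiving sparse
#' short-term-depressing synapses from the content-space excitatory pool.
#'
#' @param net an `apnet` network.
#' @param seed wiring seed.
#' @export
add_readout <- function(net, seed) {
  ro <- net$params$readout
  idx <- length(net$pops) + 1L
  pop <- pop_template("R", 2L, ro$n, 0L)
  pop$tau_m <- ro$tau_m; pop$v_rest <- ro$v_rest; pop$v_thresh <- ro$v_thresh
  pop$refr_ms <- ro$refr
  pop$V <- rep(ro$v_rest, ro$n)
  net$pops[["R"]] <- pop
  cE <- net$spaces$C$E
  with_local_seed(derive_seed(seed, "wiring/readout"), {
    e <- random_edges(net$pops[[cE]]$n, ro$n, ro$p)
    net$groups[["C_R"]] <- list(
      name = "C_R", kind = 2L, pre_pop = cE, post_pop = idx,
      w_unit = ro$w_unit_mV, pre = e$pre, post = e$post,
      w = rep(ro$tm$w, length(e$pre)),
      delay_ms = rep(ro$delay, length(e$pre)),
      plastic = FALSE, frozen = FALSE,
      U = ro$tm$U, tau_rec = ro$tm$tau_rec, tau_fac = ro$tm$tau_fac)
  })
  net
}

#' Set the default inhibition state of a space
#'
#' A locked space receives the strong lock current (default -4 nA) on all of
#' its neurons; the lock silences activity and (for neural spaces) closes the
#' plasticity gates of every synapse group touching the space.  Simulation
#' phases can override this default transiently.
#'
#' @param net an `apnet` network.
#' @param space space name.
#' @param locked logical.
#' @export
set_inhibition <- function(net, space, locked) {
  stopifnot(space %in% names(net$spaces))
  net$spaces[[space]]$inhibited <- isTRUE(locked)
  net
}

#' Freeze content-space afferent and recurrent plasticity
#'
#' After assembly induction, the input-to-content and content recurrent
#' synapses are permanently frozen.
#' @param net an `apnet` network.
#' @export
freeze_content_plasticity <- function(net) {
  for (g in c("X_C", "C_EE"))
    if (!is.null(net$groups[[g]])) net$groups[[g]]$frozen <- TRUE
  net
}

#' @export
print.apnet <- function(x, ...) {
  cat("<apnet> network, dt =", x$dt, "ms\n")
  for (p in x$pops)
    cat(sprintf("  pop %-6s n=%5d kind=%s\n", p$name, p$n,
                c("hazard", "poisson", "lif")[p$kind + 1]))
  for (s in x$spaces)
    cat(sprintf("  space %-4s %s, %s\n", s$name,
                if (s$neural) "neural" else "content",
                if (s$inhibited) "locked" else "disinhibited"))
  cat(sprintf("  %d synapse groups, %d edges total\n", length(x$groups),
              sum(vapply(x$groups, function(g) length(g$pre), 1))))
  invisible(x)
}

# mean weight of a group's edges restricted to pre in `pre_set`, post in `post_set`
#' Mean weight over a subset of a group's edges
#'
#' @param net an `apnet` network.
#' @param group group name.
#' @param pre_set,post_set neuron index sets (1-based within the pre/post
#'   population); `NULL` means all.
#' @return mean weight (NA if no edge matches).
#' @export
mean_weight <- function(net, group, pre_set = NULL, post_set = NULL) {
  g <- net$groups[[group]]
  stopifnot(!is.null(g))
  sel <- rep(TRUE, length(g$pre))
  if (!is.null(pre_set)) sel <- sel & (g$pre %in% pre_set)
  if (!is.null(post_set)) sel <- sel & (g$post %in% post_set)
  if (!any(sel)) return(NA_real_)
  mean(g$w[sel])
}
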