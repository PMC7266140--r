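# Rate-coded input patterns and their Poisson realizations.

#' Generate a set of input patterns
#'
#' Each pattern activates `n_active` of the `n_in` input neurons at
#' `rate_active` Hz while the remaining neurons fire at `rate_background` Hz.
#' When all patterns fit disjointly (`n_active * n` <= `n_in`) the active
#' sets are drawn as a random partition, so every input neuron is active in
#' at most one pattern; beyond that (capacity sweeps) independent random
#' subsets are drawn and overlap is permitted.
#'
#' @param n number of patterns.
#' @param params a [model_params()] object (stimulus statistics).
#' @param seed integer seed.
#' @return an object of class `pattern_set`: list of patterns, each with an
#'   `active` index set and the rate constants.
#' @export
make_patterns <- function(n, params = model_params(), seed = 1) {
  stopifnot(n >= 1)
  st <- params$stimulus
  n_in <- params$n_in
  with_local_seed(derive_seed(seed, "patterns"), {
    if (st$n_active * n <= n_in) {
      perm <- sample.int(n_in)
      sets <- lapply(seq_len(n), function(i)
        sort(perm[((i - 1) * st$n_active + 1):(i * st$n_active)]))
    } else {
      sets <- lapply(seq_len(n), function(i) sort(sample.int(n_in, st$n_active)))
    }
  })
  structure(list(patterns = lapply(seq_along(sets), function(i)
    list(id = i, active = sets[[i]],
         rate_active = st$rate_active,
         rate_background = st$rate_background)),
    n_in = n_in, idle_rate = st$rate_idle),
    class = "pattern_set")
}

#' Per-input-neuron rate vector for a pattern or the idle state
#'
#' @param ps a [make_patterns()] pattern set.
#' @param which pattern index, or `"idle"` for the inter-trial state in which
#'   all input neurons fire at the idle rate (chosen so the mean population
#'   input rate roughly matches the pattern phases).
#' @return numeric rate vector of length `n_in` (Hz).
#' @export
pattern_rates <- function(ps, which) {
  stopifnot(inherits(ps, "pattern_set"))
  if (identical(which, "idle")) return(rep(ps$idle_rate, ps$n_in))
  p <- ps$patterns[[which]]
  r <- rep(p$rate_background, ps$n_in)
  r[p$active] <- p$rate_active
  r
}

#' Realize independent Poisson spike trains on the simulation grid
#'
#' Standalone realization of the input process (the engine generates input
#' internally during network runs; this function exposes the same law for
#' analysis and testing).
#'
#' @param rates per-neuron rates in Hz.
#' @param duration_ms duration.
#' @param dt grid step in ms.
#' @param seed integer seed.
#' @return data frame with `neuron` and `time_ms` (empty for zero duration).
#' @export
realize_poisson <- function(rates, duration_ms, dt = 0.1, seed = 1) {
  stopifnot(duration_ms >= 0)
  nstep <- round(duration_ms / dt)
  if (nstep == 0)
    return(data.frame(neuron = integer(0), time_ms = numeric(0)))
  p <- 1 - exp(-rates * dt / 1000)
  with_local_seed(seed, {
    hits <- lapply(seq_along(rates), function(i) {
      if (p[i] <= 0) return(numeric(0))
      which(stats::runif(nstep) < p[i]) * dt - dt
    })
  })
  data.frame(neuron = rep(seq_along(rates), lengths(hits)),
             time_ms = unlist(hits) %||% numeric(0))
}

#' Reduced-rate stimulus preset
#'
#' Robustness variant with active input neurons at 60 Hz and background
#' neurons at 1 Hz.
#' @param params a [model_params()] object.
#' @export
reduced_rate_params <- function(params = model_params()) {
  params$stimulus$rate_active <- 60
  params$stimulus$rate_background <- 1
  params
}

#' Write / read a pattern set as plain structured text
#'
#' One line per pattern: `id<TAB>comma-separated sorted active indices`.
#' @param ps a `pattern_set`.
#' @param path file path.
#' @export
write_patterns <- function(ps, path) {
  lines <- c(sprintf("# n_in=%d idle=%g active=%g background=%g",
                     ps$n_in, ps$idle_rate,
                     ps$patterns[[1]]$rate_active,
                     ps$patterns[[1]]$rate_background),
             vapply(ps$patterns, function(p)
               paste0(p$id, "\t", paste(p$active, collapse = ",")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(regmatches(lines[1],
    gregexpr("[0-9.]+", lines[1]))[[1]])
  body <- strsplit(lines[-1], "\t")
  pats <- lapply(body, function(f) list(
    id = as.integer(f[1]),
    active = as.integer(strsplit(f[2], ",")[[1]]),
    rate_active = hdr[3], rate_background = hdr[4]))
  structure(list(patterns = pats, n_in = as.integer(hdr[1]),
                 idle_rate = hdr[2]),
            class = "pattern_set")
}
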