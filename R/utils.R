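# Internal helpers: deterministic seed derivation and scoped RNG use.

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package is rooted in one integer master seed.
#' Independent streams (wiring of a space, a pattern set, dynamics of a run,
#' decoder noise, ...) are derived from it with a fixed string label, so that
#' adding one component never perturbs the realizations of another.
#'
#' @param seed integer master seed.
#' @param label character label naming the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  # one extra scramble round so labels differing in a suffix decorrelate
  h <- (h * 48271) %% m
  as.integer(h)
}

# Evaluate `expr` under a local R RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
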