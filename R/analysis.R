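# Spike-train analysis: low-pass filtering, assembly identification, the
# similarity criterion, linear decoders, and fMRI-style voxelization.

#' Low-pass filter spike trains onto a 1-ms grid
#'
#' \eqn{r_i(t) = \sum_{s \in [t - T_{LP},\, t]} e^{-(t - t_s)/\tau_{LP}}}
#' over the spikes of neuron \eqn{i}; spikes older than `T_LP` contribute
#' nothing.
#'
#' @param spikes data frame with `neuron` and `time_ms` (one population).
#' @param n_neurons number of neurons (columns of the result).
#' @param t_start,t_end window of the output grid in ms.
#' @param step grid step in ms (1 ms).
#' @param tau_lp filter time constant in ms.
#' @param T_lp kernel truncation in ms.
#' @return matrix of filtered activity, time points x neurons, with the grid
#'   times as rownames.
#' @export
lowpass_traces <- function(spikes, n_neurons, t_start, t_end, step = 1,
                           tau_lp = 20, T_lp = 100) {
  grid <- seq(t_start, t_end, by = step)
  out <- matrix(0, length(grid), n_neurons)
  if (nrow(spikes)) {
    kern <- exp(-seq(0, T_lp, by = step) / tau_lp)
    nk <- length(kern)
    keep <- spikes$time_ms <= t_end & spikes$time_ms >= t_start - T_lp
    sn <- spikes$neuron[keep]
    st <- spikes$time_ms[keep]
    for (k in seq_along(st)) {
      # first grid index at or after the spike
      i0 <- ceiling((st[k] - t_start) / step) + 1
      if (i0 < 1) i0 <- 1
      # support ends at the last grid point within T_lp of the spike
      i1 <- min(length(grid), i0 + nk - 1,
                floor((st[k] + T_lp - t_start) / step + 1e-9) + 1)
      if (i0 > i1) next
      lag0 <- grid[i0] - st[k]
      out[i0:i1, sn[k]] <- out[i0:i1, sn[k]] +
        exp(-lag0 / tau_lp) * kern[seq_len(i1 - i0 + 1)]
    }
  }
  rownames(out) <- grid
  out
}

#' Identify an assembly from firing rates
#'
#' Neurons whose firing rate strictly exceeds the threshold over the window
#' belong to the assembly.
#'
#' @param counts per-neuron spike counts over the window.
#' @param window_ms window length in ms.
#' @param thresh rate threshold in Hz (strict inequality).
#' @return integer vector of neuron indices.
#' @export
identify_assembly <- function(counts, window_ms, thresh = 50) {
  stopifnot(window_ms > 0)
  which(counts / window_ms * 1000 > thresh)
}

#' Similarity criterion between a reference assembly and a recalled set
#'
#' A recall passes if at least a fraction `retain` (default 80%) of the
#' reference assembly is active during the recall, while the number of
#' excess neurons (active but not in the reference) does not exceed a
#' fraction `excess` (default 20%) of the reference size.
#'
#' @param reference integer vector: the reference assembly (nonempty).
#' @param recalled integer vector: neurons active during the recall.
#' @param retain,excess the two criterion fractions.
#' @return list of class `similarity_report` with `original_size`,
#'   `retained_fraction`, `excess_count`, `passes`.
#' @export
similarity <- function(reference, recalled, retain = 0.8, excess = 0.2) {
  if (length(reference) == 0) stop("empty reference assembly")
  rf <- length(intersect(reference, recalled)) / length(reference)
  ex <- length(setdiff(recalled, reference))
  structure(list(original_size = length(reference), retained_fraction = rf,
                 excess_count = ex,
                 passes = rf >= retain && ex <= excess * length(reference)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("similarity: retained %.1f%% of %d, %d excess -> %s\n",
              100 * x$retained_fraction, x$original_size, x$excess_count,
              if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

#' Train the linear content readout
#'
#' Multinomial linear classifier (ridge-regularized maximum likelihood, via
#' glmnet) on per-millisecond low-pass-filtered activity vectors of the
#' content space, labeled by the driving pattern.
#'
#' @param X samples x features matrix of filtered traces.
#' @param y class labels (one per row of `X`).
#' @param lambda ridge penalty.
#' @return fitted decoder of class `linear_decoder`.
#' @importFrom glmnet glmnet
#' @export
train_decoder <- function(X, y, lambda = 1e-3) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  fit <- glmnet::glmnet(X, y, family = if (nlevels(y) == 2) "binomial"
                        else "multinomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, levels = levels(y), lambda = lambda),
            class = "linear_decoder")
}

#' @rdname train_decoder
#' @param decoder a fitted `linear_decoder`.
#' @export
classify <- function(decoder, X) {
  cl <- predict(decoder$fit, newx = X, type = "class",
                s = decoder$lambda)
  factor(as.vector(cl), levels = decoder$levels)
}

#' Per-sample classification error of a recall window
#'
#' The per-trial recall error is the fraction of misclassified 1-ms samples
#' in the window starting 50 ms after recall onset.
#'
#' @param decoder a `linear_decoder`.
#' @param traces time x neurons matrix from [lowpass_traces()] covering the
#'   scoring window.
#' @param label the true class.
#' @return error fraction in `[0, 1]`.
#' @export
decoder_error <- function(decoder, traces, label) {
  pred <- classify(decoder, traces)
  mean(pred != as.character(label))
}

#' Voxelize filtered activity into a coarse noisy signal
#'
#' Emulates fMRI-resolution measurements: neurons are partitioned into
#' `n_voxels` fixed groups, filtered activity is summed within each group and
#' averaged over the trial window, and independent Gaussian noise is added.
#'
#' @param traces time x neurons matrix (already restricted to the retained
#'   window).
#' @param partition list of neuron index sets (from [voxel_partition()]).
#' @param noise_var Gaussian noise variance (0 disables noise).
#' @param seed seed for the noise draws.
#' @return numeric vector, one value per voxel.
#' @export
voxelize <- function(traces, partition, noise_var = 5, seed = 1) {
  v <- vapply(partition, function(idx)
    mean(rowSums(traces[, idx, drop = FALSE])), 1.0)
  if (noise_var > 0)
    v <- v + with_local_seed(seed,
      stats::rnorm(length(v), 0, sqrt(noise_var)))
  v
}

#' Fixed random voxel partition of a population
#'
#' Drawn once per network instance and reused across train and test trials.
#'
#' @param n_neurons population size.
#' @param n_voxels number of equally sized groups.
#' @param seed seed.
#' @export
voxel_partition <- function(n_neurons, n_voxels = 5, seed = 1) {
  stopifnot(n_neurons %% n_voxels == 0)
  with_local_seed(derive_seed(seed, "voxels"), {
    perm <- sample.int(n_neurons)
  })
  split(perm, rep(seq_len(n_voxels), each = n_neurons / n_voxels))
}
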