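# Plain-text IO: spike records (gdf-like), weight snapshots, experiment
# configuration files, and the config-driven suite runner.

#' Write / read a spike record as columnar text
#'
#' One event per line: `population<TAB>neuron_index<TAB>time_ms`.
#'
#' @param spikes data frame with `pop`, `neuron`, `time_ms`.
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.table(spikes[, c("pop", "neuron", "time_ms")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("pop", "neuron",
                                                          "time_ms"))
  df$neuron <- as.integer(df$neuron)
  df
}

#' Write / read a weight snapshot as sparse triplets
#'
#' Header line names the group and timestamp; body lines are
#' `pre<TAB>post<TAB>weight`.
#'
#' @param net an `apnet` network.
#' @param group group name.
#' @param path file path.
#' @param timestamp optional timestamp string for the header.
#' @export
write_weights <- function(net, group, path, timestamp = "") {
  g <- net$groups[[group]]
  stopifnot(!is.null(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# group=%s time=%s n_edges=%d", group, timestamp,
                     length(g$pre)), con)
  utils::write.table(data.frame(g$pre, g$post, g$w), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- utils::read.table(path, sep = "\t", skip = 1,
                          col.names = c("pre", "post", "w"))
  attr(df, "group") <- sub(".*group=(\\S+).*", "\\1", hdr)
  df
}

#' Load / store an experiment configuration (YAML)
#'
#' @param path file path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config a named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default experiment configuration
#'
#' Desk-scale profiles for all named suites; the full-scale profiles used
#' for the long-running reproductions set larger multiplicities but leave
#' all durations and parameters unchanged.
#'
#' @param experiment suite name.
#' @param scale `"desk"` or `"full"`.
#' @export
default_config <- function(experiment = c("recall", "copy", "compare",
                                          "roles", "robustness", "capacity"),
                           scale = c("desk", "full")) {
  experiment <- match.arg(experiment)
  scale <- match.arg(scale)
  full <- scale == "full"
  base <- list(experiment = experiment, seed = 1,
               n_patterns = 5, n_presentations = if (full) 200 else 200)
  extra <- switch(experiment,
    recall = list(n_content_seeds = if (full) 5 else 1,
                  n_space_seeds = if (full) 10 else 2),
    copy = list(n_copies = if (full) 50 else 10),
    compare = list(),
    roles = list(identity = full),
    robustness = list(sigma = 0.2, n_samples = if (full) 100 else 10,
                      n_presentations = if (full) 200 else 25),
    capacity = list(n_concepts = if (full) c(5, 30, 35, 40) else c(5, 30)))
  c(base, extra)
}

#' Run a named experiment suite from a configuration
#'
#' Executes the suite described by `config` (see [default_config()]) and
#' returns its results together with the archived configuration.  Summary
#' statistics are always recomputable from the returned per-trial records.
#'
#' @param config configuration list.
#' @param params model parameters.
#' @return list with `config` and `results`.
#' @export
run_suite <- function(config, params = model_params()) {
  seed <- config$seed %||% 1
  res <- switch(config$experiment,
    recall = {
      out <- list()
      for (cs in seq_len(config$n_content_seeds %||% 1)) {
        rig <- standard_rig(derive_seed(seed, paste0("content-", cs)),
                            params = params,
                            n_patterns = config$n_patterns %||% 5,
                            n_presentations = config$n_presentations %||% 200)
        out[[cs]] <- recall_suite(rig,
          space_seeds = derive_seed(seed, paste0("spaces-", cs)) +
            seq_len(config$n_space_seeds %||% 2) - 1,
          seed = derive_seed(seed, paste0("dyn-", cs)))
      }
      trials <- do.call(rbind, lapply(out, `[[`, "trials"))
      list(trials = trials,
           summary = list(mean_error_pct = 100 * mean(trials$error),
                          sd_error_pct = 100 * stats::sd(trials$error),
                          n_pass = sum(trials$passes),
                          n_trials = nrow(trials)))
    },
    copy = {
      rig <- standard_rig(derive_seed(seed, "content"), params = params,
                          n_patterns = config$n_patterns %||% 5,
                          n_presentations = config$n_presentations %||% 200)
      copy_suite(rig, n_copies = config$n_copies %||% 10,
                 seed = derive_seed(seed, "copy"))
    },
    compare = {
      rig <- standard_rig(derive_seed(seed, "content"), params = params,
                          n_patterns = config$n_patterns %||% 5,
                          n_presentations = config$n_presentations %||% 200)
      compare_grid(rig, seed = derive_seed(seed, "compare"))
    },
    roles = {
      rig <- standard_rig(derive_seed(seed, "content"), params = params,
                          n_patterns = config$n_patterns %||% 5,
                          n_presentations = config$n_presentations %||% 200)
      rr <- roles_rig(rig, seed = derive_seed(seed, "roles"))
      out <- list(meaning = sentence_meaning_experiment(
        rr, seed = derive_seed(seed, "meaning")))
      if (isTRUE(config$identity))
        out$identity <- role_identity_experiment(
          rr, seed = derive_seed(seed, "identity"))
      out
    },
    robustness = robustness_suite(config$sigma %||% 0.2,
                                  n_samples = config$n_samples %||% 10,
                                  seed = seed,
                                  n_presentations = config$n_presentations %||% 25,
                                  params = params),
    capacity = capacity_sweep(config$n_concepts %||% c(5, 30), seed = seed,
                              params = params),
    stop("unknown experiment: ", config$experiment))
  list(config = config, results = res)
}

#' Load the connection-parameter tables from a YAML config
#'
#' Reads a machine-readable connection config (one block per connection
#' type; the package ships its defaults in
#' `system.file("extdata", "connection_params.yaml", package = "apnet")`),
#' validates completeness against the schema, and merges it into a
#' [model_params()] object.
#'
#' @param path YAML file path (defaults to the shipped tables).
#' @param params base parameter object to merge into.
#' @return the updated `model_params` object.
#' @export
load_connection_config <- function(path = system.file("extdata",
                                     "connection_params.yaml",
                                     package = "apnet"),
                                   params = model_params()) {
  cfg <- yaml::read_yaml(path)
  need_s <- c("p", "w", "delay")
  for (nm in c("EI", "IE", "II")) {
    row <- cfg$static[[nm]]
    if (is.null(row) || !all(need_s %in% names(row)))
      stop("incomplete static row: ", nm)
    params$static[[nm]] <- row[need_s]
  }
  need_p <- c("p", "delay", "init", "bounds", "alpha", "tau_plus",
              "A_minus", "eta")
  for (nm in c("X_C", "S_C", "EE_C", "C_S", "EE_S")) {
    row <- cfg$plastic[[nm]]
    if (is.null(row) || !all(need_p %in% names(row)))
      stop("incomplete plastic row: ", nm)
    # YAML sequences with mixed integer/real entries parse as lists
    for (f2 in c("delay", "init", "bounds"))
      row[[f2]] <- as.numeric(unlist(row[[f2]]))
    params$plastic[[nm]] <- stdp_params(
      eta = row$eta, alpha = row$alpha, tau_plus = row$tau_plus,
      tau_minus = if (is.null(row$tau_minus)) NA else row$tau_minus,
      A_minus = row$A_minus, w_min = row$bounds[1], w_max = row$bounds[2],
      w_init_lo = row$init[1], w_init_hi = row$init[2],
      delay_lo = row$delay[1], delay_hi = row$delay[2], p = row$p)
  }
  if (!is.null(cfg$readout_tm))
    params$readout$tm <- tm_params(U = cfg$readout_tm$U,
                                   tau_rec = cfg$readout_tm$tau_rec,
                                   tau_fac = cfg$readout_tm$tau_fac,
                                   w = cfg$readout_tm$w)
  params
}
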