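# Experiment suites: the standard recall experiment, copy and compare
# suites, the role-binding (voxel decoding) experiments, robustness and
# capacity sweeps.  Every suite derives all randomness from one seed and
# returns per-trial records plus summary statistics.

#' Set up a trained content space with readout decoder
#'
#' Builds a network with a content space only, induces assemblies, and
#' trains the linear content readout on the probe responses.
#'
#' @param seed master seed.
#' @param ps pattern set (or `NULL` to create one from the seed).
#' @param params model parameters.
#' @param n_patterns number of patterns if `ps` is `NULL`.
#' @param n_presentations induction presentations.
#' @return list with `net`, `ps`, `assemblies`, `decoder`, `probe`.
#' @export
standard_rig <- function(seed, ps = NULL, params = model_params(),
                         n_patterns = 5, n_presentations = 200) {
  if (is.null(ps)) ps <- make_patterns(n_patterns, params, seed)
  net <- build_network(seed, neural_spaces = character(0), params = params)
  ind <- induce_assemblies(net, ps, n_presentations,
                           seed = derive_seed(seed, "induction"))
  dec <- train_content_decoder(ind, params)
  list(net = ind$net, ps = ps, assemblies = ind$assemblies, decoder = dec,
       probe = ind$probe)
}

#' Train the content readout from probe responses
#'
#' One probe presentation per pattern; features are the per-millisecond
#' low-pass-filtered activity vectors of the content space from 50 ms after
#' probe onset to probe end.
#'
#' @param ind an [induce_assemblies()] result.
#' @param params model parameters.
#' @export
train_content_decoder <- function(ind, params = model_params()) {
  run <- ind$probe
  nC <- sum(grepl("^probe", run$phases$label)) / 2
  cE <- run$spikes[run$spikes$pop == "C_E", ]
  X <- NULL; y <- NULL
  for (k in seq_len(nC)) {
    i1 <- which(run$phases$label == sprintf("probe%d_h1", k))
    t0 <- run$phases$start_ms[i1]
    t1 <- run$phases$end_ms[i1 + 1]
    tr <- lowpass_traces(cE, ncol_pop(run, "C_E"), t0 + 50, t1 - 1)
    X <- rbind(X, tr)
    y <- c(y, rep(k, nrow(tr)))
  }
  train_decoder(X, y, lambda = params$decoder$lambda)
}

ncol_pop <- function(run, pop) nrow(run$counts[[pop]])

#' Readout error of one recorded recall
#'
#' @param decoder the content decoder.
#' @param run a recorded run containing the recall phases.
#' @param label true pattern index.
#' @param onset_label label of the recall-onset phase.
#' @param score_from_ms,score_to_ms scoring window relative to onset.
#' @export
recall_error <- function(decoder, run, label, onset_label = "recall_lock",
                         score_from_ms = 50, score_to_ms = 200) {
  t0 <- run$phases$start_ms[run$phases$label == onset_label][1]
  cE <- run$spikes[run$spikes$pop == "C_E", ]
  tr <- lowpass_traces(cE, ncol_pop(run, "C_E"),
                       t0 + score_from_ms, t0 + score_to_ms - 1)
  decoder_error(decoder, tr, label)
}


#' Establish assembly projections for every pattern in a neural space
#'
#' Runs the configured number of CREATE rounds (1000-ms disinhibited
#' presentations) for each pattern, with idle rest periods in between so
#' that excitability traces from earlier operations decay.  The second
#' round saturates the bidirectional content/projection coupling.
#'
#' @param net an `apnet` network containing the (trained) content space and
#'   the target neural space.
#' @param space neural-space name.
#' @param ps pattern set.
#' @param seed dynamics seed.
#' @return list with `net` and `projections` (one neuron set per pattern,
#'   from the final round).
#' @export
establish_projections <- function(net, space, ps, seed = 1) {
  pr <- net$params$protocol
  projections <- vector("list", length(ps$patterns))
  for (r in seq_len(pr$create_rounds)) for (k in seq_along(ps$patterns)) {
    cr <- create_projection(net, space, ps, k,
      seed = derive_seed(seed, sprintf("create-%s-%d-%d", space, r, k)))
    net <- cr$net
    projections[[k]] <- cr$assembly
    net <- run_rest(net, ps, pr$create_rest_ms,
      seed = derive_seed(seed, sprintf("createidle-%s-%d-%d", space, r, k)))$net
  }
  list(net = net, projections = projections)
}

#' Weight statistics of established projections
#'
#' Mean feedforward (content to space), feedback (space to content) and
#' within-projection recurrent weights, averaged over patterns, split into
#' matching and non-matching assembly pairs.
#'
#' @param net network after [establish_projections()].
#' @param space neural-space name.
#' @param assemblies content-space assemblies (per pattern).
#' @param projections neural-space projection assemblies (per pattern).
#' @return named list of means.
#' @export
projection_stats <- function(net, space, assemblies, projections) {
  gff <- net$groups[[paste0("C_", space)]]
  gfb <- net$groups[[paste0(space, "_C")]]
  gee <- net$groups[[paste0(space, "_EE")]]
  ffm <- ffo <- fbm <- fbo <- eew <- eeb <- c()
  for (k in seq_along(assemblies)) {
    A <- assemblies[[k]]; SA <- projections[[k]]
    oth <- unlist(assemblies[-k]); soth <- unlist(projections[-k])
    ffm <- c(ffm, mean(gff$w[gff$pre %in% A & gff$post %in% SA]))
    ffo <- c(ffo, mean(gff$w[gff$pre %in% oth & gff$post %in% SA]))
    fbm <- c(fbm, mean(gfb$w[gfb$pre %in% SA & gfb$post %in% A]))
    fbo <- c(fbo, mean(gfb$w[gfb$pre %in% SA & gfb$post %in% oth]))
    eew <- c(eew, mean(gee$w[gee$pre %in% SA & gee$post %in% SA]))
    eeb <- c(eeb, mean(gee$w[gee$pre %in% SA & gee$post %in% setdiff(soth, SA)]))
  }
  list(ff_match = mean(ffm), ff_other = mean(ffo),
       fb_match = mean(fbm), fb_other = mean(fbo),
       ee_within = mean(eew), ee_between = mean(eeb))
}

#' The standard recall experiment
#'
#' For each neural-space seed: instantiate a fresh neural space over the
#' trained content space, create projections for every pattern, then for
#' each pattern run LOAD (200 ms), delay (5 s, idle input, neural spaces
#' locked) and RECALL (200 ms, content space locked for the first 50 ms).
#' Each trial yields the readout error and the similarity verdict against
#' the induction-time assembly.
#'
#' @param rig a [standard_rig()].
#' @param space_seeds integer vector: one neural-space wiring seed per
#'   repetition.
#' @param seed dynamics seed.
#' @param delay_ms delay between load and recall.
#' @param n_presentations unused here (kept in the rig).
#' @return list with `trials` (data frame) and `summary`.
#' @export
recall_suite <- function(rig, space_seeds, seed = 1,
                         delay_ms = rig$net$params$protocol$delay_ms) {
  ps <- rig$ps
  n_pat <- length(ps$patterns)
  rows <- list()
  for (ss in space_seeds) {
    net <- add_neural_space(rig$net, "S1", seed = ss)
    pr <- rig$net$params$protocol
    est <- establish_projections(net, "S1", ps,
                                 seed = derive_seed(seed, paste0("est-", ss)))
    net <- est$net
    for (k in seq_len(n_pat)) {
      ld <- load_projection(net, "S1", ps, k,
        seed = derive_seed(seed, sprintf("load-%d-%d", ss, k)))
      net <- ld$net
      net <- run_delay(net, ps, delay_ms,
        seed = derive_seed(seed, sprintf("delay-%d-%d", ss, k)))$net
      rc <- recall_content(net, "S1", ps,
        seed = derive_seed(seed, sprintf("recall-%d-%d", ss, k)))
      net <- rc$net
      net <- run_rest(net, ps, pr$trial_rest_ms,
        seed = derive_seed(seed, sprintf("trialrest-%d-%d", ss, k)))$net
      sim <- similarity(rig$assemblies[[k]], rc$recalled)
      err <- recall_error(rig$decoder, rc$run, k)
      rows[[length(rows) + 1]] <- data.frame(
        space_seed = ss, pattern = k, error = err,
        retained = sim$retained_fraction, excess = sim$excess_count,
        passes = sim$passes)
    }
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       summary = list(mean_error_pct = 100 * mean(trials$error),
                      sd_error_pct = 100 * stats::sd(trials$error),
                      n_pass = sum(trials$passes), n_trials = nrow(trials)))
}

#' COPY suite
#'
#' Each trial loads a pattern into S1, copies it to S2 (recall from S1 with
#' a 100-ms additional disinhibition of S2), waits 400 ms and recalls from
#' S2; the recalled content is scored against the induction-time assembly.
#' Both spaces carry pre-created projections for all patterns.
#'
#' @param rig a [standard_rig()].
#' @param n_copies number of copy trials (patterns cycled).
#' @param seed master seed for wiring of the two spaces and dynamics.
#' @return list with `trials` and `summary`.
#' @export
copy_suite <- function(rig, n_copies = 10, seed = 1) {
  ps <- rig$ps
  n_pat <- length(ps$patterns)
  net <- add_neural_space(rig$net, "S1", seed = derive_seed(seed, "S1"))
  net <- add_neural_space(net, "S2", seed = derive_seed(seed, "S2"))
  pr <- net$params$protocol
  for (sp in c("S1", "S2"))
    net <- establish_projections(net, sp, ps,
      seed = derive_seed(seed, paste0("est-", sp)))$net
  idle <- pattern_rates(ps, "idle")
  rows <- list()
  for (trial in seq_len(n_copies)) {
    k <- ((trial - 1) %% n_pat) + 1
    phases <- list(
      sim_phase(net, 100, input = pattern_rates(ps, k), open = "S1",
                label = "load_h1"),
      sim_phase(net, 100, input = pattern_rates(ps, k), open = "S1",
                label = "load_h2"),
      sim_phase(net, 400, input = idle, label = "delay1"),
      sim_phase(net, 50, input = idle, open = "S1", close = "C",
                label = "r1_lock"),
      sim_phase(net, 150, input = idle, open = "S1", label = "r1"),
      sim_phase(net, 100, input = idle, open = c("S1", "S2"),
                label = "imprint"),
      sim_phase(net, 400, input = idle, label = "delay2"),
      sim_phase(net, 50, input = idle, open = "S2", close = "C",
                record = TRUE, label = "recall_lock"),
      sim_phase(net, 50, input = idle, open = "S2", record = TRUE,
                label = "r2_h1"),
      sim_phase(net, 100, input = idle, open = "S2", record = TRUE,
                label = "r2_h2"))
    run <- run_network(net, phases,
                       seed = derive_seed(seed, paste0("copy-", trial)))
    net <- run$net
    recalled <- identify_assembly(
      run$counts$C_E[, which(run$phases$label == "r2_h2")], 100,
      net$params$assembly_rate_thresh)
    sim <- similarity(rig$assemblies[[k]], recalled)
    err <- recall_error(rig$decoder, run, k)
    rows[[length(rows) + 1]] <- data.frame(
      trial = trial, pattern = k, error = err,
      retained = sim$retained_fraction, excess = sim$excess_count,
      passes = sim$passes)
    net <- run_rest(net, ps, pr$trial_rest_ms,
      seed = derive_seed(seed, paste0("trialrest-", trial)))$net
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       summary = list(mean_error_pct = 100 * mean(trials$error),
                      n_pass = sum(trials$passes), n_trials = nrow(trials)))
}

#' COMPARE grid
#'
#' Runs all `n x n` assignments of the patterns to the two neural spaces
#' and measures the second-phase readout activity of each comparison.  A
#' single threshold separates same from different contents when
#' `max(phase2 | same) < min(phase2 | different)`; the returned threshold is
#' the log-scale midpoint between the two groups.
#'
#' @param rig a [standard_rig()].
#' @param seed master seed.
#' @return list with `trials`, `threshold`, `separates` and error counts.
#' @export
compare_grid <- function(rig, seed = 1) {
  ps <- rig$ps
  n_pat <- length(ps$patterns)
  net <- add_neural_space(rig$net, "S1", seed = derive_seed(seed, "S1"))
  net <- add_neural_space(net, "S2", seed = derive_seed(seed, "S2"))
  net <- add_readout(net, seed = derive_seed(seed, "readout"))
  for (sp in c("S1", "S2"))
    net <- establish_projections(net, sp, ps,
      seed = derive_seed(seed, paste0("est-", sp)))$net
  base <- net # snapshot: every comparison starts from the same state
  rows <- list()
  for (i in seq_len(n_pat)) for (j in seq_len(n_pat)) {
    ct <- compare_trial(base, i, j, ps,
                        seed = derive_seed(seed, sprintf("cmp-%d-%d", i, j)))
    rows[[length(rows) + 1]] <- data.frame(
      i = i, j = j, same = ct$same, phase1 = ct$phase1, phase2 = ct$phase2)
  }
  trials <- do.call(rbind, rows)
  hi_same <- max(trials$phase2[trials$same])
  lo_diff <- min(trials$phase2[!trials$same])
  eps <- 1e-9
  thr <- exp((log(hi_same + eps) + log(lo_diff + eps)) / 2)
  verdict_same <- trials$phase2 < thr
  list(trials = trials, threshold = thr,
       separates = hi_same < lo_diff,
       n_errors = sum(verdict_same != trials$same))
}

# ---------------------------------------------------------------------------
# Role-binding experiments
# ---------------------------------------------------------------------------

#' Set up the two-role network for the sentence experiments
#'
#' Adds agent and patient spaces to a trained content space and creates
#' projections for every pattern in both.
#'
#' @param rig a [standard_rig()].
#' @param seed master seed.
#' @export
roles_rig <- function(rig, seed = 1) {
  ps <- rig$ps
  net <- add_neural_space(rig$net, "Sagent", seed = derive_seed(seed, "Sagent"))
  net <- add_neural_space(net, "Spatient", seed = derive_seed(seed, "Spatient"))
  projections <- list()
  for (sp in c("Sagent", "Spatient")) {
    est <- establish_projections(net, sp, ps,
      seed = derive_seed(seed, paste0("est-", sp)))
    net <- est$net
    projections[[sp]] <- est$projections
  }
  list(net = net, ps = ps, rig = rig, projections = projections)
}

# present one two-word sentence; words 200 ms each, no pause; the role space
# of each word is disinhibited during its word.  Returns the recorded run
# plus which word window each role space was open in.
present_sentence <- function(net, ps, words, roles, seed, word_ms = 200) {
  stopifnot(length(words) == 2, length(roles) == 2)
  sp <- c(agent = "Sagent", patient = "Spatient")
  phases <- list(
    sim_phase(net, word_ms, input = pattern_rates(ps, words[1]),
              open = sp[[roles[1]]], record = TRUE, label = "word1"),
    sim_phase(net, word_ms, input = pattern_rates(ps, words[2]),
              open = sp[[roles[2]]], record = TRUE, label = "word2"))
  out <- run_network(net, phases, seed)
  out$open_phase <- stats::setNames(match(c("agent", "patient"), roles),
                                    c("Sagent", "Spatient"))
  out
}

# voxel features of one presented sentence: per space, 5 noisy voxel values
# from the filtered activity with the first `discard_ms` of each word
# dropped.  A neural space is read out during the word for which it was
# disinhibited; the content space is read over both words.
sentence_features <- function(run, spaces_n, partitions, discard_ms = 50,
                              noise_var = 5, seed = 1, word_ms = 200) {
  starts <- run$phases$start_ms
  feats <- c()
  for (sp in names(partitions)) {
    spikes <- run$spikes[run$spikes$pop == paste0(sp, "_E"), ]
    wins <- if (!is.null(run$open_phase) && sp %in% names(run$open_phase))
      run$open_phase[[sp]] else seq_along(starts)
    tr <- do.call(rbind, lapply(wins, function(wi)
      lowpass_traces(spikes, spaces_n[[sp]], starts[wi] + discard_ms,
                     starts[wi] + word_ms - 1)))
    v <- voxelize(tr, partitions[[sp]], noise_var,
                  seed = derive_seed(seed, paste0("noise-", sp)))
    names(v) <- paste0(sp, "_v", seq_along(v))
    feats <- c(feats, v)
  }
  feats
}

#' Sentence-meaning decoding from voxelized signals
#'
#' Presents the four two-word sentences (agent/patient in both orders for
#' the two words) twice; trains a linear classifier for the sentence
#' meaning (which word is the agent) on 5-voxel noisy signals from the two
#' neural spaces of the first presentation and tests on the second.  A
#' control classifier uses content-space voxels instead.
#'
#' @param rr a [roles_rig()].
#' @param seed master seed.
#' @param noise_var voxel noise variance.
#' @return list with `error_neural_pct`, `error_content_pct`, and the
#'   feature data frame.
#' @export
sentence_meaning_experiment <- function(rr, seed = 1, noise_var = 5) {
  net <- rr$net; ps <- rr$ps
  sentences <- list( # words (truck = 1, ball = 2) in presentation order
    S1 = list(words = c(1, 2), roles = c("agent", "patient"), class = 0),
    S2 = list(words = c(2, 1), roles = c("patient", "agent"), class = 0),
    S3 = list(words = c(1, 2), roles = c("patient", "agent"), class = 1),
    S4 = list(words = c(2, 1), roles = c("agent", "patient"), class = 1))
  nS <- net$params$n_neural
  parts <- list(
    Sagent = voxel_partition(nS, 5, derive_seed(seed, "vox-agent")),
    Spatient = voxel_partition(nS, 5, derive_seed(seed, "vox-patient")),
    C = voxel_partition(net$params$n_content, 5, derive_seed(seed, "vox-C")))
  spaces_n <- list(Sagent = nS, Spatient = nS, C = net$params$n_content)
  rows <- list()
  for (rep in 1:2) for (sn in names(sentences)) {
    s <- sentences[[sn]]
    run <- present_sentence(net, ps, s$words, s$roles,
      seed = derive_seed(seed, sprintf("sent-%s-%d", sn, rep)))
    net <- run$net
    # locked rest between sentences so the excitability traces of one
    # sentence's projections decay before the next is processed
    net <- run_rest(net, ps, net$params$protocol$trial_rest_ms,
      derive_seed(seed, sprintf("sentidle-%s-%d", sn, rep)))$net
    f <- sentence_features(run, spaces_n, parts, noise_var = noise_var,
      seed = derive_seed(seed, sprintf("feat-%s-%d", sn, rep)))
    rows[[length(rows) + 1]] <-
      c(list(sentence = sn, rep = rep, class = s$class), as.list(f))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  neural_cols <- grep("^S(agent|patient)_v", names(df))
  content_cols <- grep("^C_v", names(df))
  train <- df$rep == 1
  err <- function(cols) {
    dec <- train_decoder(as.matrix(df[train, cols]), df$class[train],
                         lambda = 1e-2)
    100 * mean(classify(dec, as.matrix(df[!train, cols])) !=
                 as.character(df$class[!train]))
  }
  list(error_neural_pct = err(neural_cols),
       error_content_pct = err(content_cols),
       features = df)
}

#' Agent/patient identity decoding over all two-word sentences
#'
#' Considers every ordered assignment of two distinct items to the agent
#' and patient roles, presented in both word orders (40 sentences for five
#' items).  Identity decoders for each role are trained on the voxel
#' signals of that role's space from sentences whose unordered item pair
#' never occurs in the test set.
#'
#' @param rr a [roles_rig()].
#' @param seed master seed.
#' @param noise_var voxel noise variance.
#' @return list with per-role test errors (percent) and the feature table.
#' @export
role_identity_experiment <- function(rr, seed = 1, noise_var = 5) {
  net <- rr$net; ps <- rr$ps
  n_pat <- length(ps$patterns)
  combos <- list()
  for (a in seq_len(n_pat)) for (p in seq_len(n_pat)) {
    if (a == p) next
    for (ord in c("agent_first", "patient_first"))
      combos[[length(combos) + 1]] <- list(agent = a, patient = p, ord = ord)
  }
  nS <- net$params$n_neural
  parts <- list(
    Sagent = voxel_partition(nS, 5, derive_seed(seed, "vox-agent")),
    Spatient = voxel_partition(nS, 5, derive_seed(seed, "vox-patient")))
  spaces_n <- list(Sagent = nS, Spatient = nS)
  rows <- list()
  for (ci in seq_along(combos)) {
    cb <- combos[[ci]]
    first_agent <- cb$ord == "agent_first"
    words <- if (first_agent) c(cb$agent, cb$patient) else c(cb$patient, cb$agent)
    roles <- if (first_agent) c("agent", "patient") else c("patient", "agent")
    run <- present_sentence(net, ps, words, roles,
      seed = derive_seed(seed, paste0("ident-", ci)))
    net <- run$net
    net <- run_rest(net, ps, net$params$protocol$trial_rest_ms,
      derive_seed(seed, paste0("identidle-", ci)))$net
    f <- sentence_features(run, spaces_n, parts, noise_var = noise_var,
                           seed = derive_seed(seed, paste0("identf-", ci)))
    rows[[length(rows) + 1]] <- c(list(agent = cb$agent, patient = cb$patient,
      pair = paste(sort(c(cb$agent, cb$patient)), collapse = "-")),
      as.list(f))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  pairs <- unique(df$pair)
  test_pairs <- with_local_seed(derive_seed(seed, "split"),
                                sample(pairs, ceiling(length(pairs) / 2)))
  test <- df$pair %in% test_pairs
  err_for <- function(space, label_col) {
    cols <- grep(paste0("^", space, "_v"), names(df))
    dec <- train_decoder(as.matrix(df[!test, cols]), df[[label_col]][!test],
                         lambda = 1e-2)
    100 * mean(classify(dec, as.matrix(df[test, cols])) !=
                 as.character(df[[label_col]][test]))
  }
  list(error_agent_pct = err_for("Sagent", "agent"),
       error_patient_pct = err_for("Spatient", "patient"),
       features = df)
}

# ---------------------------------------------------------------------------
# Robustness and capacity
# ---------------------------------------------------------------------------

#' Robustness of RECALL to plasticity-parameter perturbations
#'
#' For each sample, perturbs the 20-parameter robustness subset at relative
#' SD `sigma`, rebuilds and re-trains a scaled rig (reduced induction), and
#' runs a recall suite; reports per-sample mean readout error and criterion
#' passes.
#'
#' @param sigma relative perturbation SD.
#' @param n_samples number of perturbed parameter sets.
#' @param seed master seed.
#' @param n_presentations induction presentations of the scaled suite.
#' @param space_seeds neural-space seeds per sample.
#' @param params base parameters.
#' @return list with `samples` (data frame) and `summary`.
#' @export
robustness_suite <- function(sigma, n_samples = 10, seed = 1,
                             n_presentations = 25, space_seeds = 1,
                             params = model_params()) {
  rows <- list()
  for (s in seq_len(n_samples)) {
    pp <- perturb_params(params, sigma, seed = derive_seed(seed,
                                                           paste0("pert-", s)))
    rig <- standard_rig(derive_seed(seed, paste0("rig-", s)), params = pp,
                        n_presentations = n_presentations)
    res <- recall_suite(rig,
      space_seeds = derive_seed(seed, paste0("space-", s)) + seq_along(space_seeds) - 1,
      seed = derive_seed(seed, paste0("dyn-", s)))
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, sigma = sigma,
      mean_error_pct = res$summary$mean_error_pct,
      n_pass = res$summary$n_pass, n_trials = res$summary$n_trials)
  }
  samples <- do.call(rbind, rows)
  list(samples = samples,
       summary = list(mean_error_pct = mean(samples$mean_error_pct),
                      pass_rate = sum(samples$n_pass) / sum(samples$n_trials)))
}

#' Capacity sweep over the number of stored concepts
#'
#' Induces `n_concepts` assemblies in the content space (patterns overlap
#' once more than eight concepts are stored) and measures recall
#' performance.
#'
#' @param n_concepts vector of concept counts.
#' @param seed master seed.
#' @param params model parameters.
#' @param n_presentations induction presentations per sweep point.
#' @param space_seeds neural-space seeds.
#' @return data frame with one row per concept count.
#' @export
capacity_sweep <- function(n_concepts = c(5, 30, 35, 40), seed = 1,
                           params = model_params(), n_presentations = 200,
                           space_seeds = 1) {
  rows <- list()
  for (nc in n_concepts) {
    ps <- make_patterns(nc, params, derive_seed(seed, paste0("pat-", nc)))
    rig <- standard_rig(derive_seed(seed, paste0("rig-", nc)), ps = ps,
                        params = params, n_presentations = n_presentations)
    res <- recall_suite(rig, space_seeds = space_seeds,
                        seed = derive_seed(seed, paste0("dyn-", nc)))
    rows[[length(rows) + 1]] <- data.frame(
      n_concepts = nc,
      mean_assembly_size = mean(lengths(rig$assemblies)),
      mean_error_pct = res$summary$mean_error_pct,
      pass_rate = res$summary$n_pass / res$summary$n_trials)
  }
  do.call(rbind, rows)
}
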