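# Operation protocols: assembly induction in the content space and the
# CREATE / LOAD / RECALL / COPY / COMPARE operations, expressed as
# disinhibition + stimulus schedules over the simulation engine.

#' Induce content assemblies by repeated pattern presentation
#'
#' Presents patterns drawn i.i.d. from the pattern set (`n_presentations`
#' presentations, each `present_ms` of patterned input followed by
#' `idle_ms` of idle input at the idle rate), with the content space
#' disinhibited and all neural spaces locked.  Afterwards the input and
#' content recurrent plasticity is frozen, and each pattern is probed once
#' for `present_ms`; neurons firing above the assembly threshold during the
#' second half of a probe form that pattern's assembly.
#'
#' @param net an `apnet` network (content space untrained).
#' @param ps a [make_patterns()] pattern set.
#' @param n_presentations total number of pattern presentations.
#' @param seed integer seed (presentation order and dynamics).
#' @param present_ms,idle_ms presentation and inter-presentation durations.
#' @return list with `net` (trained, plasticity frozen), `assemblies`
#'   (list of neuron index sets, one per pattern), and `probe` (the recorded
#'   probe run, used to train the content readout).
#' @export
induce_assemblies <- function(net, ps, n_presentations = 200, seed = 1,
                              present_ms = 200, idle_ms = 200) {
  n_pat <- length(ps$patterns)
  order <- with_local_seed(derive_seed(seed, "induction-order"),
                           sample.int(n_pat, n_presentations, replace = TRUE))
  phases <- list()
  for (k in order) {
    phases[[length(phases) + 1]] <- sim_phase(net, present_ms,
                                              input = pattern_rates(ps, k))
    phases[[length(phases) + 1]] <- sim_phase(net, idle_ms,
                                              input = pattern_rates(ps, "idle"))
  }
  train <- run_network(net, phases, seed = derive_seed(seed, "induction-dyn"))
  net <- freeze_content_plasticity(train$net)
  probe <- probe_assemblies(net, ps, seed = derive_seed(seed, "probe"),
                            present_ms = present_ms, idle_ms = idle_ms)
  if (any(lengths(probe$assemblies) == 0))
    stop("induction failure: a probe yielded an empty assembly")
  list(net = probe$net, assemblies = probe$assemblies, probe = probe$run)
}

#' Probe each pattern once and identify its assembly
#'
#' Each probe presentation is split into two half-phases so that the
#' assembly can be read from the second-half firing rates (strict
#' `> 50 Hz`).  Probe phases are recorded for readout training.
#'
#' @inheritParams induce_assemblies
#' @export
probe_assemblies <- function(net, ps, seed = 1, present_ms = 200,
                             idle_ms = 200) {
  n_pat <- length(ps$patterns)
  phases <- list()
  for (k in seq_len(n_pat)) {
    phases[[length(phases) + 1]] <-
      sim_phase(net, present_ms / 2, input = pattern_rates(ps, k),
                record = TRUE, label = sprintf("probe%d_h1", k))
    phases[[length(phases) + 1]] <-
      sim_phase(net, present_ms / 2, input = pattern_rates(ps, k),
                record = TRUE, label = sprintf("probe%d_h2", k))
    phases[[length(phases) + 1]] <-
      sim_phase(net, idle_ms, input = pattern_rates(ps, "idle"),
                label = sprintf("idle%d", k))
  }
  run <- run_network(net, phases, seed)
  thr <- net$params$assembly_rate_thresh
  assemblies <- lapply(seq_len(n_pat), function(k) {
    ph <- which(run$phases$label == sprintf("probe%d_h2", k))
    identify_assembly(run$counts$C_E[, ph], present_ms / 2, thr)
  })
  list(net = run$net, assemblies = assemblies, run = run)
}

#' CREATE: form an assembly projection in a neural space
#'
#' Presents one input pattern to the content space while the target neural
#' space is disinhibited; Hebbian plasticity at the feedforward, feedback
#' and recurrent synapses of the disinhibited space builds the projection.
#' The emerging assembly is measured from second-half firing rates, as in
#' the content space.
#'
#' @param net trained `apnet` network containing the target space.
#' @param space neural-space name.
#' @param ps pattern set.
#' @param pattern pattern index.
#' @param seed dynamics seed.
#' @param duration_ms presentation length (1000 for CREATE, 200 for LOAD).
#' @param record record spike events.
#' @return list with `net`, `assembly` (projection assembly in the space),
#'   `c_active` (content neurons active in the second half), `run`.
#' @export
create_projection <- function(net, space, ps, pattern, seed,
                              duration_ms = 1000, record = FALSE) {
  stopifnot(space %in% names(net$spaces))
  half <- duration_ms / 2
  phases <- list(
    sim_phase(net, half, input = pattern_rates(ps, pattern), open = space,
              record = record, label = "create_h1"),
    sim_phase(net, half, input = pattern_rates(ps, pattern), open = space,
              record = record, label = "create_h2"))
  run <- run_network(net, phases, seed)
  thr <- net$params$assembly_rate_thresh
  sE <- paste0(space, "_E")
  assembly <- identify_assembly(run$counts[[sE]][, 2], half, thr)
  if (length(assembly) == 0)
    stop("projection failure: no neuron crossed the assembly rate threshold")
  c_active <- identify_assembly(run$counts$C_E[, 2], half, thr)
  list(net = run$net, assembly = assembly, c_active = c_active, run = run)
}

#' LOAD: brief CREATE that reactivates an existing projection
#'
#' @inheritParams create_projection
#' @export
load_projection <- function(net, space, ps, pattern, seed,
                            duration_ms = 200, record = FALSE) {
  create_projection(net, space, ps, pattern, seed,
                    duration_ms = duration_ms, record = record)
}

#' Idle delay period
#'
#' Input neurons emit idle-rate activity; all neural spaces are locked (so
#' no memory is kept in recurrent activity); the content space stays
#' disinhibited.
#'
#' @param net network.
#' @param ps pattern set (for the idle rate).
#' @param delay_ms delay duration.
#' @param seed dynamics seed.
#' @export
run_delay <- function(net, ps, delay_ms = 5000, seed = 1) {
  ph <- sim_phase(net, delay_ms, input = pattern_rates(ps, "idle"),
                  close = names(Filter(function(s) s$neural, net$spaces)),
                  label = "delay")
  run_network(net, list(ph), seed)
}

#' Inter-operation rest period
#'
#' Locks every space (content space included) under idle input, resetting
#' all recurrent activity between operations while the second-scale
#' excitability traces decay.  Used between CREATE passes and between
#' recall trials; the within-trial load-recall delay uses [run_delay()],
#' which keeps the content space disinhibited.
#'
#' @param net network.
#' @param ps pattern set (for the idle rate).
#' @param rest_ms rest duration.
#' @param seed dynamics seed.
#' @export
run_rest <- function(net, ps, rest_ms, seed = 1) {
  ph <- sim_phase(net, rest_ms, input = pattern_rates(ps, "idle"),
                  close = names(net$spaces), label = "rest")
  run_network(net, list(ph), seed)
}

#' RECALL: retrieve the content bound to a neural space
#'
#' The neural space is disinhibited for `recall_ms`; during the first
#' `c_lock_ms` the content space remains locked, so that the projection
#' assembly (selected by its elevated excitability) activates first and then
#' reactivates its content assembly through the feedback synapses.  The
#' recalled content set is measured from the second half of the recall.
#'
#' @param net network with a previously loaded projection in `space`.
#' @param space neural-space name.
#' @param ps pattern set (idle input continues during recall).
#' @param seed dynamics seed.
#' @param recall_ms recall duration.
#' @param c_lock_ms initial content-space lock.
#' @param keep_open additional spaces to hold disinhibited (used by COPY).
#' @return list with `net`, `recalled` (content neurons active in the second
#'   half), `s_active` (space neurons active in the second half), `run`, and
#'   `onset_ms` (recall onset within the returned recording).
#' @export
recall_content <- function(net, space, ps, seed, recall_ms = 200,
                           c_lock_ms = 50, keep_open = character()) {
  idle <- pattern_rates(ps, "idle")
  half2 <- (recall_ms - c_lock_ms * 2) # second-half window starts at 100 ms
  phases <- list(
    sim_phase(net, c_lock_ms, input = idle, open = c(space, keep_open),
              close = "C", record = TRUE, label = "recall_lock"),
    sim_phase(net, c_lock_ms, input = idle, open = c(space, keep_open),
              record = TRUE, label = "recall_h1"),
    sim_phase(net, half2, input = idle, open = c(space, keep_open),
              record = TRUE, label = "recall_h2"))
  run <- run_network(net, phases, seed)
  thr <- net$params$assembly_rate_thresh
  recalled <- identify_assembly(run$counts$C_E[, 3], half2, thr)
  sE <- paste0(space, "_E")
  s_active <- identify_assembly(run$counts[[sE]][, 3], half2, thr)
  list(net = run$net, recalled = recalled, s_active = s_active, run = run,
       onset_ms = 0)
}

#' COPY: transfer content from one structural category to another
#'
#' Recalls the content of `src` into the content space and, while it is
#' active, disinhibits `dst` for 100 ms so that a projection for the same
#' content forms there.  The operation is verified by a later RECALL from
#' `dst`.
#'
#' @param net network with a loaded projection in `src`.
#' @param src,dst neural-space names.
#' @param ps pattern set.
#' @param seed dynamics seed.
#' @param pre_delay_ms delay before the initiating recall.
#' @return list with `net` and the initiating recall's result fields.
#' @export
copy_content <- function(net, src, dst, ps, seed, pre_delay_ms = 400) {
  idle <- pattern_rates(ps, "idle")
  phases <- list(
    sim_phase(net, pre_delay_ms, input = idle, label = "copy_delay"),
    sim_phase(net, 50, input = idle, open = src, close = "C",
              label = "copy_recall_lock"),
    sim_phase(net, 150, input = idle, open = src, label = "copy_recall"),
    sim_phase(net, 100, input = idle, open = c(src, dst),
              label = "copy_imprint"))
  run <- run_network(net, phases, seed)
  list(net = run$net, run = run)
}

#' COMPARE: test equality of the contents of two neural spaces
#'
#' Sequential recalls from `s1` then `s2` (200 ms each, content space locked
#' for the first 50 ms of each) drive a readout population connected to the
#' content space through short-term depressing synapses.  If both spaces
#' hold the same content, the readout synapses are still depressed during
#' the second recall and the response is near-absent; different contents
#' produce a second response as strong as the first.
#'
#' @param net network with readout attached (see [add_readout()]) and
#'   contents loaded into both spaces.
#' @param s1,s2 neural-space names.
#' @param ps pattern set.
#' @param seed dynamics seed.
#' @param settle_ms scoring windows start this long after each recall onset.
#' @return list with `net`, `run`, `activity` (readout population activity
#'   trace \eqn{R(t)}), and the mean first- and second-phase readout
#'   activities `phase1` / `phase2`.
#' @export
compare_recalls <- function(net, s1, s2, ps, seed, settle_ms = 50) {
  idle <- pattern_rates(ps, "idle")
  phases <- list(
    sim_phase(net, 50, input = idle, open = s1, close = "C",
              record = TRUE, label = "cmp_r1_lock"),
    sim_phase(net, 150, input = idle, open = s1, record = TRUE,
              label = "cmp_r1"),
    sim_phase(net, 50, input = idle, open = s2, close = "C",
              record = TRUE, label = "cmp_r2_lock"),
    sim_phase(net, 150, input = idle, open = s2, record = TRUE,
              label = "cmp_r2"))
  run <- run_network(net, phases, seed)
  ro <- run$spikes[run$spikes$pop == "R", ]
  tr <- lowpass_traces(ro, net$params$readout$n, 0, 400)
  act <- rowSums(tr)
  tt <- as.numeric(rownames(tr))
  list(net = run$net, run = run, activity = act, time_ms = tt,
       phase1 = mean(act[tt >= settle_ms & tt < 200]),
       phase2 = mean(act[tt >= 200 + settle_ms & tt <= 400]))
}

#' Full COMPARE trial: two loads followed by the two recalls
#'
#' Loads pattern `i` into `s1` and pattern `j` into `s2` (200 ms each, each
#' followed by 50 ms of idle input), then performs the two sequential
#' recalls with no delay.  The whole trial is one engine call, so the
#' readout's short-term depression builds up through the loads exactly as
#' it does through the recalls; the depression state is reset at the start
#' of the trial.
#'
#' @inheritParams compare_recalls
#' @param i,j pattern indices loaded into `s1` and `s2`.
#' @return as [compare_recalls()], plus `same` (whether `i == j`).
#' @export
compare_trial <- function(net, i, j, ps, seed, s1 = "S1", s2 = "S2",
                          settle_ms = 50) {
  net$groups$C_R$tm_x <- NULL
  net$groups$C_R$tm_u <- NULL
  idle <- pattern_rates(ps, "idle")
  phases <- list(
    sim_phase(net, 200, input = pattern_rates(ps, i), open = s1,
              label = "load1"),
    sim_phase(net, 50, input = idle, label = "idle1"),
    sim_phase(net, 200, input = pattern_rates(ps, j), open = s2,
              label = "load2"),
    sim_phase(net, 50, input = idle, label = "idle2"),
    sim_phase(net, 50, input = idle, open = s1, close = "C",
              record = TRUE, label = "cmp_r1_lock"),
    sim_phase(net, 150, input = idle, open = s1, record = TRUE,
              label = "cmp_r1"),
    sim_phase(net, 50, input = idle, open = s2, close = "C",
              record = TRUE, label = "cmp_r2_lock"),
    sim_phase(net, 150, input = idle, open = s2, record = TRUE,
              label = "cmp_r2"))
  run <- run_network(net, phases, seed)
  t0 <- run$phases$start_ms[run$phases$label == "cmp_r1_lock"]
  ro <- run$spikes[run$spikes$pop == "R", ]
  ro$time_ms <- ro$time_ms - t0
  tr <- lowpass_traces(ro, net$params$readout$n, 0, 400)
  act <- rowSums(tr)
  tt <- as.numeric(rownames(tr))
  list(net = run$net, run = run, activity = act, time_ms = tt,
       phase1 = mean(act[tt >= settle_ms & tt < 200]),
       phase2 = mean(act[tt >= 200 + settle_ms & tt <= 400]),
       same = i == j)
}
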