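#' Configuration of one simulated condition
#'
#' Bundles a model, integration settings and stimulus scheduling into a
#' runnable condition. `schedule_mode` is one of `"single"` (one
#' sustained stimulus episode, the mode used for all reference
#' figures), `"full"` (a 180 s sequence of brief tones at pseudo-random
#' 10–15 s intervals) or `"none"` (continuous task only, no discrete
#' stimuli).
#'
#' @param name condition label, e.g. `"seq_1_1"`.
#' @param model a [model_spec()].
#' @param settings a [simulation_settings()].
#' @param schedule_mode `"single"`, `"full"` or `"none"`.
#' @param onset stimulus onset for single mode (s).
#' @param stim_duration stimulus duration (s). Default for single mode:
#'   sustained until the end of the simulation (`Inf`); for full mode:
#'   0.333 (the tone duration).
#' @param n_trials,interval_range,seed full-sequence schedule parameters.
#' @param schedule optional explicit `"stimulus_schedule"`, overriding
#'   the mode-based construction.
#' @return An object of class `"sequence_config"`.
#' @export
sequence_config <- function(name, model = model_spec(),
                            settings = simulation_settings(),
                            schedule_mode = c("single", "full", "none"),
                            onset = 5,
                            stim_duration = NULL,
                            n_trials = 14, interval_range = c(10, 15),
                            seed = 1, schedule = NULL) {
  schedule_mode <- match.arg(schedule_mode)
  stopifnot(inherits(model, "model_spec"),
            inherits(settings, "simulation_settings"))
  if (is.null(stim_duration))
    stim_duration <- if (schedule_mode == "full") 0.333 else Inf
  structure(list(name = name, model = model, settings = settings,
                 schedule_mode = schedule_mode, onset = onset,
                 stim_duration = stim_duration, n_trials = n_trials,
                 interval_range = interval_range, seed = seed,
                 schedule = schedule),
            class = "sequence_config")
}

#' @export
print.sequence_config <- function(x, ...) {
  cat(sprintf("sequence_config '%s' (%s stimulus mode, %g s at dt=%g)\n",
              x$name, x$schedule_mode, x$settings$duration, x$settings$dt))
  print(x$model)
  invisible(x)
}

# caption on-off parameters of the eight experimental sequences
.seq_gate_params <- list(
  seq_1_0 = c(a_at = 0.25, a_pt = 0),
  seq_2_0 = c(a_at = 0.95, a_pt = 0),
  seq_0_1 = c(a_at = 0,    a_pt = 6.4),
  seq_0_2 = c(a_at = 0,    a_pt = 7.57),
  seq_1_1 = c(a_at = 0.38, a_pt = 6),
  seq_1_2 = c(a_at = 0.66, a_pt = 8.63),
  seq_2_1 = c(a_at = 1.36, a_pt = 11.5),
  seq_2_2 = c(a_at = 1.22, a_pt = 14.31)
)

#' The eight experimental sequence conditions
#'
#' Returns the catalogue of seq(AT, PT) conditions with their published
#' on-off parameters, estimated from the behavioral variability of each
#' task in each sequence. Single-task conditions zero the absent task's
#' drive amplitudes and coupling weight; conditions without an auditory
#' task carry no stimulus schedule.
#'
#' @param gate_shape gate waveform passed to every [model_spec()].
#' @param settings shared [simulation_settings()].
#' @return Named list of eight [sequence_config()]s
#'   (`seq_1_0`, ..., `seq_2_2`).
#' @examples
#' cfg <- builtin_sequences()[["seq_2_1"]]
#' cfg$model$gates
#' @export
builtin_sequences <- function(gate_shape = c("sine", "square"),
                              settings = simulation_settings()) {
  gate_shape <- match.arg(gate_shape)
  out <- lapply(names(.seq_gate_params), function(nm) {
    g <- .seq_gate_params[[nm]]
    at_level <- as.integer(substr(nm, 5, 5))
    pt_level <- as.integer(substr(nm, 7, 7))
    amp <- c(target = 1, nontarget = 1, speed = 1, direction = 1)
    b_at <- 1; b_pt <- 1
    if (at_level == 0) { amp[c("target", "nontarget")] <- 0; b_at <- 0 }
    if (pt_level == 0) { amp[c("speed", "direction")] <- 0; b_pt <- 0 }
    sequence_config(
      name = nm,
      model = model_spec(amplitude = amp, a_at = g[["a_at"]], a_pt = g[["a_pt"]],
                         b_at = b_at, b_pt = b_pt, gate_shape = gate_shape),
      settings = settings,
      schedule_mode = if (at_level == 0) "none" else "single")
  })
  names(out) <- names(.seq_gate_params)
  out
}

#' Prediction scenarios: coupling, strength and similarity manipulations
#'
#' Dual-task conditions probing the model's three control factors, all
#' run with a common on-off parameter `a_at = a_pt = 1.8`:
#' raised coupling (`B = 2`), lowered coupling (`B = 0.3`, with a 0.6
#' variant), raised drive strength of the auditory features, of the
#' tracking features, and of all features (`A = 2`), and raised
#' within-task feature similarity (auditory: frequencies 7 and 8;
#' tracking: 3.6 and 4.1).
#'
#' @param coupling_down_b weight of the lowered-coupling scenario,
#'   0.3 (default) or 0.6.
#' @param gate_shape gate waveform.
#' @param settings shared [simulation_settings()].
#' @return Named list of [sequence_config()]s.
#' @export
builtin_predictions <- function(coupling_down_b = 0.3,
                                gate_shape = c("sine", "square"),
                                settings = simulation_settings()) {
  gate_shape <- match.arg(gate_shape)
  stopifnot(coupling_down_b %in% c(0.3, 0.6))
  mk <- function(name, ...)
    sequence_config(name = name,
                    model = model_spec(a_at = 1.8, a_pt = 1.8,
                                       gate_shape = gate_shape, ...),
                    settings = settings, schedule_mode = "single")
  list(
    coupling_up   = mk("coupling_up", b_at = 2, b_pt = 2),
    coupling_down = mk("coupling_down", b_at = coupling_down_b,
                       b_pt = coupling_down_b),
    strength_at   = mk("strength_at",
                       amplitude = c(target = 2, nontarget = 2,
                                     speed = 1, direction = 1)),
    strength_pt   = mk("strength_pt",
                       amplitude = c(target = 1, nontarget = 1,
                                     speed = 2, direction = 2)),
    strength_all  = mk("strength_all",
                       amplitude = c(target = 2, nontarget = 2,
                                     speed = 2, direction = 2)),
    similarity_at = mk("similarity_at",
                       p = c(target = 7, nontarget = 8,
                             speed = 3.5, direction = 4.5)),
    similarity_pt = mk("similarity_pt",
                       p = c(target = 6, nontarget = 10,
                             speed = 3.6, direction = 4.1))
  )
}

#' Simulate a condition and summarise every unit
#'
#' Runs [run_model()], extracts the push envelope of each unit and
#' computes its harmonic RMS, variability and threshold-crossing
#' latency. Auditory units are summarised from the first stimulus onset
#' to the end of the simulation; tracking units over the full horizon
#' (the task is continuous). Without any stimulus onset all response
#' times are absent and all units use the full horizon.
#'
#' @param config a [sequence_config()].
#' @param result optional precomputed [run_model()] output for `config`.
#' @return A `"scenario_report"`: data.frame with one row per unit and
#'   columns `unit`, `rms`, `n_harmonics`, `variability`, `rt`.
#' @examples
#' run_sequence(builtin_sequences()[["seq_0_1"]])
#' @export
run_sequence <- function(config, result = NULL) {
  if (is.null(result)) result <- run_model(config)
  schedule <- attr(result, "schedule")
  onset <- if (length(schedule$onsets)) schedule$onsets[1L] else NA_real_
  threshold <- config$settings$threshold
  rows <- lapply(c("target", "nontarget", "speed", "direction"), function(u) {
    push <- extract_push(result[[u]], result$time, source_unit = u)
    at_unit <- u %in% c("target", "nontarget")
    win <- if (at_unit && !is.na(onset)) push$times >= onset
           else rep(TRUE, length(push$times))
    hr <- harmonic_rms(push$values[win])
    data.frame(unit = u,
               rms = hr$rms,
               n_harmonics = hr$n_harmonics,
               variability = push_variability(push$values[win]),
               rt = if (is.na(onset)) NA_real_
                    else response_time(push, threshold, onset))
  })
  report <- do.call(rbind, rows)
  attr(report, "config") <- config
  class(report) <- c("scenario_report", "data.frame")
  report
}

#' Difference of harmonic RMS between two conditions, per unit
#'
#' @param report_a,report_b [run_sequence()] reports (baseline and
#'   comparison).
#' @param unit one of `"target"`, `"nontarget"`, `"speed"`, `"direction"`.
#' @return `rms(report_b) - rms(report_a)` for `unit`.
#' @export
rms_increment <- function(report_a, report_b, unit) {
  get1 <- function(rep) {
    i <- match(unit, rep$unit)
    if (is.na(i)) stop("unknown unit: ", unit)
    rep$rms[i]
  }
  get1(report_b) - get1(report_a)
}

#' Recompute the headline cross-condition comparisons
#'
#' Runs the sequence catalogue and the raised-coupling prediction and
#' emits, in one table, the model's summary quantities: the target- and
#' speed-unit RMS increments from seq(1,1) to seq(1,2), the speed- and
#' target-unit RMS increments from the single-task baselines (seq(0,1),
#' seq(1,0)) to seq(1,1), the margin by which the speed unit leads all
#' other units in the raised-coupling scenario, and the two
#' model-versus-behavior correlations (simulated response times against
#' recorded mean RTs; tracking-unit push variability against recorded
#' hesitation rates).
#'
#' Fully deterministic: repeated calls give identical output.
#'
#' @param gate_shape gate waveform used throughout.
#' @param reports optional precomputed named list of
#'   [run_sequence()] reports to reuse (names `seq_1_0`, ...,
#'   `coupling_up`); missing entries are computed.
#' @return data.frame with columns `comparison`, `unit`, `value`.
#' @export
reproduce_summaries <- function(gate_shape = c("sine", "square"),
                                reports = NULL) {
  gate_shape <- match.arg(gate_shape)
  configs <- builtin_sequences(gate_shape = gate_shape)
  configs$coupling_up <- builtin_predictions(gate_shape = gate_shape)$coupling_up
  get_report <- function(nm) {
    if (!is.null(reports[[nm]])) return(reports[[nm]])
    run_sequence(configs[[nm]])
  }
  reps <- lapply(stats::setNames(nm = names(configs)), get_report)

  cu <- reps$coupling_up
  s_rms <- cu$rms[cu$unit == "speed"]
  other <- max(cu$rms[cu$unit != "speed"])

  model_rts <- vapply(.at_sequences, function(nm)
    reps[[nm]]$rt[reps[[nm]]$unit == "target"], numeric(1))
  pt_var <- vapply(.h_sequences, function(nm) {
    r <- reps[[nm]]
    mean(r$variability[r$unit %in% c("speed", "direction")])
  }, numeric(1))

  data.frame(
    comparison = c("seq_1_1 -> seq_1_2", "seq_1_1 -> seq_1_2",
                   "seq_0_1 -> seq_1_1", "seq_1_0 -> seq_1_1",
                   "coupling_up margin",
                   "rt vs behavior", "pt variability vs hesitation"),
    unit = c("target", "speed", "speed", "target", "speed", "target",
             "speed+direction"),
    value = c(rms_increment(reps$seq_1_1, reps$seq_1_2, "target"),
              rms_increment(reps$seq_1_1, reps$seq_1_2, "speed"),
              rms_increment(reps$seq_0_1, reps$seq_1_1, "speed"),
              rms_increment(reps$seq_1_0, reps$seq_1_1, "target"),
              s_rms - other,
              rt_correlation(model_rts),
              hesitation_correlation(pt_var))
  )
}

.at_sequences <- c("seq_1_0", "seq_2_0", "seq_1_1", "seq_1_2",
                   "seq_2_1", "seq_2_2")
.h_sequences <- c("seq_0_1", "seq_0_2", "seq_1_1", "seq_1_2", "seq_2_2")
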