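#' Integration and readout settings
#'
#' @param dt integration step (s); also the output sampling interval.
#' @param duration total simulated time (s).
#' @param init initial activity value `Y(0)` shared by all units
#'   ("medium level before any task starts").
#' @param init_deriv initial derivative, default 0.
#' @param threshold activation threshold applied to the push envelope.
#' @param method `"rk4"` (fixed-step 4th-order Runge-Kutta, default) or
#'   `"euler"`.
#' @param divergence_bound abort the integration with an error if any
#'   `|Y|` exceeds this bound.
#' @return An object of class `"simulation_settings"`.
#' @export
simulation_settings <- function(dt = 0.01, duration = 30, init = 0.5,
                                init_deriv = 0, threshold = 1.1,
                                method = c("rk4", "euler"),
                                divergence_bound = 1e3) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration >= dt, threshold > 0, divergence_bound > 0,
            is.finite(init), is.finite(init_deriv))
  structure(list(dt = dt, duration = duration, init = init,
                 init_deriv = init_deriv, threshold = threshold,
                 method = method, divergence_bound = divergence_bound),
            class = "simulation_settings")
}

#' Pseudo-random stimulus schedule
#'
#' Generates `n_trials` stimulus onsets separated by gaps drawn
#' uniformly from `interval_range`, reproducing the experimental design
#' of 14 auditory trials at 10–15 s pseudo-random intervals within a
#' 180 s sequence. The first onset is also drawn from `interval_range`
#' (measured from t = 0). Identical seeds give identical schedules.
#'
#' @param n_trials number of stimuli (>= 0).
#' @param interval_range length-2 numeric, `c(low, high)` inter-onset gap (s).
#' @param duration stimulus (tone) duration (s); default 0.333.
#' @param seed integer seed.
#' @param total_duration optional sequence length (s); the schedule is
#'   rejected with an error if the last stimulus would end after it.
#' @return An object of class `"stimulus_schedule"` with fields
#'   `onsets`, `duration`, `seed`.
#' @examples
#' make_stimulus_schedule(14, c(10, 15), seed = 7)
#' @export
make_stimulus_schedule <- function(n_trials, interval_range = c(10, 15),
                                   duration = 0.333, seed = 1,
                                   total_duration = NULL) {
  stopifnot(n_trials >= 0, length(interval_range) == 2L,
            interval_range[1] <= interval_range[2], duration > 0)
  onsets <- numeric(0)
  if (n_trials > 0) {
    gaps <- withr_seed(seed, stats::runif(n_trials, interval_range[1],
                                          interval_range[2]))
    onsets <- cumsum(gaps)
  }
  if (!is.null(total_duration) && length(onsets) &&
      max(onsets) + duration > total_duration)
    stop(sprintf(paste0("schedule does not fit: last stimulus ends at %.2f s ",
                        "but the sequence lasts %.2f s"),
                 max(onsets) + duration, total_duration))
  structure(list(onsets = onsets, duration = duration, seed = seed),
            class = "stimulus_schedule")
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

#' Single sustained stimulus episode
#'
#' The default mode for reproducing the reference figures: one stimulus
#' episode starting at `onset` and lasting `duration` (default: until
#' the end of the simulation; pass a finite value such as 0.333 for a
#' single brief tone).
#'
#' @param onset stimulus onset (s).
#' @param duration stimulus duration (s); `Inf` means "until the end".
#' @return An object of class `"stimulus_schedule"`.
#' @export
single_stimulus_schedule <- function(onset = 5, duration = Inf) {
  stopifnot(onset >= 0, duration > 0)
  structure(list(onsets = onset, duration = duration, seed = NA_integer_),
            class = "stimulus_schedule")
}

#' Empty schedule (no discrete stimuli)
#' @return A `"stimulus_schedule"` with no onsets.
#' @export
empty_schedule <- function() {
  structure(list(onsets = numeric(0), duration = 0.333, seed = NA_integer_),
            class = "stimulus_schedule")
}

#' Is a stimulus window open at time t?
#'
#' @param schedule a `"stimulus_schedule"`.
#' @param t time(s), scalar or vector.
#' @return Logical vector: `TRUE` where some onset satisfies
#'   `onset <= t <= onset + duration`.
#' @export
stimulus_active <- function(schedule, t) {
  if (!length(schedule$onsets)) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (o in schedule$onsets)
    out <- out | (t >= o & t <= o + schedule$duration)
  out
}

#' Fixed-step integration of an assembled system
#'
#' Integrates `system` (a derivative function `f(t, state)`, e.g. from
#' [assemble_system()]) on the uniform grid `t = 0, dt, 2 dt, ...` with
#' the method named in `settings`. Integration is delegated to
#' [deSolve::ode()]; non-finite states or excursions beyond
#' `divergence_bound` abort with a diagnostic.
#'
#' @param system derivative function `f(t, state)` returning a numeric
#'   vector of the same length as `state`.
#' @param settings a [simulation_settings()].
#' @param state0 initial state; default: all units at
#'   `(settings$init, settings$init_deriv)` (length inferred as 8).
#' @return Numeric matrix, first column `time`, then the state columns.
#' @export
integrate_system <- function(system, settings, state0 = NULL) {
  stopifnot(inherits(settings, "simulation_settings"), is.function(system))
  if (is.null(state0))
    state0 <- rep(c(settings$init, settings$init_deriv), 4L)
  stopifnot(all(is.finite(state0)))
  times <- seq(0, settings$duration, by = settings$dt)
  f <- function(t, y, parms) list(system(t, y))
  out <- deSolve::ode(y = state0, times = times, func = f, parms = NULL,
                      method = settings$method)
  out <- unclass(out)
  states <- out[, -1L, drop = FALSE]
  if (anyNA(states) || any(!is.finite(states)))
    stop("integration produced non-finite state values (divergence)")
  if (max(abs(states)) > settings$divergence_bound)
    stop(sprintf("integration diverged: |state| reached %.3g (bound %.3g)",
                 max(abs(states)), settings$divergence_bound))
  colnames(out)[1L] <- "time"
  out
}

#' Simulate one model condition
#'
#' Runs a full sequence condition: builds (or takes) a stimulus
#' schedule, assembles the coupled system, integrates it, and returns
#' the four unit trajectories on the common grid together with the
#' stimulus window mask. Deterministic given the schedule seed.
#'
#' @param config a [sequence_config()].
#' @return An object of class `"simulation_result"`: a `data.frame` with
#'   columns `time`, `stimulus`, `target`, `nontarget`, `speed`,
#'   `direction`, carrying the generating config and schedule as
#'   attributes.
#' @examples
#' res <- run_model(builtin_sequences()[["seq_1_0"]])
#' head(res)
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "sequence_config"))
  schedule <- config_schedule(config)
  system <- assemble_system(config$model, schedule)
  out <- integrate_system(system, config$settings)
  res <- data.frame(time = out[, "time"],
                    stimulus = stimulus_active(schedule, out[, "time"]),
                    target = out[, 2L],
                    nontarget = out[, 4L],
                    speed = out[, 6L],
                    direction = out[, 8L])
  attr(res, "config") <- config
  attr(res, "schedule") <- schedule
  class(res) <- c("simulation_result", "data.frame")
  res
}

# resolve the schedule implied by a sequence_config
config_schedule <- function(config) {
  if (!is.null(config$schedule)) return(config$schedule)
  switch(config$schedule_mode,
         none = empty_schedule(),
         single = single_stimulus_schedule(onset = config$onset,
                                           duration = config$stim_duration),
         full = make_stimulus_schedule(config$n_trials,
                                       config$interval_range,
                                       duration = config$stim_duration,
                                       seed = config$seed,
                                       total_duration = config$settings$duration),
         stop("unknown schedule_mode: ", config$schedule_mode))
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("simulation_result: %d samples, dt=%g s, %d stimulus window(s)\n",
              nrow(x), diff(x$time[1:2]),
              length(attr(x, "schedule")$onsets)))
  if (!is.null(cfg)) cat("  condition:", cfg$name, "\n")
  utils::str(unclass(x)[c("time", "target", "nontarget", "speed", "direction")],
             max.level = 0, give.attr = FALSE)
  invisible(x)
}
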