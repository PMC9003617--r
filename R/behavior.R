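#' Behavioral reference table
#'
#' The embedded per-sequence behavioral means of the dual-task
#' experiment the model describes: mean auditory response time (ms, with
#' standard error), hesitation rate (% of sequence duration spent
#' paused), auditory error rate (%) and tracking error rate (% of time
#' the cursor was outside the target). Cells that the design leaves
#' empty (e.g. response time in tracking-only sequences) are `NA`.
#' Read-only reference data; values are checksum-frozen in the test
#' suite.
#'
#' @return data.frame with columns `sequence`, `at`, `pt`, `rt_ms`,
#'   `rt_se`, `h_rate`, `h_se`, `at_error`, `pt_error`.
#' @examples
#' behavioral_reference()
#' @export
behavioral_reference <- function() {
  data.frame(
    sequence = c("seq_1_0", "seq_2_0", "seq_0_1", "seq_0_2",
                 "seq_1_1", "seq_1_2", "seq_2_1", "seq_2_2"),
    at = c(1L, 2L, 0L, 0L, 1L, 1L, 2L, 2L),
    pt = c(0L, 0L, 1L, 2L, 1L, 2L, 1L, 2L),
    rt_ms    = c(330, 550, NA, NA, 329, 357, 593, 629),
    rt_se    = c(7, 11, NA, NA, 7, 8, 12, 13),
    h_rate   = c(NA, NA, 4.16, 4.5, 5.08, 5.24, NA, 7.7),
    h_se     = c(NA, NA, 0.36, 0.38, 0.34, 0.41, NA, 0.52),
    at_error = c(0.29, 8.86, NA, NA, 0.57, 0.29, 9.43, 4.86),
    pt_error = c(NA, NA, 0.09, 0.21, 0.1, 0.26, 0.05, 0.24)
  )
}

#' Detect tracking hesitations (pauses)
#'
#' A hesitation is a maximal run during which the cursor stays fixed at
#' one vertical position (within `position_tol`) for strictly longer
#' than `min_duration`. Run duration is measured as the elapsed time
#' between the first and last sample of the run.
#'
#' @param trace a [synth_tracking_trace()] result, or any data.frame
#'   with `time` and `y` columns on a uniform grid.
#' @param min_duration cutoff (s); default 0.333, the tone duration.
#' @param position_tol position tolerance (cm) for "fixed"; default 0
#'   (exact equality, appropriate for synthetic traces).
#' @return data.frame with columns `start`, `duration`, one row per
#'   hesitation event, plus attribute `h_rate` (% of the trace duration
#'   spent hesitating).
#' @export
detect_hesitations <- function(trace, min_duration = 0.333, position_tol = 0) {
  stopifnot(all(c("time", "y") %in% names(trace)), min_duration > 0)
  y <- trace$y
  t <- trace$time
  n <- length(y)
  changed <- abs(diff(y)) > position_tol
  run_id <- cumsum(c(0L, as.integer(changed)))
  starts <- which(!duplicated(run_id))
  ends <- c(starts[-1L] - 1L, n)
  dur <- t[ends] - t[starts]
  keep <- dur > min_duration
  events <- data.frame(start = t[starts[keep]], duration = dur[keep])
  attr(events, "h_rate") <- 100 * sum(events$duration) / (t[n] - t[1L])
  events
}

#' Tracking error rate
#'
#' Percentage of samples at which the cursor lies outside the target:
#' `|y - target_y| > target_halfwidth`.
#'
#' @param trace a data.frame with `y`, `target_y` columns and a
#'   `target_halfwidth` attribute or column.
#' @param target_halfwidth half the target's vertical extent (cm);
#'   default taken from the trace.
#' @return Percentage in `[0, 100]`.
#' @export
pt_error_rate <- function(trace, target_halfwidth = attr(trace, "target_halfwidth")) {
  stopifnot(all(c("y", "target_y") %in% names(trace)),
            is.numeric(target_halfwidth), target_halfwidth >= 0)
  100 * mean(abs(trace$y - trace$target_y) > target_halfwidth)
}

# published force-function parameter sets (cm/s and cm)
.pt_speeds <- c(3.62, 4.57, 5.17, 5.5, 6.72)
.pt_amplitudes <- c(2.1, 2.7, 3, 3.3, 3.9)

#' Synthetic pursuit-tracking trace
#'
#' Emulates the vertical pursuit-tracking task: the target follows a
#' pseudo-sinusoidal path made of constant-speed segments, each segment
#' running to a randomly drawn amplitude (from the published set
#' 2.1–3.9 cm) at a randomly drawn speed (from the published set
#' 3.62–6.72 cm/s), alternating direction at every peak. The cursor
#' follows the target with a configurable lag and additive Gaussian
#' jitter. Pauses listed in `inject_pauses` freeze the cursor's
#' vertical position exactly, for round-trip testing of
#' [detect_hesitations()].
#'
#' @param seed integer seed; identical seeds give identical traces.
#' @param duration trace length (s).
#' @param dt sampling interval (s), default 0.01.
#' @param inject_pauses optional list of `c(start, length)` pairs (s);
#'   overlapping pauses are rejected.
#' @param lag cursor lag behind the target (s).
#' @param noise_sd cursor jitter (cm); 0 gives a noiseless follower.
#' @param difficulty `"easy"` (target 4x cursor size) or `"hard"` (3x);
#'   sets the stored target half-width (cursor square is 2.6 mm).
#' @return data.frame (`time`, `y`, `target_y`) with attributes
#'   `target_halfwidth` (cm) and `seed`.
#' @examples
#' tr <- synth_tracking_trace(seed = 1, duration = 20,
#'                            inject_pauses = list(c(4, 0.4)))
#' nrow(detect_hesitations(tr))
#' @export
synth_tracking_trace <- function(seed = 1, duration = 60, dt = 0.01,
                                 inject_pauses = NULL, lag = 0.1,
                                 noise_sd = 0.02,
                                 difficulty = c("easy", "hard")) {
  difficulty <- match.arg(difficulty)
  stopifnot(duration > 0, dt > 0, lag >= 0, noise_sd >= 0)
  times <- seq(0, duration, by = dt)
  n <- length(times)

  if (!is.null(inject_pauses)) {
    pm <- do.call(rbind, lapply(inject_pauses, function(p) {
      stopifnot(length(p) == 2L, p[1L] >= 0, p[2L] > 0,
                p[1L] + p[2L] <= duration)
      p
    }))
    pm <- pm[order(pm[, 1L]), , drop = FALSE]
    if (nrow(pm) > 1L &&
        any(pm[-nrow(pm), 1L] + pm[-nrow(pm), 2L] > pm[-1L, 1L]))
      stop("injected pauses overlap")
  }

  trace <- withr_seed(seed, {
    # piecewise constant-speed target path, direction alternating at peaks
    target_y <- numeric(n)
    pos <- 0; direction <- 1; i <- 1L
    while (i < n) {
      amp <- sample(.pt_amplitudes, 1L)
      speed <- sample(.pt_speeds, 1L)
      goal <- direction * amp
      seg_len <- max(1L, round(abs(goal - pos) / speed / dt))
      j <- i + seg_len
      if (j > n) {
        # truncate the final segment at the same speed
        goal <- pos + sign(goal - pos) * speed * (n - i) * dt
        j <- n
      }
      target_y[i:j] <- seq(pos, goal, length.out = j - i + 1L)
      pos <- goal
      direction <- -direction
      i <- j
    }
    lag_steps <- round(lag / dt)
    y <- c(rep(target_y[1L], lag_steps),
           target_y[seq_len(n - lag_steps)])
    if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
    list(target_y = target_y, y = y)
  })

  y <- trace$y
  if (!is.null(inject_pauses)) {
    for (k in seq_len(nrow(pm))) {
      # grid indices spanning the pause; rounding keeps grid-aligned
      # pauses exact so the detector can recover their durations
      i0 <- max(1L, round(pm[k, 1L] / dt) + 1L)
      i1 <- min(n, round((pm[k, 1L] + pm[k, 2L]) / dt) + 1L)
      y[i0:i1] <- y[i0]
    }
  }

  out <- data.frame(time = times, y = y, target_y = trace$target_y)
  attr(out, "target_halfwidth") <-
    if (difficulty == "easy") 4 * 0.26 / 2 else 3 * 0.26 / 2
  attr(out, "seed") <- seed
  out
}

#' Correlation of simulated and recorded response times
#'
#' Pearson correlation between the model's threshold-crossing latencies
#' and the recorded mean response times over the auditory-task-containing
#' sequences (seq(1,0), (2,0), (1,1), (1,2), (2,1), (2,2)).
#'
#' @param model_rts named numeric vector of model latencies; names are
#'   sequence labels (`seq_1_0`, ...). Sequences without a behavioral RT
#'   entry are ignored.
#' @param table reference table, default [behavioral_reference()].
#' @return Correlation coefficient.
#' @export
rt_correlation <- function(model_rts, table = behavioral_reference()) {
  stopifnot(!is.null(names(model_rts)))
  common <- intersect(names(model_rts),
                      table$sequence[!is.na(table$rt_ms)])
  if (length(common) < 3L)
    stop("need model RTs for at least 3 sequences with behavioral RT")
  beh <- table$rt_ms[match(common, table$sequence)]
  pearson_correlation(as.numeric(model_rts[common]), beh)
}

#' Correlation of tracking-unit variability with hesitation rates
#'
#' Pearson correlation between the per-sequence variability of the
#' tracking units' push envelopes and the recorded hesitation rates,
#' over the sequences with a recorded hesitation value. The model-side
#' quantity is the aggregate of the speed- and direction-unit push
#' standard deviations (`"mean"` by default; `"max"` and `"sum"`
#' exposed as alternatives).
#'
#' @param model_variability either a named numeric vector of
#'   already-aggregated per-sequence variabilities, or a data.frame with
#'   columns `sequence`, `speed`, `direction`.
#' @param table reference table, default [behavioral_reference()].
#' @param aggregate aggregation of the two tracking units,
#'   `"mean"` (default), `"max"` or `"sum"`.
#' @return Correlation coefficient.
#' @export
hesitation_correlation <- function(model_variability,
                                   table = behavioral_reference(),
                                   aggregate = c("mean", "max", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(model_variability)) {
    fun <- switch(aggregate, mean = function(s, d) (s + d) / 2,
                  max = pmax, sum = `+`)
    v <- stats::setNames(fun(model_variability$speed,
                             model_variability$direction),
                         model_variability$sequence)
  } else {
    v <- model_variability
  }
  stopifnot(!is.null(names(v)))
  common <- intersect(names(v), table$sequence[!is.na(table$h_rate)])
  if (length(common) < 3L)
    stop("need variabilities for at least 3 sequences with a hesitation rate")
  beh <- table$h_rate[match(common, table$sequence)]
  pearson_correlation(as.numeric(v[common]), beh)
}
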