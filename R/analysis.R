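#' Peak-envelope ("push") of an oscillatory trajectory
#'
#' The push of a signal is the pattern traced by its successive peaks:
#' strict local maxima of the trajectory are located and linearly
#' interpolated back onto the common time grid, holding the first and
#' last peak values at the edges. A trajectory with no interior maximum
#' (e.g. a monotone ramp) yields a constant envelope at its maximum
#' value.
#'
#' @param values numeric trajectory (>= 3 samples).
#' @param times time grid, same length as `values`.
#' @param source_unit optional unit label carried along.
#' @return An object of class `"push_series"`: list with `times`,
#'   `values`, `source_unit`.
#' @export
extract_push <- function(values, times, source_unit = NA_character_) {
  stopifnot(length(values) >= 3L, length(values) == length(times))
  n <- length(values)
  mid <- 2:(n - 1L)
  is_max <- values[mid] > values[mid - 1L] & values[mid] > values[mid + 1L]
  idx <- mid[is_max]
  env <- if (length(idx) == 0L) {
    rep(max(values), n)
  } else if (length(idx) == 1L) {
    rep(values[idx], n)
  } else {
    stats::approx(times[idx], values[idx], xout = times, rule = 2)$y
  }
  structure(list(times = times, values = env, source_unit = source_unit),
            class = "push_series")
}

#' @export
print.push_series <- function(x, ...) {
  cat(sprintf("push_series (%s): %d samples, range [%.4g, %.4g]\n",
              x$source_unit, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Threshold-crossing response time
#'
#' The model reaction time is the latency from stimulus onset to the
#' first instant the push envelope crosses the activation threshold from
#' below. If the push is already at or above threshold at onset the
#' latency is 0; if the threshold is never reached the response is
#' absent (`NA`).
#'
#' @param push a [extract_push()] result.
#' @param threshold activation threshold (> 0).
#' @param stimulus_onset onset time (s), inside the grid.
#' @return Latency in seconds, or `NA_real_`.
#' @export
response_time <- function(push, threshold = 1.1, stimulus_onset) {
  stopifnot(inherits(push, "push_series"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  if (stimulus_onset < min(push$times) || stimulus_onset > max(push$times))
    stop("`stimulus_onset` lies outside the time grid")
  idx <- which(push$times >= stimulus_onset)
  vals <- push$values[idx]
  if (vals[1L] >= threshold) return(0)
  hit <- which(vals >= threshold)
  if (!length(hit)) return(NA_real_)
  push$times[idx[hit[1L]]] - stimulus_onset
}

#' Harmonic-decomposition RMS of a push envelope
#'
#' Decomposes the envelope into its discrete Fourier components and
#' keeps the mean (DC) plus the `k` largest-magnitude sine harmonics,
#' with `k` the smallest value in `min_harmonics..max_harmonics` whose
#' components capture at least `energy_frac` of the non-DC spectral
#' energy (clipped to `max_harmonics` for complex signals). The RMS is
#' then \eqn{\sqrt{DC^2 + \sum_k A_k^2 / 2}}.
#'
#' @param push a [extract_push()] result, or a numeric vector (>= 16
#'   samples).
#' @param max_harmonics upper bound on harmonics used (default 8).
#' @param min_harmonics lower bound (default 3).
#' @param energy_frac spectral-energy coverage rule (default 0.95).
#' @return List with `rms` and `n_harmonics`.
#' @export
harmonic_rms <- function(push, max_harmonics = 8L, min_harmonics = 3L,
                         energy_frac = 0.95) {
  x <- if (inherits(push, "push_series")) push$values else push
  stopifnot(is.numeric(x), length(x) >= 16L,
            min_harmonics >= 1L, max_harmonics >= min_harmonics)
  n <- length(x)
  spec <- stats::fft(x) / n
  dc <- Re(spec[1L])
  n_half <- floor((n - 1L) / 2L)
  amps <- 2 * Mod(spec[2:(n_half + 1L)])
  energy <- amps^2
  total <- sum(energy)
  if (total == 0) {
    # constant signal: DC only, report the minimum harmonic count
    return(list(rms = abs(dc), n_harmonics = as.integer(min_harmonics)))
  }
  ord <- order(energy, decreasing = TRUE)
  coverage <- cumsum(energy[ord]) / total
  k <- which(coverage >= energy_frac)[1L]
  if (is.na(k)) k <- length(ord)
  k <- min(max(k, min_harmonics), max_harmonics, length(ord))
  list(rms = sqrt(dc^2 + sum(amps[ord[seq_len(k)]]^2) / 2),
       n_harmonics = as.integer(k))
}

#' Variability of a push envelope
#'
#' Population standard deviation of the envelope values over the
#' analysis window.
#'
#' @param push a [extract_push()] result or numeric vector (>= 2 samples).
#' @return Non-negative scalar.
#' @export
push_variability <- function(push) {
  x <- if (inherits(push, "push_series")) push$values else push
  stopifnot(is.numeric(x), length(x) >= 2L)
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Scale task variances onto the on-off parameter range
#'
#' Min-max rescaling of per-sequence task variances onto `[0, a_max]`,
#' the admissible range of the on-off switching parameter. Equal
#' variances (degenerate range) all map to 0.
#'
#' @param variances numeric vector (>= 1 value, all >= 0), optionally named.
#' @param a_max upper limit, default 20 (the gate saturation value).
#' @return Numeric vector of `a` values in `[0, a_max]`, order-preserving.
#' @examples
#' variance_to_onoff(c(0, 5, 10))
#' @export
variance_to_onoff <- function(variances, a_max = 20) {
  stopifnot(is.numeric(variances), length(variances) >= 1L)
  if (any(variances < 0)) stop("variances must be >= 0")
  rng <- range(variances)
  if (rng[1L] == rng[2L]) return(variances * 0)
  a_max * (variances - rng[1L]) / (rng[2L] - rng[1L])
}

#' Product-moment correlation with validation
#'
#' Standard Pearson correlation, rejecting unequal lengths, short
#' series, and zero-variance inputs (rather than returning `NA`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(x, y)
}
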