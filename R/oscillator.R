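#' Intrinsic constants of one oscillator unit
#'
#' A neural feature unit is modelled as a Van der Pol oscillator
#' \deqn{\ddot Y - (\lambda - Y^2)\dot Y + p^2 Y = F(t),}
#' where `lambda` sets the intrinsic (limit-cycle) amplitude and `p` the
#' natural frequency. In the oscillatory regime (`0 < lambda < 1`) the
#' unforced unit settles onto a limit cycle of peak amplitude close to
#' \eqn{2\sqrt\lambda}; for `lambda <= 0` activity decays to rest.
#'
#' @param lambda bifurcation parameter (dimensionless). Default 0.2, the
#'   value used for every unit in the reference scenarios.
#' @param p natural frequency, in the same numeric convention as the
#'   drive frequencies (see [model_spec()]).
#' @return An object of class `"oscillator_params"`.
#' @examples
#' oscillator_params(p = 6)
#' @export
oscillator_params <- function(lambda = 0.2, p) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(p), length(p) == 1L, is.finite(p), p > 0)
  structure(list(lambda = lambda, p = p), class = "oscillator_params")
}

#' Sinusoidal feature drive
#'
#' Each stimulus feature enters the model as a sinusoidal forcing
#' `amplitude * sin(frequency * t)`. Auditory features are *windowed*:
#' they act only while a discrete stimulus is being presented. Tracking
#' features act continuously.
#'
#' @param amplitude drive strength (dimensionless, >= 0).
#' @param frequency drive frequency (must be > 0 when `amplitude > 0`).
#' @param windowed logical; `TRUE` for stimulus-locked (auditory)
#'   features, `FALSE` for continuous (tracking) features.
#' @return An object of class `"feature_drive_spec"`.
#' @export
drive <- function(amplitude = 1, frequency, windowed = FALSE) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(frequency), length(frequency) == 1L)
  if (amplitude > 0 && frequency <= 0)
    stop("`frequency` must be > 0 when `amplitude` > 0")
  structure(list(amplitude = amplitude, frequency = frequency,
                 windowed = isTRUE(windowed)),
            class = "feature_drive_spec")
}

#' On-off attentional gate
#'
#' The time-varying gate multiplying each task's contribution to the
#' shared coupling drive. It alternates between an "on" level (1) and an
#' "off" level (0) around a midpoint of 0.5, switching with half-period
#' `1/a`; larger `a` means faster attentional switching between tasks.
#' At the saturation value `a >= 20` the gate is constantly "on"
#' (returns 1); at `a = 0` it stays at its midpoint 0.5.
#'
#' Two readings of the gate waveform are supported. The default
#' `"sine"` shape is the smooth wave `0.5 + 0.5 sin(pi * a * t)`; the
#' `"square"` shape is its hard-switching counterpart
#' `0.5 + 0.5 sgn(sin(pi * a * t))` (with `sgn(0) = 0`, so the square
#' gate passes through 0.5 at its switching instants). Both have period
#' `2/a` and half-period `1/a` and agree at `a = 0` and at saturation;
#' see `vignette("dual-task-oscillators")` for why the smooth shape is
#' the default.
#'
#' @param a switching-rate parameter, in `[0, 20]` (values above 20 are
#'   treated as saturated).
#' @param t time (s); may be a vector.
#' @param shape `"sine"` (default) or `"square"`.
#' @return Gate level(s) in `[0, 1]`, same length as `t`.
#' @examples
#' gate_value(0, 3.7)        # midpoint
#' gate_value(20, 0.123)     # saturated on
#' gate_value(1, c(0.5, 1.5))
#' @export
gate_value <- function(a, t, shape = c("sine", "square")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  if (a < 0) stop("gate parameter `a` must be >= 0")
  if (a >= 20) return(rep(1, length(t)))
  if (a == 0) return(rep(0.5, length(t)))
  s <- sin(pi * a * t)
  if (shape == "square") 0.5 + 0.5 * sign(s) else 0.5 + 0.5 * s
}

#' Summed sinusoidal forcing of a set of feature drives
#'
#' Evaluates `sum(A_i * sin(omega_i * t))` over a list of drives.
#' Windowed drives contribute zero while no stimulus is being presented.
#'
#' @param t time (s), scalar or vector.
#' @param drives list of [drive()] objects.
#' @param stimulus_active logical; whether a discrete stimulus window is
#'   currently open (scalar or vector matching `t`).
#' @return Scalar forcing value(s).
#' @export
feature_drive <- function(t, drives, stimulus_active = TRUE) {
  stopifnot(is.list(drives))
  out <- numeric(length(t))
  for (d in drives) {
    term <- d$amplitude * sin(d$frequency * t)
    if (d$windowed) term <- term * as.numeric(stimulus_active)
    out <- out + term
  }
  out
}

#' Shared coupling drive linking the two task pathways
#'
#' The coupling term received identically by all four units:
#' \deqn{B_{AT}\, g(a_{AT}, t)\, F_{AT}(t) + B_{PT}\, g(a_{PT}, t)\, F_{PT}(t),}
#' where `g` is the on-off gate ([gate_value()]) and `F_AT`, `F_PT` are
#' the summed auditory and tracking feature drives. The auditory part
#' vanishes outside stimulus windows.
#'
#' @param t time (s).
#' @param model a [model_spec()].
#' @param stimulus_active logical; whether a stimulus window is open.
#' @return Scalar coupling value(s).
#' @export
coupling_drive <- function(t, model, stimulus_active = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  at <- feature_drive(t, model$drives[c("target", "nontarget")], stimulus_active)
  pt <- feature_drive(t, model$drives[c("speed", "direction")], stimulus_active)
  model$coupling$b_at * gate_value(model$gates$a_at, t, model$gate_shape) * at +
    model$coupling$b_pt * gate_value(model$gates$a_pt, t, model$gate_shape) * pt
}

#' Time derivative of one forced Van der Pol unit
#'
#' @param state numeric vector `c(y, v)`: activity and its derivative.
#' @param params an [oscillator_params()].
#' @param forcing additive forcing on the acceleration equation.
#' @return `c(dy, dv)` with `dy = v` and
#'   `dv = (lambda - y^2) v - p^2 y + forcing`.
#' @export
unit_derivative <- function(state, params, forcing = 0) {
  stopifnot(length(state) == 2L, all(is.finite(state)), is.finite(forcing))
  y <- state[[1L]]
  v <- state[[2L]]
  c(v, (params$lambda - y^2) * v - params$p^2 * y + forcing)
}

.unit_names <- c("target", "nontarget", "speed", "direction")

#' Full model specification for the four-unit dual-task system
#'
#' Assembles the intrinsic parameters, feature drives, on-off gates and
#' coupling weights for the four units: auditory `target` and
#' `nontarget`, tracking `speed` and `direction`. All defaults are the
#' reference values of the published scenarios: `lambda = 0.2`,
#' natural/drive frequencies `(6, 10, 3.5, 4.5)`, unit drive amplitudes
#' 1 and coupling weights 1.
#'
#' Frequencies are used directly as the argument rate of `sin(omega t)`
#' and as the stiffness `p^2`; `freq_scale` rescales all of them
#' (e.g. `2*pi` for a cycles-per-second reading) for sensitivity
#' studies, preserving the resonance condition `omega = p`.
#'
#' @param lambda bifurcation parameter shared by the four units.
#' @param p named numeric vector of natural frequencies for
#'   `target`, `nontarget`, `speed`, `direction`.
#' @param omega named numeric vector of drive frequencies; defaults to `p`
#'   (resonant driving).
#' @param amplitude named numeric vector of drive strengths.
#' @param a_at,a_pt on-off gate parameters of the auditory and tracking
#'   task, each in `[0, 20]`.
#' @param b_at,b_pt coupling weights of the auditory and tracking task,
#'   each in `[0, 2]` (1 = normal interaction).
#' @param gate_shape `"sine"` (default) or `"square"`; see [gate_value()].
#' @param freq_scale multiplier applied to all `p` and `omega` values.
#' @return An object of class `"model_spec"`.
#' @examples
#' m <- model_spec(a_at = 0.38, a_pt = 6)
#' m$units$target$p
#' @export
model_spec <- function(lambda = 0.2,
                       p = c(target = 6, nontarget = 10,
                             speed = 3.5, direction = 4.5),
                       omega = p,
                       amplitude = c(target = 1, nontarget = 1,
                                     speed = 1, direction = 1),
                       a_at = 0, a_pt = 0,
                       b_at = 1, b_pt = 1,
                       gate_shape = c("sine", "square"),
                       freq_scale = 1) {
  gate_shape <- match.arg(gate_shape)
  p <- .complete_units(p, c(target = 6, nontarget = 10, speed = 3.5, direction = 4.5))
  omega <- .complete_units(omega, p)
  amplitude <- .complete_units(amplitude,
                               c(target = 1, nontarget = 1, speed = 1, direction = 1))
  stopifnot(is.numeric(freq_scale), length(freq_scale) == 1L, freq_scale > 0)
  for (nm in c("a_at", "a_pt")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || val < 0 || val > 20)
      stop("`", nm, "` must be a single value in [0, 20]")
  }
  for (nm in c("b_at", "b_pt")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || val < 0 || val > 2)
      stop("`", nm, "` must be a single value in [0, 2]")
  }
  units <- lapply(.unit_names, function(u)
    oscillator_params(lambda = lambda, p = freq_scale * p[[u]]))
  names(units) <- .unit_names
  drives <- lapply(.unit_names, function(u)
    drive(amplitude = amplitude[[u]], frequency = freq_scale * omega[[u]],
          windowed = u %in% c("target", "nontarget")))
  names(drives) <- .unit_names
  structure(list(units = units,
                 drives = drives,
                 gates = list(a_at = a_at, a_pt = a_pt),
                 coupling = list(b_at = b_at, b_pt = b_pt),
                 gate_shape = gate_shape,
                 freq_scale = freq_scale),
            class = "model_spec")
}

.complete_units <- function(x, defaults) {
  if (is.null(names(x)) && length(x) == 4L) names(x) <- .unit_names
  bad <- setdiff(names(x), .unit_names)
  if (length(bad)) stop("unknown unit name(s): ", paste(bad, collapse = ", "))
  out <- defaults
  out[names(x)] <- x
  stopifnot(all(is.finite(out)))
  out
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Dual-task oscillator model (4 units)\n")
  for (u in .unit_names) {
    cat(sprintf("  %-9s lambda=%.3g  p=%.3g  A=%.3g  omega=%.3g%s\n",
                u, x$units[[u]]$lambda, x$units[[u]]$p,
                x$drives[[u]]$amplitude, x$drives[[u]]$frequency,
                if (x$drives[[u]]$windowed) "  [windowed]" else ""))
  }
  cat(sprintf("  gates: a_at=%.3g a_pt=%.3g (%s)   coupling: b_at=%.3g b_pt=%.3g\n",
              x$gates$a_at, x$gates$a_pt, x$gate_shape,
              x$coupling$b_at, x$coupling$b_pt))
  invisible(x)
}

#' Assemble the 8-dimensional first-order system
#'
#' Builds the derivative function of the coupled four-unit system. Each
#' auditory unit receives the summed auditory drive plus the shared
#' coupling term; each tracking unit the summed tracking drive plus the
#' same coupling term — all four right-hand sides see the identical
#' coupling value at each instant. Auditory drives (direct and inside
#' the coupling) are multiplied by the stimulus-window indicator of
#' `schedule`.
#'
#' @param model a [model_spec()].
#' @param schedule a stimulus schedule, e.g. from
#'   [make_stimulus_schedule()] or [single_stimulus_schedule()].
#' @return A function `f(t, state)` returning the 8-vector of
#'   derivatives; state layout is `(y, v)` pairs in unit order
#'   target, nontarget, speed, direction.
#' @export
assemble_system <- function(model, schedule) {
  stopifnot(inherits(model, "model_spec"))
  at_drives <- model$drives[c("target", "nontarget")]
  pt_drives <- model$drives[c("speed", "direction")]
  lam <- vapply(model$units, `[[`, numeric(1), "lambda")
  p2 <- vapply(model$units, `[[`, numeric(1), "p")^2
  g <- model$gates
  b <- model$coupling
  shape <- model$gate_shape
  function(t, state) {
    active <- stimulus_active(schedule, t)
    f_at <- feature_drive(t, at_drives, active)
    f_pt <- feature_drive(t, pt_drives, TRUE)
    cpl <- b$b_at * gate_value(g$a_at, t, shape) * f_at +
      b$b_pt * gate_value(g$a_pt, t, shape) * f_pt
    y <- state[c(1L, 3L, 5L, 7L)]
    v <- state[c(2L, 4L, 6L, 8L)]
    forcing <- c(f_at, f_at, f_pt, f_pt) + cpl
    dv <- (lam - y^2) * v - p2 * y + forcing
    as.vector(rbind(v, dv))
  }
}
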