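test_that("stimulus schedules respect trial count, gaps and determinism", {
  empty <- make_stimulus_schedule(0, seed = 3)
  expect_length(empty$onsets, 0)

  s <- make_stimulus_schedule(14, c(10, 15), duration = 0.333, seed = 7,
                              total_duration = 240)
  expect_length(s$onsets, 14)
  gaps <- diff(c(0, s$onsets))
  expect_true(all(gaps >= 10 & gaps <= 15))
  s2 <- make_stimulus_schedule(14, c(10, 15), duration = 0.333, seed = 7,
                               total_duration = 240)
  expect_identical(s, s2)
  s3 <- make_stimulus_schedule(14, c(10, 15), seed = 8)
  expect_false(identical(s$onsets, s3$onsets))

  # a 14-trial schedule cannot fit into 60 s
  expect_error(make_stimulus_schedule(14, c(10, 15), seed = 1,
                                      total_duration = 60),
               "does not fit")
})

test_that("schedule generation leaves the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  make_stimulus_schedule(14, c(10, 15), seed = 7)
  expect_identical(.Random.seed, before)
})

test_that("integrator reproduces known dynamics and flags divergence", {
  settings <- simulation_settings(duration = 5)
  zero_sys <- function(t, y) rep(0, length(y))
  out <- integrate_system(zero_sys, settings, state0 = c(0, 0))
  expect_true(all(out[, -1] == 0))

  # exponential growth beyond the divergence bound is reported
  grow <- function(t, y) 10 * y
  expect_error(
    integrate_system(grow, simulation_settings(duration = 5,
                                               divergence_bound = 100),
                     state0 = c(1, 1)),
    "diverged")
})

test_that("unforced unit settles on the weakly nonlinear limit cycle", {
  lam <- 0.2
  vdp <- function(t, y) unit_derivative(y, oscillator_params(lam, p = 6), 0)
  out <- integrate_system(vdp, simulation_settings(duration = 60),
                          state0 = c(0.5, 0))
  late <- out[, "time"] >= 40
  peak <- max(out[late, 2])
  expect_equal(peak, 2 * sqrt(lam), tolerance = 0.05)
})

test_that("unit with non-positive bifurcation parameter decays to rest", {
  par <- structure(list(lambda = -0.3, p = 6), class = "oscillator_params")
  vdp <- function(t, y) unit_derivative(y, par, 0)
  out <- integrate_system(vdp, simulation_settings(duration = 40),
                          state0 = c(0.4, 0))
  expect_lt(max(abs(out[out[, "time"] >= 35, 2])), 1e-2)
})

test_that("RK4 shows fourth-order self-convergence on a smooth system", {
  vdp <- function(t, y)
    unit_derivative(y, oscillator_params(0.2, p = 3.5), sin(3.5 * t))
  run_at <- function(dt)
    integrate_system(vdp, simulation_settings(dt = dt, duration = 10),
                     state0 = c(0.5, 0))
  ref <- run_at(0.00125)
  err <- function(dt) {
    out <- run_at(dt)
    sub <- ref[seq(1, nrow(ref), by = dt / 0.00125), ]
    max(abs(out[, 2] - sub[, 2]))
  }
  ratio <- err(0.02) / err(0.01)
  expect_gt(ratio, 8)   # ~16 expected for a 4th-order method
  expect_lt(ratio, 32)
})

test_that("forward Euler integrator is available and less accurate than RK4", {
  vdp <- function(t, y) unit_derivative(y, oscillator_params(0.2, p = 3.5), 0)
  rk <- integrate_system(vdp, simulation_settings(duration = 10),
                         state0 = c(0.5, 0))
  eu <- integrate_system(vdp, simulation_settings(duration = 10,
                                                  method = "euler"),
                         state0 = c(0.5, 0))
  ref <- integrate_system(vdp, simulation_settings(dt = 0.001, duration = 10),
                          state0 = c(0.5, 0))
  ref10 <- ref[seq(1, nrow(ref), by = 10), ]
  expect_lt(max(abs(rk[, 2] - ref10[, 2])),
            max(abs(eu[, 2] - ref10[, 2])))
})

test_that("run_model is deterministic and records the stimulus mask", {
  cfg <- builtin_sequences()[["seq_1_1"]]
  r1 <- cached_result("seq_1_1")
  r2 <- run_model(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_named(r1, c("time", "stimulus", "target", "nontarget",
                     "speed", "direction"))
  expect_false(any(r1$stimulus[r1$time < 5]))
  expect_true(all(r1$stimulus[r1$time >= 5]))
  expect_true(all(is.finite(as.matrix(r1[, -2]))))
  expect_equal(unique(round(diff(r1$time), 10)), 0.01)
})

test_that("tracking-only conditions carry no stimulus and stay finite", {
  for (nm in c("seq_0_1", "seq_0_2")) {
    r <- cached_result(nm)
    expect_false(any(r$stimulus))
    expect_true(all(is.finite(r$speed)))
  }
})

test_that("pre-onset dynamics in an AT-only condition are unforced", {
  # before the stimulus window opens, every unit of seq(1,0) is an
  # unforced oscillator started at (0.5, 0)
  r <- cached_result("seq_1_0")
  vdp <- function(t, y)
    unit_derivative(y, oscillator_params(0.2, p = 6), 0)
  out <- integrate_system(vdp, simulation_settings(duration = 4.99),
                          state0 = c(0.5, 0))
  pre <- seq_len(nrow(out))   # all sampled before the 5 s onset
  expect_equal(r$target[pre], out[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("an early stimulus response is unaffected by later stimuli", {
  m <- model_spec(a_at = 0.38, a_pt = 6)
  settings <- simulation_settings(duration = 30)
  one <- sequence_config("one", m, settings,
                         schedule = structure(list(onsets = 5,
                                                   duration = 0.333,
                                                   seed = NA_integer_),
                                              class = "stimulus_schedule"))
  two <- sequence_config("two", m, settings,
                         schedule = structure(list(onsets = c(5, 20),
                                                   duration = 0.333,
                                                   seed = NA_integer_),
                                              class = "stimulus_schedule"))
  r1 <- run_model(one)
  r2 <- run_model(two)
  before <- r1$time < 20
  expect_equal(r1$target[before], r2$target[before])
  expect_false(isTRUE(all.equal(r1$target, r2$target)))
})
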