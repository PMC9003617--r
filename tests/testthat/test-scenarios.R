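test_that("sequence catalogue carries the published condition parameters", {
  seqs <- builtin_sequences()
  expect_named(seqs, c("seq_1_0", "seq_2_0", "seq_0_1", "seq_0_2",
                       "seq_1_1", "seq_1_2", "seq_2_1", "seq_2_2"))
  gate_table <- list(
    seq_1_0 = c(0.25, 0),   seq_2_0 = c(0.95, 0),
    seq_0_1 = c(0, 6.4),    seq_0_2 = c(0, 7.57),
    seq_1_1 = c(0.38, 6),   seq_1_2 = c(0.66, 8.63),
    seq_2_1 = c(1.36, 11.5), seq_2_2 = c(1.22, 14.31))
  for (nm in names(gate_table)) {
    g <- seqs[[nm]]$model$gates
    expect_equal(c(g$a_at, g$a_pt), gate_table[[nm]], info = nm)
    expect_s3_class(seqs[[nm]]$model, "model_spec")
    expect_equal(seqs[[nm]]$model$units$target$lambda, 0.2, info = nm)
    expect_equal(seqs[[nm]]$settings$threshold, 1.1, info = nm)
  }
  # single-task conditions silence the absent task entirely
  s02 <- seqs[["seq_0_2"]]$model
  expect_equal(s02$drives$target$amplitude, 0)
  expect_equal(s02$drives$nontarget$amplitude, 0)
  expect_equal(s02$coupling$b_at, 0)
  expect_identical(seqs[["seq_0_2"]]$schedule_mode, "none")
  s20 <- seqs[["seq_2_0"]]$model
  expect_equal(s20$drives$speed$amplitude, 0)
  expect_equal(s20$coupling$b_pt, 0)
  # natural and drive frequencies are the reference quadruple
  expect_equal(vapply(seqs[["seq_1_1"]]$model$units, `[[`, numeric(1), "p"),
               c(target = 6, nontarget = 10, speed = 3.5, direction = 4.5))
})

test_that("prediction catalogue encodes the three manipulations", {
  preds <- builtin_predictions()
  for (p in preds) {
    expect_equal(p$model$gates$a_at, 1.8)
    expect_equal(p$model$gates$a_pt, 1.8)
  }
  expect_equal(preds$coupling_up$model$coupling$b_at, 2)
  expect_equal(preds$coupling_up$model$coupling$b_pt, 2)
  expect_equal(preds$coupling_down$model$coupling$b_at, 0.3)
  alt <- builtin_predictions(coupling_down_b = 0.6)
  expect_equal(alt$coupling_down$model$coupling$b_pt, 0.6)
  expect_error(builtin_predictions(coupling_down_b = 1.5))

  sim_at <- preds$similarity_at$model
  expect_equal(sim_at$units$target$p, 7)
  expect_equal(sim_at$units$nontarget$p, 8)
  expect_equal(sim_at$drives$target$frequency, 7)
  expect_equal(sim_at$drives$nontarget$frequency, 8)
  sim_pt <- preds$similarity_pt$model
  expect_equal(sim_pt$units$speed$p, 3.6)
  expect_equal(sim_pt$units$direction$p, 4.1)
  expect_equal(preds$strength_at$model$drives$target$amplitude, 2)
  expect_equal(preds$strength_at$model$drives$speed$amplitude, 1)
  expect_equal(preds$strength_all$model$drives$direction$amplitude, 2)
})

test_that("scenario reports expose per-unit summaries with sensible RTs", {
  r10 <- cached_report("seq_1_0")
  expect_s3_class(r10, "scenario_report")
  expect_equal(r10$unit, c("target", "nontarget", "speed", "direction"))
  expect_true(all(r10$rms >= 0))
  expect_true(all(r10$n_harmonics >= 3 & r10$n_harmonics <= 8))

  # the target push stays below threshold before onset and crosses after
  res <- cached_result("seq_1_0")
  push <- extract_push(res$target, res$time)
  expect_lt(max(push$values[res$time < 5]), 1.1)
  rt <- r10$rt[r10$unit == "target"]
  expect_true(is.finite(rt) && rt > 0)

  # no discrete stimulus: no response time for any unit
  r01 <- cached_report("seq_0_1")
  expect_true(all(is.na(r01$rt)))

  # adding the tracking task changes the non-target summary via coupling
  r11 <- cached_report("seq_1_1")
  expect_false(isTRUE(all.equal(r11$rms[r11$unit == "nontarget"],
                                r10$rms[r10$unit == "nontarget"])))
})

test_that("rms_increment differences behave like a signed comparison", {
  a <- cached_report("seq_1_1")
  b <- cached_report("seq_1_2")
  expect_equal(rms_increment(a, a, "speed"), 0)
  expect_equal(rms_increment(a, b, "target"), -rms_increment(b, a, "target"))
  expect_gt(rms_increment(a, b, "speed"), 0)
  expect_error(rms_increment(a, b, "bogus"), "unknown unit")
})

test_that("desired-unit RMS is nondecreasing in the coupling weight", {
  rms_b <- vapply(c(0, 0.5, 1, 2), function(B) {
    cfg <- sequence_config("b_sweep",
                           model_spec(a_at = 0.38, a_pt = 6,
                                      b_at = B, b_pt = B))
    rep <- run_sequence(cfg)
    stats::setNames(rep$rms, rep$unit)[c("target", "speed", "direction")]
  }, numeric(3))
  for (u in rownames(rms_b))
    expect_true(all(diff(rms_b[u, ]) >= 0), info = u)
})

test_that("doubling all drive strengths strictly increases every unit's RMS", {
  rms_a <- vapply(c(1, 2), function(A) {
    cfg <- sequence_config("a_sweep",
                           model_spec(amplitude = c(target = A, nontarget = A,
                                                    speed = A, direction = A),
                                      a_at = 0.38, a_pt = 6))
    rep <- run_sequence(cfg)
    stats::setNames(rep$rms, rep$unit)
  }, numeric(4))
  expect_true(all(rms_a[, 2] > rms_a[, 1]))
})

test_that("moving the non-target frequency toward the target raises its RMS", {
  base <- run_sequence(sequence_config("base",
                                       model_spec(a_at = 1.8, a_pt = 1.8)))
  closer <- run_sequence(sequence_config(
    "closer",
    model_spec(a_at = 1.8, a_pt = 1.8,
               p = c(target = 6, nontarget = 8, speed = 3.5, direction = 4.5))))
  expect_gt(closer$rms[closer$unit == "nontarget"],
            base$rms[base$unit == "nontarget"])
})

test_that("summary table is complete, labeled and reproducible", {
  reports <- lapply(stats::setNames(nm = c(seq_names(), "coupling_up")),
                    cached_report)
  tab <- reproduce_summaries(reports = reports)
  expect_equal(nrow(tab), 7)
  expect_named(tab, c("comparison", "unit", "value"))
  expect_true(all(is.finite(tab$value)))
  tab2 <- reproduce_summaries(reports = reports)
  expect_identical(tab, tab2)
})
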