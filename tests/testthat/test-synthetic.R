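test_that("generate_beat honours the length contract and zero amplitudes", {
  tpl <- beat_template()
  expect_length(generate_beat(tpl, period = 1, fs = 367), 367L)
  expect_length(generate_beat(tpl, period = 0.45, fs = 367), round(0.45 * 367))
  z <- beat_template(systolic_amp = 0, diastolic_amp = 0)
  expect_equal(generate_beat(z, 1, 100), rep(0, 100))
  expect_error(generate_beat(tpl, period = 0, fs = 367), "positive")
  expect_error(generate_beat(tpl, period = 1, fs = -1), "positive")
})

test_that("beat maximum sits at the systolic centre", {
  tpl <- beat_template()
  pulse <- generate_beat(tpl, period = 1, fs = 367)
  peak_frac <- (which.max(pulse) - 1) / length(pulse)
  # oracle: argmax of the analytic two-bump sum on a dense grid
  expect_lt(abs(peak_frac - dense_template_argmax(tpl)), 1.5 / 367)
  expect_lt(abs(dense_template_argmax(tpl) - tpl$systolic_center), 0.02)
})

test_that("template and stage parameter invariants are enforced", {
  expect_error(beat_template(systolic_amp = 0.3, diastolic_amp = 0.4), "systolic_amp")
  expect_error(beat_template(systolic_width = 0), "width")
  expect_error(beat_template(systolic_center = 0.7, diastolic_center = 0.6), "center")
  expect_error(stage_params(-10, 5), "hr_mean")
  expect_error(stage_params(70, -1), "non-negative")
  expect_error(stage_params(70, 10, amp_scale = 0), "amp_scale")
})

test_that("a noiseless fixed-rate record is exactly periodic", {
  st <- stage_params(60, 0, hr_jitter_sd = 0, noise_sd = 0)
  rec <- generate_record(st, duration = 20, fs = 367, seed = 1)
  expect_length(rec$onsets, 20L)                     # 20 beats in 20 s at 60 bpm
  expect_equal(diff(rec$onsets), rep(367L, 19L))
  expect_equal(unique(aa_intervals(rec$fiducials)), 367L)
})

test_that("the same seed reproduces the identical record", {
  st <- heat_stress_stages()$E1
  r1 <- generate_record(st, seed = 42)
  r2 <- generate_record(st, seed = 42)
  expect_identical(r1$record$samples, r2$record$samples)
  expect_identical(r1$fiducials$a, r2$fiducials$a)
})

test_that("mean aa interval tracks the stage heart rate", {
  st <- stage_params(76, 0, hr_jitter_sd = 2, noise_sd = 0)
  # Monte-Carlo over seeds: aa intervals drawn around 60/76 s
  mean_aa <- vapply(1:100, function(s) {
    rec <- generate_record(st, duration = 20, fs = 367, seed = 1000 + s)
    mean(aa_intervals(rec$fiducials)) / 367
  }, numeric(1))
  expect_lt(abs(mean(mean_aa) - 60 / 76) / (60 / 76), 0.02)
})

test_that("the generator is amplitude-linear in the noiseless case", {
  st1 <- stage_params(80, 0, hr_jitter_sd = 1, noise_sd = 0, amp_scale = 1)
  st2 <- stage_params(80, 0, hr_jitter_sd = 1, noise_sd = 0, amp_scale = 2)
  r1 <- generate_record(st1, seed = 7)
  r2 <- generate_record(st2, seed = 7)
  expect_equal(r2$record$samples, 2 * r1$record$samples, tolerance = 1e-12)
})

test_that("ground-truth a waves are APG maxima of the noiseless signal", {
  st <- stage_params(90, 0, hr_jitter_sd = 2, noise_sd = 0)
  rec <- generate_record(st, seed = 11)
  proc <- process_signal(rec$record)  # noise_sd = 0: record equals clean signal
  redetected <- suppressWarnings(locate_ab_waves(proc$apg, rec$onsets))
  common <- min(length(rec$fiducials$a), length(redetected$a))
  # truth drops the two edge beats; align on the interior
  off <- match(rec$fiducials$a[1], redetected$a)
  expect_false(is.na(off))
  idx <- off:(off + rec$fiducials$n_beats - 1L)
  expect_true(all(abs(redetected$a[idx] - rec$fiducials$a) <= 2L))
})

test_that("a cohort has one record per subject and stage, reproducibly", {
  cfg <- cohort_config(n_subjects = 3, seed = 77)
  ch1 <- generate_cohort(cfg)
  expect_equal(nrow(ch1), 12L)
  expect_equal(as.vector(table(ch1$stage)), rep(3L, 4L))
  expect_false(anyDuplicated(ch1[, c("subject_id", "stage")]) > 0)
  ch2 <- generate_cohort(cohort_config(n_subjects = 3, seed = 77))
  expect_identical(
    lapply(ch1$record, function(r) r$samples),
    lapply(ch2$record, function(r) r$samples)
  )
})

test_that("cohort records are paired through subject-level effects", {
  cohort <- small_cohort()
  feats <- small_features()
  # subject amplitude factor is shared: within-subject BE energies should
  # correlate with within-subject E1 energies across subjects
  be <- feats[feats$stage == "BE", ]
  e1 <- feats[feats$stage == "E1", ]
  e1 <- e1[match(be$subject_id, e1$subject_id), ]
  expect_gt(cor(be$energy_aa_ppg, e1$energy_aa_ppg), 0.5)
})

test_that("too-short records are rejected", {
  st <- stage_params(40, 0, hr_jitter_sd = 0, noise_sd = 0)
  expect_error(generate_record(st, duration = 1, fs = 367, seed = 1), "too short")
})
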