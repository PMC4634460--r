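test_that("energy features match the direct-summation oracle on toy inputs", {
  s <- c(1, 2, 3, 4, 5)
  fid <- fiducial_set(a = c(0, 4), b = 2)
  expect_equal(energy_ab(s, fid), direct_sq_sum(s, 0, 2))          # 14
  expect_equal(energy_aa(s, fid), direct_sq_sum(s, 0, 4))          # 55
  expect_equal(energy_ba(s, fid), direct_sq_sum(s, 2, 4))          # 50
  expect_equal(energy_ab(s, fid), 14)
  expect_equal(energy_aa(s, fid), 55)
  expect_equal(energy_ba(s, fid), 50)

  s2 <- c(1, 2, 3, 0, 1, 2, 3)
  fid2 <- fiducial_set(a = c(0, 4), b = c(2, 6))
  expect_equal(energy_ab(s2, fid2), direct_sq_sum(s2, c(0, 4), c(2, 6)))  # 28

  zfid <- fiducial_set(a = c(0, 4), b = 2)
  expect_equal(energy_ab(rep(0, 5), zfid), 0)
  expect_equal(energy_aa(rep(0, 5), zfid), 0)
})

test_that("the inclusive-range identity f1 + f3 = f2 + sum S(B)^2 holds", {
  set.seed(14)
  for (r in 1:25) {
    n_beats <- sample(2:8, 1)
    a <- cumsum(sample(20:60, n_beats, replace = TRUE))
    b <- a[-n_beats] + sample(5:15, n_beats - 1, replace = TRUE)
    fid <- fiducial_set(a, b)
    s <- rnorm(max(a) + 10)
    # identity on the N-1 spans with both endpoints: each interior b sample
    # is counted in both the ab and ba pieces
    f1_part <- direct_sq_sum(s, a[-n_beats], b)
    f3 <- energy_ba(s, fid)
    f2 <- energy_aa(s, fid)
    expect_equal(f1_part + f3, f2 + sum(s[b + 1]^2), tolerance = 1e-12)
  }
})

test_that("energy preconditions are enforced", {
  s <- rnorm(50)
  expect_error(energy_aa(s, fiducial_set(a = 5, b = 10)), "at least 2")
  expect_error(energy_ba(s, fiducial_set(a = 5, b = 10)), "at least 2")
  expect_warning(out <- energy_ab(s, fiducial_set(integer(0), integer(0))), "no complete beats")
  expect_equal(out, 0)
  expect_error(energy_aa(rnorm(3), fiducial_set(a = c(0, 4), b = 2)), "outside")
})

test_that("amplitude features reproduce hand arithmetic", {
  s <- numeric(60)
  s[11] <- -1.8   # a wave at index 10 (0-based)
  s[51] <- -1.2   # b wave at index 50
  af <- amplitude_features(s, fiducial_set(a = 10, b = 50))
  expect_equal(af$amp_a, -1.8)
  expect_equal(af$amp_b, -1.2)
  expect_equal(af$ratio_ba, -1.2 / -1.8, tolerance = 1e-12)
  expect_equal(af$slope_ab, (-1.2 - (-1.8)) / 40)  # 0.015 per sample

  # equal amplitudes give zero slope; duplicated beats leave means unchanged
  s2 <- rep(0.5, 100)
  af2 <- amplitude_features(s2, fiducial_set(a = c(0, 50), b = c(20, 70)))
  expect_equal(af2$slope_ab, 0)
  expect_equal(af2$ratio_ba, 1)
  one <- amplitude_features(s2, fiducial_set(a = 0, b = 20))
  expect_equal(af2$amp_a, one$amp_a)
})

test_that("zero a-wave amplitudes are excluded from the ratio with a warning", {
  s <- c(0, 1, 2, 0.5, 1, 2, 3)
  fid <- fiducial_set(a = c(0, 3), b = c(1, 5))
  expect_warning(af <- amplitude_features(s, fid), "zero a-wave")
  expect_equal(af$ratio_ba, 2 / 0.5)  # only the second beat contributes
  expect_equal(af$amp_b, mean(c(1, 2)))  # means keep all beats
})

test_that("rmssd matches hand-computed cases", {
  expect_equal(rmssd(c(1, 1, 1) * 100, fs = 100), 0)
  expect_equal(rmssd(c(0.8, 1.0) * 100, fs = 100), 0.2)
  expect_equal(rmssd(c(0.7, 0.9, 0.7, 0.9) * 367, fs = 367), 0.2, tolerance = 1e-12)
  expect_error(rmssd(100, fs = 100), "at least 2")
  expect_error(rmssd(c(-1, 2), fs = 100), "positive")
  # literal reading: root mean square of the intervals themselves
  expect_equal(rmssd(c(0.6, 0.8) * 100, fs = 100, method = "literal"),
               sqrt(mean(c(0.6, 0.8)^2)))
})

test_that("feature extraction is homogeneous in signal scale", {
  st <- stage_params(80, 0, hr_jitter_sd = 2, noise_sd = 0)
  r1 <- generate_record(st, duration = 10, seed = 5)
  p1 <- process_signal(r1$record)
  f1v <- extract_features(p1, r1$fiducials)
  rec2 <- ppg_record(3 * r1$record$samples, r1$record$fs)
  p2 <- process_signal(rec2)
  f2v <- extract_features(p2, r1$fiducials)
  for (nm in c("energy_ab_ppg", "energy_aa_ppg", "energy_ba_ppg",
               "energy_ab_apg", "energy_aa_apg", "energy_ba_apg")) {
    expect_equal(f2v[[nm]], 9 * f1v[[nm]], tolerance = 1e-9)
  }
  for (nm in c("amp_a_ppg", "amp_b_ppg", "slope_ab_ppg", "amp_a_apg",
               "amp_b_apg", "slope_ab_apg")) {
    expect_equal(f2v[[nm]], 3 * f1v[[nm]], tolerance = 1e-9)
  }
  expect_equal(f2v$ratio_ba_ppg, f1v$ratio_ba_ppg, tolerance = 1e-9)
  expect_equal(f2v$rmssd, f1v$rmssd)
})

test_that("features ignore samples outside the annotated span", {
  set.seed(33)
  s <- rnorm(200)
  fid <- fiducial_set(a = c(20, 80, 150), b = c(45, 110))
  base <- c(energy_ab(s, fid), energy_aa(s, fid), energy_ba(s, fid),
            unlist(amplitude_features(s, fid)))
  s2 <- s
  s2[1:20] <- 99          # strictly before A[1]
  s2[152:200] <- -99      # strictly after A[N]
  mod <- c(energy_ab(s2, fid), energy_aa(s2, fid), energy_ba(s2, fid),
           unlist(amplitude_features(s2, fid)))
  expect_equal(mod, base)
})

test_that("APG polarity of synthetic records matches wave anatomy", {
  rec <- generate_record(heat_stress_stages()$BE, seed = 19)
  fv <- extract_features(process_signal(rec$record), rec$fiducials)
  expect_gt(fv$energy_aa_ppg, 0)
  expect_gt(fv$energy_ab_apg, 0)
  expect_gt(fv$amp_a_apg, 0)    # a wave above baseline
  expect_lt(fv$amp_b_apg, 0)    # b wave below baseline
  expect_lt(fv$ratio_ba_apg, 0)
  expect_lt(fv$slope_ab_apg, 0)
})

test_that("single-beat records degrade gracefully", {
  s <- rnorm(100)
  fid <- fiducial_set(a = 10, b = 40)
  proc <- structure(list(ppg_filtered = s, deriv1 = s, apg = s, fs = 100,
                         valid_range = c(3L, 98L)), class = "ppg_processed")
  expect_warning(fv <- extract_features(proc, fid), "single-beat")
  expect_true(is.na(fv$energy_aa_ppg))
  expect_true(is.na(fv$rmssd))
  expect_false(is.na(fv$energy_ab_ppg))
  expect_false(is.na(fv$amp_a_ppg))
  expect_equal(fv$n_beats_used, 1L)
})

test_that("cohort feature extraction produces the expected table", {
  feats <- small_features()
  expect_equal(nrow(feats), 32L)
  expect_true(all(ppg_feature_names() %in% names(feats)))
  expect_true(all(feats$n_beats_used >= 3))
  expect_false(anyNA(feats[, ppg_feature_names()]))
})
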