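test_that("zero-variance process yields exact uniform breaths", {
  bt <- uniform_truth()
  expect_equal(nrow(bt), 60)
  expect_true(all(bt$ttot == 5))
  expect_true(all(bt$rate == 12))
  expect_equal(bt$onset, seq(0, 295, by = 5))
})

test_that("breath sequences are deterministic given the seed", {
  sp <- eupnea_spec()
  expect_identical(simulate_breath_sequence(sp, seed = 1),
                   simulate_breath_sequence(sp, seed = 1))
  expect_false(identical(simulate_breath_sequence(sp, seed = 1),
                         simulate_breath_sequence(sp, seed = 2)))
})

test_that("symmetric timing gives unit I/E ratios", {
  sp <- breath_process_spec(mean_ti = 2, mean_te = 2, sd_ti = 0, sd_te = 0,
                            sd_amp = 0, duration = 300)
  expect_true(all(simulate_breath_sequence(sp, 1)$ie_ratio == 1))
})

test_that("ground-truth breath tables are internally consistent", {
  for (s in 1:5) {
    bt <- simulate_breath_sequence(eupnea_spec(), seed = s)
    expect_true(all(diff(bt$onset) > 0))
    expect_true(all(bt$onset < bt$peak & bt$peak < bt$offset))
    expect_equal(bt$ttot, bt$ti + bt$te)
    expect_equal(bt$rate, 60 / bt$ttot)
    # eupnea is gap-free: each breath ends where the next begins
    expect_equal(bt$onset[-1], bt$offset[-nrow(bt)], tolerance = 1e-12)
    expect_gte(max(bt$offset), 330)
  }
})

test_that("spec validation names the offending field", {
  expect_error(breath_process_spec(mean_ti = -1), "mean_ti")
  expect_error(breath_process_spec(ar1_rho = 1), "ar1_rho")
  expect_error(breath_process_spec(sd_ti = -0.1), "sd_ti")
  expect_error(breath_process_spec(duration = 0), "duration")
})

test_that("biot pattern alternates 3-5 breath clusters with 10-30 s apneas", {
  for (s in 1:5) {
    bt <- simulate_breath_sequence(
      breath_process_spec(pattern = "biot", duration = 330), seed = s)
    gaps <- bt$onset[-1] - bt$offset[-nrow(bt)]
    pauses <- gaps[gaps > 1]
    expect_gte(length(pauses), 3)
    expect_true(all(pauses >= 10 & pauses <= 30))
    cluster_sizes <- rle(cumsum(c(0, gaps > 1)))$lengths
    expect_true(all(cluster_sizes <= 5))
  }
})

test_that("rendering matches the requested sampling grid", {
  bt <- uniform_truth()
  rec <- render_acceleration(bt, fs = 10, noise_sd = 0, seed = 1)
  expect_equal(nrow(rec), 3000) # 300 s at 10 Hz
  expect_equal(attr(rec, "fs"), 10)
  # noiseless rendering: one local maximum per breath on the dominant axis
  z <- rec$az
  expect_equal(sum(diff(sign(diff(z))) == -2), 60)
  expect_error(render_acceleration(bt, fs = 0.3), "fs")
})

test_that("rendered recordings are bit-identical for the same seed", {
  bt <- simulate_breath_sequence(eupnea_spec(), seed = 2)
  r1 <- render_acceleration(bt, noise_sd = 0.05, seed = 9)
  r2 <- render_acceleration(bt, noise_sd = 0.05, seed = 9)
  expect_identical(r1, r2)
})

test_that("rendered dominant spectral peak sits at the breathing frequency", {
  bt <- uniform_truth()
  rec <- render_acceleration(bt, fs = 10, noise_sd = 0, seed = 1)
  sp <- spec.pgram(ts(rec$az - mean(rec$az), frequency = 10), taper = 0,
                   plot = FALSE, detrend = TRUE)
  f_peak <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(f_peak - 1 / 5) / (1 / 5), 0.1)
})

test_that("cohorts have the requested arms and clinical labels", {
  spec <- cohort_spec(n_patients = 6, n_controls = 5)
  coh <- simulate_cohort(spec, seed = 3, render = FALSE)
  expect_length(coh$subjects, 11)
  subj <- cohort_subjects(coh)
  expect_equal(sum(subj$group == "patient"), 6)
  expect_true(all(is.na(subj$crsr_total[subj$group == "control"])))
  expect_true(all(!is.na(subj$crsr_total[subj$group == "patient"])))
  expect_true(all(subj$crsr_total >= 0 & subj$crsr_total <= 23, na.rm = TRUE))
  expect_true(all(subj$outcome[subj$group == "patient"] %in%
                    c("improved", "unimproved")))
  feats <- cohort_features(coh)
  expect_equal(dim(feats), c(11, 37))
  # rendering on demand, deterministic
  c2 <- simulate_cohort(spec, seed = 3, render = TRUE)
  expect_s3_class(c2$subjects[[1]]$recording, "raw_recording")
  c3 <- simulate_cohort(spec, seed = 3, render = TRUE)
  expect_identical(c2$subjects[[1]]$recording, c3$subjects[[1]]$recording)
})

test_that("identical group specs give no systematic feature difference", {
  diffs <- vapply(1:40, function(s) {
    coh <- simulate_cohort(
      cohort_spec(n_patients = 8, n_controls = 8,
                  patient_spec = breath_process_spec(),
                  control_spec = breath_process_spec()),
      seed = s, render = FALSE)
    f <- cohort_features(coh)
    g <- cohort_subjects(coh)$group
    mean(f$ie_ratio_sd2[g == "patient"]) - mean(f$ie_ratio_sd2[g == "control"])
  }, 0)
  pooled_sd <- sd(diffs)
  expect_lt(abs(mean(diffs)), 2.5 * pooled_sd / sqrt(length(diffs)))
})

test_that("zero-slope outcome link recovers the intercept probability", {
  coh <- simulate_cohort(
    cohort_spec(n_patients = 400, n_controls = 1,
                outcome_link = c(intercept = 0.4)),
    seed = 5, render = FALSE)
  subj <- cohort_subjects(coh)
  frac <- mean(subj$outcome[subj$group == "patient"] == "improved")
  p_true <- plogis(0.4)
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / 400))
})

test_that("noise-free CRS-R link is exactly linear in the true features", {
  slope <- -25
  coh <- simulate_cohort(
    cohort_spec(n_patients = 10, n_controls = 1,
                crsr_link = c(intercept = 15, ie_ratio_sd2 = slope),
                crsr_noise_sd = 0),
    seed = 8, render = FALSE)
  subj <- cohort_subjects(coh)
  feats <- cohort_features(coh)
  pat <- subj$group == "patient"
  expect_equal(subj$crsr_latent[pat],
               15 + slope * feats$ie_ratio_sd2[pat], tolerance = 1e-12)
})
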