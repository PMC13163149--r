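test_that("recording CSV round-trips with validation", {
  bt <- uniform_truth()
  rec <- render_acceleration(bt, fs = 10, noise_sd = 0.02, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(nrow(back), 3000)
  expect_equal(attr(back, "fs"), 10, tolerance = 1e-6)
  expect_equal(back$az, rec$az, tolerance = 1e-9)
})

test_that("malformed recordings are rejected or repaired", {
  d <- data.frame(time = (0:999) / 10, ax = 0.1, ay = 0.2,
                  az = sin(2 * pi * 0.25 * (0:999) / 10))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[, c("time", "ax", "az")], p1, row.names = FALSE)
  expect_error(read_recording(p1), "missing column")

  p2 <- withr::local_tempfile(fileext = ".csv")
  d2 <- d
  d2$time <- sample(d2$time)
  write.csv(d2, p2, row.names = FALSE)
  expect_error(read_recording(p2), "strictly increasing")

  p3 <- withr::local_tempfile(fileext = ".csv")
  lines <- c("time,ax,ay,az",
             apply(format(d, digits = 10), 1, paste, collapse = ","))
  lines[500] <- "49.8,oops,0.2,0.1"
  writeLines(lines, p3)
  expect_warning(back <- read_recording(p3), "dropped 1")
  expect_equal(nrow(back), 999)

  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[1:200, ], p4, row.names = FALSE) # 20 s only
  expect_error(read_recording(p4), "at least 30 s")
})

test_that("axis selection picks the respiratory axis with documented tie-break", {
  t <- (0:2999) / 10
  resp <- sin(2 * pi * 0.25 * t)
  mk <- function(ax, ay, az) {
    structure(data.frame(time = t, ax = ax, ay = ay, az = az),
              fs = 10, subject_id = "t", class = c("raw_recording", "data.frame"))
  }
  noise <- withr::with_seed(1, rnorm(3000, 0, 0.01))
  expect_match(select_axis(mk(noise, noise, resp))$provenance[[1]]$axis, "az")
  # 80/20 power split between z and y still selects z
  r2 <- mk(noise, sqrt(0.2) * resp + noise, sqrt(0.8) * resp + noise)
  expect_match(select_axis(r2)$provenance[[1]]$axis, "az")
  # exact tie: lowest axis index wins
  r3 <- mk(resp, resp, resp)
  expect_match(select_axis(r3)$provenance[[1]]$axis, "ax")
})

test_that("band-pass filter has the specified frequency response", {
  t <- (0:5999) / 10
  mk_sig <- function(x) make_signal(t, x, 10)
  trim <- 300:5700
  # DC rejected
  out <- bandpass_filter(mk_sig(rep(2.5, 6000)))
  expect_lt(max(abs(out$x[trim])), 1e-8)
  # 0.25 Hz passes within 1%
  s25 <- bandpass_filter(mk_sig(sin(2 * pi * 0.25 * t)))
  expect_lt(abs(max(s25$x[trim]) - 1) , 0.01)
  # 5 Hz is not representable at fs = 10; check 2 Hz attenuation > 40 dB
  s2 <- bandpass_filter(mk_sig(sin(2 * pi * 2 * t)))
  expect_lt(max(abs(s2$x[trim])), 10^(-40 / 20))
  expect_error(bandpass_filter(mk_sig(t), low = 0.1, high = 6), "Nyquist|fs/2")
})

test_that("band-pass is zero-phase and idempotent on in-band content", {
  t <- (0:5999) / 10
  x <- sin(2 * pi * 0.25 * t)
  sig <- make_signal(t, x, 10)
  f1 <- bandpass_filter(sig)
  f2 <- bandpass_filter(f1)
  trim <- 300:5700
  # the peak nearest t = 100 s moves < 1 sample
  near <- which(t >= 98 & t <= 102)
  p_raw <- t[near][which.max(x[near])]
  p_f <- t[near][which.max(f1$x[near])]
  expect_lte(abs(p_raw - p_f), 0.1)
  # second pass changes in-band amplitude < 2%
  expect_lt(abs(max(f2$x[trim]) - max(f1$x[trim])) / max(f1$x[trim]), 0.02)
})

test_that("moving average matches direct convolution and handles edges", {
  t <- (0:99) / 10
  const <- make_signal(t, rep(4, 100), 10)
  expect_equal(moving_average(const, 0.5)$x, rep(4, 100))
  sig <- make_signal(t, sin(t), 10)
  expect_equal(moving_average(sig, 0.1)$x, sig$x) # 1-sample window
  alt <- make_signal(t, rep(c(1, -1), 50), 10)
  out <- moving_average(alt, 0.2)$x # 2-sample window
  expect_true(all(abs(out[1:99]) < 1e-12))
  expect_error(moving_average(sig, 60), "longer than the signal")
})

test_that("drift correction removes ramps and preserves clean signals", {
  t <- (0:3299) / 10
  resp <- sin(2 * pi * 0.25 * t)
  drifted <- make_signal(t, resp + 0.01 * t, 10)
  out <- correct_drift(drifted)
  expect_gt(cor(out$x, resp), 0.99)
  clean <- make_signal(t, resp, 10)
  out2 <- correct_drift(clean)
  expect_lt(max(abs(out2$x - resp)), 0.05 * IQR(resp))
  ramp <- make_signal(t, 0.02 * t, 10)
  out3 <- correct_drift(ramp)
  expect_lt(max(abs(out3$x[150:3150])), 1e-6)
})

test_that("provenance reconstructs the applied parameter chain", {
  bt <- uniform_truth()
  rec <- render_acceleration(bt, fs = 10, noise_sd = 0.02, seed = 1)
  sig <- condition_signal(rec, qc = FALSE)
  prov <- sig$provenance
  expect_equal(vapply(prov, `[[`, "", "op"),
               c("select_axis", "bandpass_filter", "moving_average",
                 "correct_drift"))
  round_trip <- jsonlite::fromJSON(jsonlite::toJSON(prov, auto_unbox = TRUE),
                                   simplifyVector = FALSE)
  expect_equal(round_trip[[2]]$low, 0.1)
  expect_equal(round_trip[[2]]$order, 4)
})

test_that("quality control flags pathological and short recordings", {
  spb <- breath_process_spec(pattern = "biot", duration = 330)
  recb <- render_acceleration(simulate_breath_sequence(spb, 3),
                              noise_sd = 0.05, seed = 3)
  qb <- quality_check(select_axis(recb))
  expect_true("biot_pattern" %in% qb$flags)
  expect_false(qb$usable)
  expect_gt(qb$apnea_fraction, 0.2)

  recc <- render_acceleration(simulate_breath_sequence(eupnea_spec(), 3),
                              noise_sd = 0.05, seed = 3)
  qc_ <- quality_check(select_axis(recc))
  expect_true(qc_$usable)
  expect_length(qc_$flags, 0)

  short <- render_acceleration(simulate_breath_sequence(
    eupnea_spec(duration = 200), 3), noise_sd = 0.05, seed = 3)
  qs <- quality_check(select_axis(short))
  expect_true("too_short" %in% qs$flags)
})
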