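# signal_processing: resampling, truncation, band-pass filtering, epoching

test_that("filter design matches its analytic frequency response", {
  f <- butter_design(4, c(0.29, 10), fs = 30, type = "band")
  # DC is a zero of the band-pass transfer function
  expect_lt(abs(filter_gain(f, 0)), 1e-12)
  # zero-phase filtering realizes |H|^2 on a long sinusoid
  tt <- seq(0, 120, by = 1 / 30)
  for (freq in c(0.5, 2, 5, 9)) {
    x <- sin(2 * pi * freq * tt)
    gain <- sqrt(mean(filtfilt(f, x)^2)) / sqrt(mean(x^2))
    expect_equal(gain, abs(filter_gain(f, freq))^2, tolerance = 2e-3)
  }
  expect_error(butter_design(4, c(0.29, 16), fs = 30, type = "band"),
               "Nyquist")
})

test_that("resampling preserves DC and pass-band amplitude, refuses upsampling", {
  rec <- make_rec(1.0, rate = 100, dur = 60)
  out <- resample_recording(rec, 30)
  expect_equal(out$sample_rate, 30)
  expect_equal(out$x, rep(1, length(out$x)), tolerance = 1e-8)

  # 5 Hz unit sinusoid survives 100 -> 30 Hz within 1 % (vs the analytic
  # sinusoid evaluated on the 30 Hz grid, interior to avoid edge transients)
  rec <- sine_rec(5, amp = 1, rate = 100, dur = 60)
  out <- resample_recording(rec, 30)
  tnew <- (seq_along(out$x) - 1) / 30
  keep <- tnew > 2 & tnew < 58
  ref <- sin(2 * pi * 5 * tnew[keep])
  expect_lt(abs(sqrt(mean(out$x[keep]^2)) / sqrt(mean(ref^2)) - 1), 0.01)
  expect_lt(max(abs(out$x[keep] - ref)), 0.02)

  # length bookkeeping: 10 s at 100 Hz -> 300 +- 1 samples at 30 Hz
  rec <- make_rec(0, rate = 100, dur = 10)
  expect_lt(abs(length(resample_recording(rec, 30)$x) - 300), 2)

  expect_error(resample_recording(rec, 200), "upsampling")
})

test_that("truncation clips into the limit and is idempotent", {
  rec <- make_rec(0, rate = 10, dur = 2)
  rec$x <- c(7.2, -6.5, rep(0.5, 18))
  out <- truncate_recording(rec, 6)
  expect_equal(out$x[1:2], c(6, -6))
  expect_equal(out$x[3:20], rep(0.5, 18))
  expect_identical(truncate_recording(out, 6)[c("x", "y", "z")],
                   out[c("x", "y", "z")])
  # values already inside the range are untouched
  rec2 <- sine_rec(1, amp = 2, rate = 30, dur = 10)
  expect_equal(truncate_recording(rec2, 6)$x, rec2$x)
})

test_that("band-pass rejects DC, keeps the pass band, kills the stop band", {
  # constant 1 g axis -> < 1 mg everywhere
  rec <- make_rec(1.0, rate = 30, dur = 120)
  out <- bandpass_recording(rec)
  expect_lt(max(abs(out$x)) * 1000, 1)

  # 5 Hz, amplitude 0.5 g: RMS within 5 % of 0.5/sqrt(2)
  rec <- sine_rec(5, amp = 0.5, rate = 30, dur = 120)
  out <- bandpass_recording(rec)
  expect_lt(abs(sqrt(mean(out$x^2)) / (0.5 / sqrt(2)) - 1), 0.05)

  # 0.05 Hz: RMS below 10 % of the input RMS
  rec <- sine_rec(0.05, amp = 0.5, rate = 30, dur = 240)
  out <- bandpass_recording(rec)
  expect_lt(sqrt(mean(out$x^2)) / sqrt(mean(rec$x^2)), 0.10)

  expect_error(bandpass_recording(make_rec(0, 30, 10), 0.29, 15), "Nyquist")
})

test_that("epoch_mg equals the brute-force norm-then-mean oracle", {
  set.seed(41)
  rec <- make_rec(0, rate = 30, dur = 33)
  rec$x <- rnorm(length(rec$x), 0, 0.05)
  rec$y <- rnorm(length(rec$y), 0, 0.08)
  rec$z <- rnorm(length(rec$z), 0, 0.02)
  ep <- epoch_mg(rec, 3)
  # independent oracle: explicit per-epoch loop
  spe <- 90
  nrm <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  oracle <- vapply(seq_len(11), function(k)
    1000 * mean(nrm[((k - 1) * spe + 1):(k * spe)]), numeric(1))
  expect_equal(ep$intensity, oracle, tolerance = 1e-9)
  expect_length(ep$intensity, 11)   # trailing partial epoch dropped
})

test_that("epoch_mg basics: zeros, constant norm, scale equivariance, errors", {
  rec <- make_rec(0, rate = 30, dur = 30)
  expect_equal(epoch_mg(rec, 3)$intensity, rep(0, 10))

  rec$x <- rep(0.1, length(rec$x))
  expect_equal(epoch_mg(rec, 3)$intensity, rep(100, 10))

  # scale equivariance through the whole filtered chain
  set.seed(7)
  base <- make_rec(0, rate = 30, dur = 30)
  base$x <- rnorm(900, 0, 0.05); base$y <- rnorm(900, 0, 0.05)
  base$z <- rnorm(900, 0, 0.05)
  fb <- bandpass_recording(base)
  for (k in c(0.5, 2, 7)) {
    scaled <- base
    for (ax in c("x", "y", "z")) scaled[[ax]] <- scaled[[ax]] * k
    fs <- bandpass_recording(scaled)
    expect_equal(epoch_mg(fs, 3)$intensity, k * epoch_mg(fb, 3)$intensity,
                 tolerance = 1e-9)
  }
  expect_error(epoch_mg(make_rec(0, rate = 0.2, dur = 60), 3), "2 samples")
})

test_that("epoch_enmo subtracts gravity and clips negatives", {
  rec <- make_rec(0, rate = 30, dur = 6)
  # ||v|| = 1 exactly at an arbitrary orientation -> 0
  u <- c(0.2, -0.5, sqrt(1 - 0.04 - 0.25))
  rec$x <- rep(u[1], 180); rec$y <- rep(u[2], 180); rec$z <- rep(u[3], 180)
  expect_equal(epoch_enmo(rec, 3)$intensity, rep(0, 2))
  # ||v|| = 1.25 -> 250 mg
  for (ax in c("x", "y", "z")) rec[[ax]] <- rec[[ax]] * 1.25
  expect_equal(epoch_enmo(rec, 3)$intensity, rep(250, 2), tolerance = 1e-9)
  # ||v|| = 0.8 -> clipped to 0
  for (ax in c("x", "y", "z")) rec[[ax]] <- rec[[ax]] / 1.25 * 0.8
  expect_equal(epoch_enmo(rec, 3)$intensity, rep(0, 2))
})

test_that("calibration window averages [165, 225) s and validates the stage", {
  tt <- seq(0, 239.5, by = 0.5)
  expect_equal(calibration_window(tt, rep(7.5, length(tt)), 0), 7.5)
  # linear ramp: mean of samples in the half-open window
  win <- calibration_window(tt, tt, 0)
  expect_equal(win, mean(seq(165, 224.5, by = 0.5)))
  expect_lt(abs(win - 195), 0.5)
  expect_error(calibration_window(tt, tt, 0, stage_duration = 200), "extends")

  # noisy plateau: recovered mean within 2 SE
  set.seed(11)
  noise_sd <- 30
  v <- 2000 + rnorm(length(tt), 0, noise_sd)
  se <- noise_sd / sqrt(sum(tt >= 165 & tt < 225))
  expect_lt(abs(calibration_window(tt, v, 0) - 2000), 2 * se)
})

test_that("recording and epoch-series containers validate their invariants", {
  expect_error(triaxial_recording(1:3, 1:2, 1:3, 100), "equal length")
  expect_error(triaxial_recording(c(1, NA), c(1, 1), c(1, 1), 100), "missing")
  expect_error(triaxial_recording(1:3, 1:3, 1:3, -5), "positive")
  expect_error(epoch_series(c(1, -2), 3), ">= 0")
  expect_error(epoch_series(1:5, 120), "epoch_length")
  expect_error(epoch_series(1:5, 3, wear = c(TRUE, FALSE)), "parallel")
})
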