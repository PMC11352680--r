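fs <- 1000
tt <- (0:999) / fs

test_that("windowing counts and truncation follow the 1 s grid", {
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      class_band_profiles = band_profile_zero(),
                      drift_coeff_scale = 0, powerline_amp = 0,
                      artifact_amp = 0, outlier_prob = 0)
  rec8 <- generate_recording(cfg, "P01", "S1", "no", 1)
  expect_length(slice_windows(rec8, preprocess_config()), 8)
  rec85 <- rec8
  rec85$samples <- cbind(rec8$samples, rec8$samples[, 1:500])
  expect_length(slice_windows(rec85, preprocess_config()), 8)
  rec05 <- rec8
  rec05$samples <- rec8$samples[, 1:500, drop = FALSE]
  expect_warning(w <- slice_windows(rec05, preprocess_config()), "shorter")
  expect_length(w, 0)
  w1 <- slice_windows(rec8, preprocess_config())[[3]]
  expect_equal(w1$provenance$window, 3)
  expect_equal(w1$stage, "raw")
})

test_that("polynomial detrend annihilates its model class", {
  tn <- seq(-1, 1, length.out = 1000)
  quartic <- 500 + 300 * tn - 200 * tn^2 + 100 * tn^3 + 50 * tn^4
  out <- detrend_poly(make_window(quartic))
  expect_lt(max(abs(out$samples)), 1e-6)
  expect_equal(out$stage, "detrended")
  zero <- detrend_poly(make_window(rep(0, 1000)))
  expect_true(all(zero$samples == 0))
  expect_error(detrend_poly(make_window(c(NA, rnorm(999)))), "finite")
  expect_error(detrend_poly(make_window(rnorm(1000)), degree = 5), "exceed 4")
})

test_that("detrend of quartic plus sinusoid deviates from the tone exactly by its polynomial projection", {
  tn <- seq(-1, 1, length.out = 1000)
  quartic <- 400 - 250 * tn + 150 * tn^2 - 90 * tn^3 + 60 * tn^4
  s <- sin(2 * pi * 50 * tt)
  out <- detrend_poly(make_window(quartic + s))
  # independent least-squares oracle: joint fit of trend + sinusoid
  B <- cbind(1, stats::poly(tn, 4))
  oracle_proj <- drop(B %*% qr.solve(B, s))
  dev <- out$samples[1, ] - s
  expect_lt(max(abs(dev + oracle_proj)), 1e-8)
  expect_lt(max(abs(dev)), 0.1)
})

test_that("zero-phase high-pass matches the closed-form squared Butterworth response", {
  # DC: gain exactly 0
  hp <- highpass_butterworth(make_window(rep(100, 1000), stage = "detrended"))
  expect_lt(max(abs(hp$samples)), 0.1)
  expect_equal(hp$stage, "highpassed")
  # 50 Hz: passband, |H(50)|^2 with fc = 10, order 4
  hp50 <- highpass_butterworth(make_window(sin(2 * pi * 50 * tt), stage = "detrended"))
  amp50 <- max(abs(hp50$samples[1, ]))
  expect_gt(amp50, 0.99)
  expect_lt(amp50, 1.01)
  u <- (50 / 10)^4
  expect_equal(amp50, (u / sqrt(1 + (50 / 10)^8))^2, tolerance = 1e-4)
  # 1 Hz: stopband, closed form ~ 1e-8
  hp1 <- highpass_butterworth(make_window(sin(2 * pi * 1 * tt), stage = "detrended"))
  expect_lt(max(abs(hp1$samples[1, ])), 1e-6)
  expect_error(
    highpass_butterworth(make_window(rnorm(1000), stage = "detrended"), cutoff = 600),
    "Nyquist")
})

test_that("broadband energy below the cutoff is attenuated per the closed form", {
  set.seed(4)
  x <- rnorm(1000, sd = 50)
  out <- highpass_butterworth(make_window(x, stage = "detrended"))
  bandpow <- function(v, lo, hi) {
    m <- Mod(stats::fft(v))[1:501]
    sum(m[(lo + 1):(hi + 1)]^2)
  }
  # zero-phase energy gain at f is |H(f)|^4; 0.25 at the 10 Hz cutoff
  expect_lt(bandpow(out$samples[1, ], 1, 10) / bandpow(x, 1, 10), 0.25)
  expect_lt(bandpow(out$samples[1, ], 1, 3) / bandpow(x, 1, 3), 1e-4)
})

test_that("adaptive notch attenuates standing harmonics and passes clean spectra", {
  cfg <- preprocess_config()
  # no spectral peak at any harmonic: output equals input
  x <- sin(2 * pi * 73 * tt)
  out <- adaptive_notch(make_window(x, stage = "highpassed"), cfg)
  expect_lt(max(abs(out$samples[1, ] - x)), 1e-9)
  expect_equal(out$stage, "notched")
  # 5x 50 Hz tone on top of a 73 Hz tone: notch kills 50, keeps 73
  y <- sin(2 * pi * 73 * tt) + 5 * sin(2 * pi * 50 * tt)
  outy <- adaptive_notch(make_window(y, stage = "highpassed"), cfg)
  my <- Mod(stats::fft(outy$samples[1, ]))
  flank <- stats::median(Mod(stats::fft(y))[c(41:49, 52:60) + 1])
  expect_lte(my[51], flank + 1e-9)
  expect_equal(my[74], 500, tolerance = 0.01)
  # two harmonics both above threshold are both pulled to their flank level
  z <- 4 * sin(2 * pi * 50 * tt) + 3 * cos(2 * pi * 150 * tt) + sin(2 * pi * 210 * tt)
  outz <- adaptive_notch(make_window(z, stage = "highpassed"), cfg)
  mz <- Mod(stats::fft(outz$samples[1, ]))
  expect_lt(mz[51], 1)
  expect_lt(mz[151], 1)
  expect_equal(mz[211], 500, tolerance = 0.01)
})

test_that("abnormal-amplitude rejection partitions without modifying samples", {
  w_keep <- make_window(rep(1999, 1000), stage = "notched")
  spike <- rep(0, 1000); spike[500] <- 2001
  w_drop <- make_window(spike, stage = "notched")
  res <- reject_abnormal(list(w_keep, w_drop), 2000)
  expect_length(res$kept, 1)
  expect_length(res$dropped, 1)
  expect_identical(res$kept[[1]]$samples, w_keep$samples)
  expect_identical(res$dropped[[1]]$samples, w_drop$samples)
  empty <- reject_abnormal(list(), 2000)
  expect_length(empty$kept, 0)
  expect_length(empty$dropped, 0)
})

test_that("full chain keeps clean windows and drops exactly the burst window", {
  cfg <- synth_config(n_participants = 1, sessions = 1, outlier_prob = 0, seed = 2)
  rec <- generate_recording(cfg, "P01", "S1", "mt", 11)
  kept <- preprocess_pipeline(rec, preprocess_config())
  expect_length(kept, 8)
  expect_true(all(vapply(kept, function(w) w$stage == "notched", logical(1))))
  # inject a 10 ms 4000 uV burst confined to window 4
  rec2 <- rec
  idx <- 3200:3209
  rec2$samples[2, idx] <- rec2$samples[2, idx] +
    4000 * sin(pi * (0:9) / 9)
  kept2 <- preprocess_pipeline(rec2, preprocess_config())
  expect_length(kept2, 7)
  log <- attr(kept2, "log")
  expect_equal(log$n_dropped, 1)
  expect_equal(log$dropped[[1]]$window, 4)
})

test_that("drift and powerline interference are removed to sub-microvolt residuals", {
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      class_band_profiles = band_profile_zero(),
                      drift_coeff_scale = 300, powerline_amp = 20,
                      powerline_harmonics = 3, artifact_amp = 0,
                      outlier_prob = 0)
  rec <- generate_recording(cfg, "P01", "S1", "no", 8)
  kept <- preprocess_pipeline(rec, preprocess_config())
  expect_length(kept, 8)
  rmss <- vapply(kept, function(w) sqrt(mean(w$samples^2)), numeric(1))
  expect_lt(max(rmss), 1)
})

test_that("the chain is idempotent on the interference it targets", {
  # deterministic interference only: a second pass has nothing left to remove
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      class_band_profiles = band_profile_zero(),
                      drift_coeff_scale = 300, powerline_amp = 20,
                      artifact_amp = 0, outlier_prob = 0)
  rec <- generate_recording(cfg, "P01", "S1", "no", 9)
  kept <- preprocess_pipeline(rec, preprocess_config())
  for (w in kept[c(1, 5)]) {
    again <- w
    again$stage <- "raw"
    again <- adaptive_notch(highpass_butterworth(detrend_poly(again)),
                            preprocess_config())
    expect_lt(max(abs(again$samples - w$samples)), 0.5)
  }
  # stochastic content: each detrend pass re-projects broadband noise onto
  # the degree-4 basis (expected sqrt(5/L) of its RMS), so the change is
  # bounded but not zero
  cfg2 <- synth_config(n_participants = 1, sessions = 1, outlier_prob = 0,
                       seed = 6)
  rec2 <- generate_recording(cfg2, "P01", "S1", "st", 3)
  kept2 <- preprocess_pipeline(rec2, preprocess_config())
  for (w in kept2[c(1, 5)]) {
    again <- w
    again$stage <- "raw"
    again <- adaptive_notch(highpass_butterworth(detrend_poly(again)),
                            preprocess_config())
    d <- again$samples - w$samples
    expect_lt(sqrt(mean(d^2)), 0.35 * sqrt(mean(w$samples^2)))
  }
})
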