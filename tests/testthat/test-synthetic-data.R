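test_that("zero-amplitude configuration yields all-zero samples", {
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      class_band_profiles = band_profile_zero(),
                      drift_coeff_scale = 0, powerline_amp = 0,
                      artifact_amp = 0, outlier_prob = 0)
  rec <- generate_recording(cfg, "P01", "S1", "sr", seed = 1)
  expect_equal(dim(rec$samples), c(6, 8000))
  expect_true(all(rec$samples == 0))
})

test_that("pure powerline component has the closed-form DFT magnitude per window", {
  A <- 3.5
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      class_band_profiles = band_profile_zero(),
                      drift_coeff_scale = 0, powerline_amp = A,
                      powerline_harmonics = 1, artifact_amp = 0, outlier_prob = 0)
  rec <- generate_recording(cfg, "P01", "S1", "no", seed = 42)
  wins <- slice_windows(rec, preprocess_config())
  for (w in wins) {
    mag <- Mod(stats::fft(w$samples[1, ]))[51]   # bin 50
    expect_equal(mag, 500 * A, tolerance = 1e-6)
  }
})

test_that("identical config, ids and seed reproduce samples bitwise", {
  cfg <- synth_config(n_participants = 2, sessions = 1, seed = 9)
  r1 <- generate_recording(cfg, "P02", "S1", "bt", seed = 77)
  r2 <- generate_recording(cfg, "P02", "S1", "bt", seed = 77)
  expect_identical(r1$samples, r2$samples)
  d1 <- generate_dataset(synth_config(n_participants = 1, sessions = 1, seed = 5))
  d2 <- generate_dataset(synth_config(n_participants = 1, sessions = 1, seed = 5))
  expect_identical(lapply(d1$recordings, `[[`, "samples"),
                   lapply(d2$recordings, `[[`, "samples"))
})

test_that("manifest enumerates the full provenance grid", {
  expect_equal(nrow(build_manifest(synth_config(n_participants = 1, sessions = 1))), 6)
  m <- build_manifest(synth_config(n_participants = 8, sessions = 4))
  expect_equal(nrow(m), 192)
  expect_equal(length(unique(paste(m$participant, m$session))), 32)
  ds <- generate_dataset(synth_config(
    n_participants = 1, sessions = 1, trial_duration = 1,
    class_band_profiles = band_profile_zero(), drift_coeff_scale = 0,
    powerline_amp = 0, artifact_amp = 0, outlier_prob = 0))
  expect_length(ds$recordings, 6)
})

test_that("zero heterogeneity gives every participant identical profiles", {
  cfg <- synth_config(n_participants = 4, sessions = 1,
                      participant_heterogeneity = 0)
  for (p in participant_ids(cfg))
    expect_equal(participant_band_multipliers(cfg, p), rep(1, 13))
  cfg2 <- synth_config(n_participants = 4, sessions = 1,
                       participant_heterogeneity = 0.5)
  m1 <- participant_band_multipliers(cfg2, "P01")
  expect_identical(m1, participant_band_multipliers(cfg2, "P01"))
  expect_false(identical(m1, participant_band_multipliers(cfg2, "P02")))
})

test_that("invalid inputs are rejected with labelled errors", {
  cfg <- synth_config(n_participants = 1, sessions = 1)
  expect_error(generate_recording(cfg, "P01", "S1", "umami", 1), "unknown taste")
  expect_error(synth_config(n_participants = 0), "participant")
  expect_error(synth_config(sessions = 0), "session")
  expect_error(synth_config(trial_duration = 0.7771, fs = 997), "integer")
  expect_error(synth_config(outlier_prob = 1.4), "outlier_prob")
  expect_error(synth_config(tastes = c("no", "xx"),
                            class_band_profiles = default_band_profiles("no")),
               "band profile")
})

test_that("mean window spectrum matches the configured band profile", {
  prof <- default_band_profiles("sr")
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      trials_per_taste_per_session = 13, tastes = "sr",
                      class_band_profiles = prof,
                      participant_heterogeneity = 0, drift_coeff_scale = 0,
                      powerline_amp = 0, artifact_amp = 0, outlier_prob = 0,
                      seed = 31)
  ds <- generate_dataset(cfg)
  wins <- unlist(lapply(ds$recordings, slice_windows), recursive = FALSE)
  expect_gte(length(wins), 100)
  B <- vapply(wins, function(w)
    band_average_features(compute_spectrum(w$samples[1, ], w$fs)), numeric(13))
  rel_err <- abs(rowMeans(B) - prof$sr) / prof$sr
  expect_true(all(rel_err < 0.05))
})

test_that("fraction of trials with a >2000 uV excursion converges to outlier_prob", {
  p <- 0.2
  cfg <- synth_config(n_participants = 1, sessions = 1,
                      trials_per_taste_per_session = 1000, tastes = "no",
                      class_band_profiles = band_profile_zero("no"),
                      n_channels = 1, trial_duration = 1,
                      drift_coeff_scale = 0, powerline_amp = 0,
                      artifact_amp = 0, outlier_prob = p, seed = 13)
  ds <- generate_dataset(cfg)
  hit <- vapply(ds$recordings, function(r) max(abs(r$samples)) > 2000, logical(1))
  se <- sqrt(p * (1 - p) / length(hit))
  expect_lt(abs(mean(hit) - p), 3 * se)
})

test_that("with zero heterogeneity, participant feature distributions are exchangeable", {
  cfg <- synth_config(n_participants = 2, sessions = 1,
                      trials_per_taste_per_session = 63, tastes = "no",
                      class_band_profiles = default_band_profiles("no"),
                      participant_heterogeneity = 0, outlier_prob = 0, seed = 41)
  ds <- generate_dataset(cfg)
  wins <- unlist(lapply(ds$recordings, slice_windows), recursive = FALSE)
  feat <- extract_feature_table(wins)
  expect_gte(min(table(feat$participant)), 500)
  cols <- feature_columns(feat)
  pvals <- vapply(cols, function(cl) {
    suppressWarnings(stats::ks.test(
      feat[[cl]][feat$participant == "P01"],
      feat[[cl]][feat$participant == "P02"])$p.value)
  }, numeric(1))
  expect_gt(min(pvals), 0.01 / length(cols))  # Bonferroni at alpha = 0.01
})
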