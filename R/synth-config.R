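#' Taste-state label sets
#'
#' The six-state electronic-taste label set (`no` = no taste, `sr` = sour,
#' `sp` = sprite, `bt` = bitter, `mt` = mint, `st` = salty) and the four-state
#' set used when electronic stimulation is compared against actual tastants.
#'
#' @param scenario `"etaste6"` (default) or `"actual4"`.
#' @return Character vector of taste labels.
#' @export
#' @examples
#' taste_labels()
#' taste_labels("actual4")
taste_labels <- function(scenario = c("etaste6", "actual4")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    etaste6 = c("no", "sr", "sp", "bt", "mt", "st"),
    actual4 = c("no", "sr", "bt", "st")
  )
}

#' Spectral band partition used for the band-average features
#'
#' Thirteen contiguous frequency intervals: nine of width 10 Hz covering
#' 10-100 Hz (where facial-sEMG energy concentrates) and four of width 100 Hz
#' covering 100-500 Hz. Band `n` spans `[lo, hi)`.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (Hz), 13 rows.
#' @export
spectral_bands <- function() {
  data.frame(
    band = 1:13,
    lo = c(seq(10, 90, by = 10), seq(100, 400, by = 100)),
    hi = c(seq(20, 100, by = 10), seq(200, 500, by = 100))
  )
}

#' Default per-taste spectral band profiles
#'
#' Mean one-sided spectral magnitude (arbitrary microvolt scale) of the muscle
#' activity component in each of the 13 analysis bands, per taste state. The
#' base shape peaks around 20-30 Hz and decays towards 500 Hz, reflecting the
#' low-pass character of circular surface electrodes; each taste tilts the
#' shape towards a different part of the 10-100 Hz range, the "no taste" state
#' being a uniformly weaker version of the base.
#'
#' @param tastes Character vector of taste labels to build profiles for.
#' @return Named list mapping each taste to a numeric vector of 13 band
#'   magnitudes (microvolts).
#' @export
default_band_profiles <- function(tastes = taste_labels()) {
  base <- c(450, 550, 500, 400, 300, 225, 175, 140, 110, 62, 38, 25, 20)
  tilt <- list(
    no = rep(0.80, 13),
    sr = c(1.00, 1.35, 1.35, 1.20, 1.00, 1.00, 1.00, 1.00, 1.00, 1, 1, 1, 1),
    sp = c(1.00, 1.00, 1.10, 1.30, 1.30, 1.10, 1.00, 1.00, 1.00, 1, 1, 1, 1),
    bt = c(1.00, 1.00, 1.00, 1.00, 1.15, 1.30, 1.30, 1.10, 1.00, 1, 1, 1, 1),
    mt = c(1.15, 1.25, 1.10, 1.00, 1.00, 1.00, 1.10, 1.20, 1.10, 1, 1, 1, 1),
    st = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.20, 1.35, 1.35, 1.1, 1, 1, 1)
  )
  out <- lapply(tastes, function(t) base * (tilt[[t]] %||% rep(1, 13)))
  names(out) <- tastes
  out
}

#' Configuration for the synthetic sEMG generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: the recording
#' protocol (8 s trials at 1000 Hz over 6 channels), the label structure, and
#' the signal model (per-taste band-shaped muscle activity, per-participant
#' spectral heterogeneity, polynomial baseline drift, powerline interference
#' with harmonics, band-limited motion artifacts, and occasional high-amplitude
#' excursions).
#'
#' @param n_participants Number of participants (default 8).
#' @param tastes Character vector of taste labels; see [taste_labels()].
#' @param trials_per_taste_per_session Trials per taste within one session
#'   (default 1: each session presents every taste once).
#' @param sessions Sessions per participant (default 4).
#' @param trial_duration Trial length in seconds (default 8).
#' @param fs Sampling frequency in Hz (default 1000).
#' @param n_channels Number of sEMG channels (default 6).
#' @param class_band_profiles Named list, one numeric vector of 13 band
#'   magnitudes (microvolts) per taste; see [default_band_profiles()].
#' @param participant_heterogeneity Non-negative scale of the per-participant
#'   log-normal perturbation of band profiles (default 0.15; 0 makes all
#'   participants statistically identical).
#' @param drift_coeff_scale Standard deviation (microvolts) of the i.i.d.
#'   coefficients of the degree-4 polynomial baseline drift (default 300).
#' @param powerline_amp Amplitude (microvolts) of the 50 Hz powerline component
#'   (default 20).
#' @param powerline_harmonics Number of odd-harmonic components: component `k`
#'   sits at `(2k - 1) * 50` Hz with amplitude `powerline_amp / k` (default 3,
#'   i.e. 50, 150 and 250 Hz).
#' @param artifact_band Frequency band (Hz) of the motion-artifact component
#'   (default `c(1, 10)`).
#' @param artifact_amp RMS amplitude (microvolts) of the motion artifact
#'   (default 20).
#' @param outlier_prob Probability that a trial contains one high-amplitude
#'   (>2000 microvolt) excursion (default 0.05).
#' @param seed Integer root seed; all randomness in dataset generation derives
#'   from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 8,
                         tastes = taste_labels(),
                         trials_per_taste_per_session = 1,
                         sessions = 4,
                         trial_duration = 8,
                         fs = 1000,
                         n_channels = 6,
                         class_band_profiles = default_band_profiles(tastes),
                         participant_heterogeneity = 0.15,
                         drift_coeff_scale = 300,
                         powerline_amp = 20,
                         powerline_harmonics = 3,
                         artifact_band = c(1, 10),
                         artifact_amp = 20,
                         outlier_prob = 0.05,
                         seed = 1L) {
  if (fs <= 0) stop_emg("fs must be positive, got %s", fs)
  n_samp <- trial_duration * fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop_emg("trial_duration * fs must be an integer sample count, got %s", n_samp)
  if (outlier_prob < 0 || outlier_prob > 1)
    stop_emg("outlier_prob must lie in [0, 1], got %s", outlier_prob)
  if (participant_heterogeneity < 0)
    stop_emg("participant_heterogeneity must be non-negative")
  if (n_participants < 1) stop_emg("n_participants must be at least 1")
  if (sessions < 1) stop_emg("sessions must be at least 1")
  if (trials_per_taste_per_session < 1) stop_emg("trials_per_taste_per_session must be at least 1")
  if (length(tastes) < 1) stop_emg("at least one taste label is required")
  missing_prof <- setdiff(tastes, names(class_band_profiles))
  if (length(missing_prof) > 0)
    stop_emg("no band profile for taste(s): %s", paste(missing_prof, collapse = ", "))
  for (t in tastes) {
    p <- class_band_profiles[[t]]
    if (!is.numeric(p) || length(p) != nrow(spectral_bands()) || any(p < 0) || any(!is.finite(p)))
      stop_emg("band profile for taste '%s' must be 13 finite non-negative numbers", t)
  }
  if (length(artifact_band) != 2 || artifact_band[1] >= artifact_band[2])
    stop_emg("artifact_band must be an increasing (lo, hi) Hz pair")

  structure(list(
    n_participants = as.integer(n_participants),
    tastes = tastes,
    trials_per_taste_per_session = as.integer(trials_per_taste_per_session),
    sessions = as.integer(sessions),
    trial_duration = trial_duration,
    fs = fs,
    n_channels = as.integer(n_channels),
    class_band_profiles = class_band_profiles[tastes],
    participant_heterogeneity = participant_heterogeneity,
    drift_coeff_scale = drift_coeff_scale,
    powerline_amp = powerline_amp,
    powerline_harmonics = as.integer(powerline_harmonics),
    artifact_band = artifact_band,
    artifact_amp = artifact_amp,
    outlier_prob = outlier_prob,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Participant identifiers for a generator configuration
#' @param config A `synth_config`.
#' @return Character vector `"P01"`, `"P02"`, ...
#' @export
participant_ids <- function(config) {
  sprintf("P%02d", seq_len(config$n_participants))
}

#' Per-participant band-profile multipliers
#'
#' Each participant carries a fixed multiplicative log-normal perturbation of
#' the band profiles, `exp(h * z)` per band with `z ~ N(0, 1)` and
#' `h = participant_heterogeneity`, drawn deterministically from the config
#' seed and the participant index; with `h = 0` every participant gets unit
#' multipliers. The perturbation is shared across tastes (a participant-level
#' spectral gain), which is what makes pooled multi-participant datasets harder
#' to classify than single-participant ones.
#'
#' @param config A `synth_config`.
#' @param participant_id One of [participant_ids()].
#' @return Numeric vector of 13 positive multipliers.
#' @export
participant_band_multipliers <- function(config, participant_id) {
  idx <- match(participant_id, participant_ids(config))
  if (is.na(idx)) stop_emg("unknown participant_id '%s'", participant_id)
  if (config$participant_heterogeneity == 0) return(rep(1, nrow(spectral_bands())))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(config$seed, 1000000 + idx))
  exp(config$participant_heterogeneity * rnorm(nrow(spectral_bands())))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic sEMG generator configuration\n")
  cat(sprintf("  %d participants x %d sessions x %d tastes x %d trial(s)\n",
              x$n_participants, x$sessions, length(x$tastes),
              x$trials_per_taste_per_session))
  cat(sprintf("  %g s trials, %g Hz, %d channels; tastes: %s\n",
              x$trial_duration, x$fs, x$n_channels, paste(x$tastes, collapse = " ")))
  cat(sprintf("  heterogeneity %g, drift %g uV, powerline %g uV (%d harmonics), artifact %g uV RMS, outlier p=%g, seed %d\n",
              x$participant_heterogeneity, x$drift_coeff_scale, x$powerline_amp,
              x$powerline_harmonics, x$artifact_amp, x$outlier_prob, x$seed))
  invisible(x)
}
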