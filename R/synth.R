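new_raw_recording <- function(samples, fs, participant_id, session_id, taste,
                              duration, band_profile = NULL, trial = NA) {
  structure(list(
    samples = samples, fs = fs, participant_id = participant_id,
    session_id = session_id, taste = taste, duration = duration,
    band_profile = band_profile, trial = trial
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d channels x %d samples (%g s at %g Hz)\n",
              nrow(x$samples), ncol(x$samples), x$duration, x$fs))
  cat(sprintf("  participant %s, session %s, taste '%s'; range [%.1f, %.1f] uV\n",
              x$participant_id, x$session_id, x$taste,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.raw_recording <- function(x, channels = seq_len(nrow(x$samples)), ...) {
  tt <- seq_len(ncol(x$samples)) / x$fs
  offs <- (rev(seq_along(channels)) - 1) * 2 * max(abs(x$samples[channels, ]))
  graphics::matplot(tt, t(x$samples[channels, , drop = FALSE] + offs),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "amplitude (offset, uV)",
                    main = sprintf("%s / %s / %s", x$participant_id,
                                   x$session_id, x$taste), ...)
  invisible(x)
}

# One 1 s block of band-shaped Gaussian muscle activity, synthesized in the
# frequency domain: each one-sided DFT bin inside a band gets an independent
# complex-Gaussian coefficient whose expected magnitude equals the band's
# configured level (Rayleigh mean sigma * sqrt(pi/2)).
emg_block <- function(profile, fs, L = fs) {
  half <- L %/% 2
  freqs <- (1:(half - 1)) * fs / L        # strictly inside (0, Nyquist)
  sigma <- numeric(half - 1)
  bands <- spectral_bands()
  for (b in seq_len(nrow(bands))) {
    in_band <- freqs >= bands$lo[b] & freqs < bands$hi[b]
    sigma[in_band] <- profile[b] * sqrt(2 / pi)
  }
  z <- complex(real = rnorm(half - 1) * sigma,
               imaginary = rnorm(half - 1) * sigma)
  full <- complex(length.out = L)
  full[2:half] <- z
  full[(half + 2):L] <- Conj(rev(z))
  Re(fft(full, inverse = TRUE)) / L
}

# Band-limited Gaussian noise over an arbitrary length, calibrated to a target
# RMS; used for the 1-10 Hz motion-artifact component.
band_noise <- function(n, fs, lo, hi, rms) {
  if (rms <= 0) return(numeric(n))
  half <- n %/% 2
  freqs <- (1:(half - 1)) * fs / n
  in_band <- freqs >= lo & freqs < hi
  n_band <- sum(in_band)
  if (n_band == 0) return(numeric(n))
  sigma <- rms * n / (2 * sqrt(n_band))
  z <- complex(real = rnorm(half - 1), imaginary = rnorm(half - 1)) * ifelse(in_band, sigma, 0)
  full <- complex(length.out = n)
  full[2:half] <- z
  full[(half + 2):n] <- Conj(rev(z))
  Re(fft(full, inverse = TRUE)) / n
}

polyval_norm <- function(coefs, n) {
  tt <- seq(-1, 1, length.out = n)
  drop(outer(tt, 0:(length(coefs) - 1), `^`) %*% coefs)
}

#' Generate one synthetic sEMG trial
#'
#' Synthesizes a single multichannel recording as the sum of four components:
#' band-shaped Gaussian muscle activity following the participant-adjusted
#' per-taste band profile (generated in independent 1 s blocks aligned with
#' the downstream windowing grid), a degree-4 polynomial baseline drift with
#' i.i.d. coefficients on a time axis normalized to \[-1, 1\], powerline
#' sinusoids at 50 Hz and configured odd harmonics, and band-limited 1-10 Hz
#' motion-artifact noise. With probability `outlier_prob` one 50 ms half-sine
#' burst of 2500-5000 microvolt amplitude is added at a random position inside
#' a single window of one random channel.
#'
#' @param config A [synth_config()].
#' @param participant_id One of [participant_ids()].
#' @param session_id Session identifier (e.g. `"S1"`).
#' @param taste A taste label present in `config$tastes`.
#' @param seed Integer seed controlling this trial's randomness; identical
#'   inputs reproduce the recording bitwise.
#' @return A `raw_recording`: `samples` is an `n_channels x T` matrix in
#'   microvolts, plus provenance fields and the effective band profile used.
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 1, sessions = 1)
#' rec <- generate_recording(cfg, "P01", "S1", "sr", seed = 42)
#' rec
generate_recording <- function(config, participant_id, session_id, taste, seed) {
  if (!inherits(config, "synth_config")) stop_emg("config must be a synth_config")
  if (!taste %in% config$tastes)
    stop_emg("unknown taste '%s'; configured tastes: %s", taste,
             paste(config$tastes, collapse = ", "))
  n_samp <- config$trial_duration * config$fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop_emg("trial_duration * fs must be an integer sample count")
  n_samp <- as.integer(round(n_samp))
  fs <- config$fs
  L <- as.integer(fs)  # 1 s synthesis block

  profile <- config$class_band_profiles[[taste]] *
    participant_band_multipliers(config, participant_id)

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n_blocks <- ceiling(n_samp / L)
  x <- matrix(0, nrow = config$n_channels, ncol = n_samp)
  for (ch in seq_len(config$n_channels)) {
    emg <- unlist(lapply(seq_len(n_blocks), function(b) emg_block(profile, fs, L)))
    x[ch, ] <- emg[seq_len(n_samp)]
  }

  if (config$drift_coeff_scale > 0) {
    for (ch in seq_len(config$n_channels)) {
      coefs <- rnorm(5, sd = config$drift_coeff_scale)
      x[ch, ] <- x[ch, ] + polyval_norm(coefs, n_samp)
    }
  }

  if (config$powerline_amp > 0 && config$powerline_harmonics > 0) {
    tt <- (seq_len(n_samp) - 1) / fs
    for (k in seq_len(config$powerline_harmonics)) {
      f_k <- (2 * k - 1) * 50
      if (f_k >= fs / 2) next
      phase <- runif(1, 0, 2 * pi)
      comp <- (config$powerline_amp / k) * sin(2 * pi * f_k * tt + phase)
      x <- sweep(x, 2, comp, `+`)   # common-mode: same phase on all channels
    }
  }

  if (config$artifact_amp > 0) {
    # per-block like the EMG component, so windows are statistically
    # independent and small-sample evaluation properties are exact
    for (ch in seq_len(config$n_channels)) {
      art <- unlist(lapply(seq_len(n_blocks), function(b) {
        band_noise(L, fs, config$artifact_band[1], config$artifact_band[2],
                   config$artifact_amp)
      }))
      x[ch, ] <- x[ch, ] + art[seq_len(n_samp)]
    }
  }

  if (config$outlier_prob > 0 && runif(1) < config$outlier_prob) {
    # 10 ms half-sine: short enough that the 10 Hz high-pass passes most of
    # its energy, so the excursion still exceeds the 2000 uV rejection
    # threshold after the full preprocessing chain
    burst_len <- max(2L, as.integer(round(0.01 * fs)))
    ch <- sample.int(config$n_channels, 1)
    win <- sample.int(max(1L, n_samp %/% L), 1)
    offset <- (win - 1L) * L + sample.int(L - burst_len + 1L, 1)
    amp <- runif(1, 3000, 6000) * sample(c(-1, 1), 1)
    burst <- amp * sin(pi * (0:(burst_len - 1)) / (burst_len - 1))
    idx <- offset:(offset + burst_len - 1L)
    x[ch, idx] <- x[ch, idx] + burst
  }

  new_raw_recording(x, fs, participant_id, session_id, taste,
                    config$trial_duration, band_profile = profile)
}

#' Enumerate the trial grid of a generator configuration
#'
#' Builds the dataset manifest without synthesizing any signal: one row per
#' (participant, session, taste, trial) combination, with a per-trial seed
#' derived deterministically from the configuration's root seed.
#'
#' @param config A [synth_config()].
#' @return A data frame with columns `participant`, `session`, `taste`,
#'   `trial`, `seed`, `file` (`NA` until recordings are written to disk).
#' @export
#' @examples
#' nrow(build_manifest(synth_config(n_participants = 8, sessions = 4)))  # 192
build_manifest <- function(config) {
  if (!inherits(config, "synth_config")) stop_emg("config must be a synth_config")
  if (config$n_participants < 1 || config$sessions < 1)
    stop_emg("need at least one participant and one session")
  grid <- expand.grid(
    trial = seq_len(config$trials_per_taste_per_session),
    taste = config$tastes,
    session = sprintf("S%d", seq_len(config$sessions)),
    participant = participant_ids(config),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("participant", "session", "taste", "trial")]
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  grid$seed <- sample.int(2147483646L, nrow(grid))
  grid$file <- NA_character_
  rownames(grid) <- NULL
  grid
}

#' Generate a full labelled synthetic dataset
#'
#' Synthesizes one recording per row of [build_manifest()] and returns the
#' collection together with its manifest and the effective per-participant
#' band profiles (generator metadata). Fully reproducible: the same
#' configuration (including its `seed`) yields bitwise-identical samples.
#'
#' @param config A [synth_config()].
#' @return An object of class `semg_dataset`: a list with elements
#'   `recordings` (list of `raw_recording`), `manifest` (data frame),
#'   `profiles` (participant x taste list of effective band profiles) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  manifest <- build_manifest(config)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- generate_recording(config, manifest$participant[i], manifest$session[i],
                              manifest$taste[i], manifest$seed[i])
    rec$trial <- manifest$trial[i]
    rec
  })
  profiles <- lapply(participant_ids(config), function(p) {
    mult <- participant_band_multipliers(config, p)
    lapply(config$class_band_profiles, function(prof) prof * mult)
  })
  names(profiles) <- participant_ids(config)
  structure(list(recordings = recordings, manifest = manifest,
                 profiles = profiles, config = config),
            class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf("Synthetic sEMG dataset: %d recordings (%d participants, %d sessions, %d tastes)\n",
              length(x$recordings), x$config$n_participants, x$config$sessions,
              length(x$config$tastes)))
  invisible(x)
}
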