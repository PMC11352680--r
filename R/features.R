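#' The 21 per-channel feature types
#'
#' Sixteen frequency-domain features (13 spectral band averages, frequency
#' centroid FC, RMSF and RVF) and five time-domain features (RMS, ZCR, MAV,
#' kurtosis, skewness), in their canonical order F1..F21.
#'
#' @return Data frame with columns `index`, `name`, `domain`.
#' @export
feature_types <- function() {
  bands <- spectral_bands()
  data.frame(
    index = 1:21,
    name = c(sprintf("band_%d_%d", bands$lo, bands$hi),
             "FC", "RMSF", "RVF", "RMS", "ZCR", "MAV", "Ku", "Sk"),
    domain = c(rep("frequency", 16), rep("time", 5))
  )
}

#' One-sided magnitude spectrum of a channel
#'
#' `f(i)`, the unnormalized magnitude of the length-`L` discrete Fourier
#' transform at bin `i = 0..L/2`; bin `i` corresponds to frequency
#' `i * fs / L` Hz (1 Hz bins for the default 1 s window at 1000 Hz).
#'
#' @param x Numeric vector of channel samples.
#' @param fs Sampling frequency in Hz.
#' @return Object of class `spectrum_view` with fields `magnitude`
#'   (length `L/2 + 1`), `fs`, `L`, `bin_width`.
#' @export
#' @examples
#' tt <- (0:999) / 1000
#' sp <- compute_spectrum(sin(2 * pi * 50 * tt), fs = 1000)
#' sp$magnitude[51]  # bin 50: L/2 * amplitude = 500
compute_spectrum <- function(x, fs) {
  if (!all(is.finite(x))) stop_emg("non-finite samples in channel")
  L <- length(x)
  mag <- Mod(fft(x))[1:(L %/% 2 + 1)]
  structure(list(magnitude = mag, fs = fs, L = L, bin_width = fs / L),
            class = "spectrum_view")
}

#' Spectral band-average features F1..F13
#'
#' Mean one-sided DFT magnitude within each of the 13 analysis bands of
#' [spectral_bands()]: nine 10 Hz bands over 10-100 Hz and four 100 Hz bands
#' over 100-500 Hz. With 1 Hz bins this reduces to the plain averages
#' `F[n] = (1/10) * sum(f(i), i = 10n .. 10(n+1) - 1)` for the narrow bands
#' and the analogous 100-bin averages for the wide ones; for other
#' resolutions the bands are defined in Hz and bin indices rescale.
#'
#' @param spec A `spectrum_view`.
#' @return Named numeric vector of 13 band averages.
#' @export
band_average_features <- function(spec) {
  bands <- spectral_bands()
  nyquist <- spec$fs / 2
  if (nyquist < max(bands$hi) - spec$bin_width)
    stop_emg("spectrum too short: Nyquist %g Hz below top band %g Hz",
             nyquist, max(bands$hi))
  freqs <- (seq_along(spec$magnitude) - 1) * spec$bin_width
  out <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs >= bands$lo[b] & freqs < bands$hi[b]
    mean(spec$magnitude[sel])
  }, numeric(1))
  names(out) <- sprintf("F%d", 1:13)
  out
}

#' Spectral moment features F14..F16 (FC, RMSF, RVF)
#'
#' Magnitude-weighted moments of frequency over bins `i = 1..L/2`:
#' the frequency centroid `FC = sum(f(i) * f_i) / sum(f(i))`, the second
#' moment about zero (RMSF) and the second moment about the centroid (RVF),
#' with `f_i = i * fs / L`. The moments are returned as printed in their
#' defining equations, i.e. without a square root, although the names
#' suggest one; set `apply_root = TRUE` to take it.
#'
#' @param spec A `spectrum_view`.
#' @param apply_root Take the square root of RMSF and RVF (default `FALSE`).
#' @return Named vector `c(F14, F15, F16)`; all `NA` when the spectrum is
#'   identically zero (the undefined-feature signal).
#' @export
spectral_moment_features <- function(spec, apply_root = FALSE) {
  half <- spec$L %/% 2
  f <- spec$magnitude[2:(half + 1)]
  fr <- (1:half) * spec$fs / spec$L
  s <- sum(f)
  if (s <= 0) return(c(F14 = NA_real_, F15 = NA_real_, F16 = NA_real_))
  fc <- sum(f * fr) / s
  rmsf <- sum(f * fr^2) / s
  rvf <- sum(f * (fr - fc)^2) / s
  if (apply_root) {
    rmsf <- sqrt(rmsf)
    rvf <- sqrt(rvf)
  }
  c(F14 = fc, F15 = rmsf, F16 = rvf)
}

#' Time-domain features F17..F21 (RMS, ZCR, MAV, Ku, Sk)
#'
#' Root mean square, zero-crossing rate, mean absolute value, kurtosis and
#' skewness of the window samples. ZCR counts strict sign changes
#' (`x_i * x_{i+1} < 0`) scaled by 1/10, as the defining equation prints it.
#' Kurtosis and skewness use the population standard deviation (divisor `L`);
#' they are `NA` for a constant window (the undefined-feature signal).
#'
#' @param x Numeric vector of at least 2 samples.
#' @return Named vector `c(F17, F18, F19, F20, F21)`.
#' @export
time_features <- function(x) {
  L <- length(x)
  if (L < 2) stop_emg("time_features needs at least 2 samples")
  if (!all(is.finite(x))) stop_emg("non-finite samples in channel")
  rms <- sqrt(sum(x^2) / L)
  zcr <- sum(x[-L] * x[-1] < 0) / 10
  mav <- sum(abs(x)) / L
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / L)
  if (sigma == 0) {
    ku <- NA_real_
    sk <- NA_real_
  } else {
    z <- (x - mu) / sigma
    ku <- sum(z^4) / L
    sk <- sum(z^3) / L
  }
  c(F17 = rms, F18 = zcr, F19 = mav, F20 = ku, F21 = sk)
}

#' Extract the full per-window feature vector
#'
#' Computes all 21 feature types for every channel and concatenates them
#' channel-major, giving `n_channels * 21` values (126 for the standard
#' 6-channel montage). Names follow the `ch{c}_F{n}` convention.
#'
#' @param window A `window_sample` (fully preprocessed for the standard
#'   pipeline, though the computation itself only requires finite samples).
#' @param apply_root Passed to [spectral_moment_features()].
#' @return Named numeric vector of length `n_channels * 21`; entries are `NA`
#'   where a feature is undefined (zero spectrum or constant channel).
#' @export
extract_features <- function(window, apply_root = FALSE) {
  n_ch <- nrow(window$samples)
  per_ch <- lapply(seq_len(n_ch), function(ch) {
    x <- window$samples[ch, ]
    spec <- compute_spectrum(x, window$fs)
    c(band_average_features(spec),
      spectral_moment_features(spec, apply_root = apply_root),
      time_features(x))
  })
  out <- unlist(per_ch)
  names(out) <- as.vector(t(outer(seq_len(n_ch), 1:21,
                                  function(c, n) sprintf("ch%d_F%d", c, n))))
  out
}

#' Build a feature table from preprocessed windows
#'
#' Applies [extract_features()] to each window and assembles the rows into a
#' data frame with label and provenance columns, the input expected by the
#' evaluation functions. Windows yielding any undefined (non-finite) feature
#' are excluded, with the count reported via a message.
#'
#' @param windows List of `window_sample` objects.
#' @param apply_root Passed to [extract_features()].
#' @return Data frame with feature columns `ch{c}_F{n}` plus `label`,
#'   `participant`, `session`, `trial`, `window`.
#' @export
extract_feature_table <- function(windows, apply_root = FALSE) {
  if (length(windows) == 0) stop_emg("no windows to extract features from")
  rows <- lapply(windows, extract_features, apply_root = apply_root)
  mat <- do.call(rbind, rows)
  meta <- do.call(rbind, lapply(windows, function(w) {
    p <- w$provenance
    data.frame(label = w$label,
               participant = as.character(p$participant %||% NA),
               session = as.character(p$session %||% NA),
               trial = as.integer(p$trial %||% NA),
               window = as.integer(p$window %||% NA),
               stringsAsFactors = FALSE)
  }))
  ok <- apply(mat, 1, function(r) all(is.finite(r)))
  if (any(!ok))
    message(sprintf("excluded %d window(s) with undefined features", sum(!ok)))
  out <- cbind(as.data.frame(mat[ok, , drop = FALSE]), meta[ok, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Names of the feature columns in a feature table
#' @param data A feature table data frame.
#' @return Character vector of `ch{c}_F{n}` column names.
#' @export
feature_columns <- function(data) {
  grep("^ch[0-9]+_F[0-9]+$", names(data), value = TRUE)
}
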