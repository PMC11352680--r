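# Independent brute-force transcription of the 21 feature definitions:
# literal loops over the printed formulas, used as the oracle against the
# vectorised implementation.
oracle_channel_features <- function(x, fs = 1000) {
  L <- length(x)
  f <- Mod(stats::fft(x))[1:(L / 2 + 1)]  # f[i + 1] is spectrum amplitude f(i)
  F <- numeric(21)
  for (n in 1:9) {
    s <- 0
    for (i in (n * 10):((n + 1) * 10 - 1)) s <- s + f[i + 1]
    F[n] <- s / 10
  }
  for (n in 10:13) {
    s <- 0
    for (i in ((n - 9) * 100):((n - 8) * 100 - 1)) s <- s + f[i + 1]
    F[n] <- s / 100
  }
  num <- 0; den <- 0
  for (i in 1:(L / 2)) { num <- num + f[i + 1] * (i * fs / L); den <- den + f[i + 1] }
  F[14] <- num / den
  num <- 0
  for (i in 1:(L / 2)) num <- num + f[i + 1] * (i * fs / L)^2
  F[15] <- num / den
  num <- 0
  for (i in 1:(L / 2)) num <- num + f[i + 1] * (i * fs / L - F[14])^2
  F[16] <- num / den
  F[17] <- sqrt(sum(x^2) / L)
  cnt <- 0
  for (i in 1:(L - 1)) if (x[i] * x[i + 1] < 0) cnt <- cnt + 1
  F[18] <- cnt / 10
  F[19] <- sum(abs(x)) / L
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / L)
  F[20] <- sum(((x - mu) / sigma)^4) / L
  F[21] <- sum(((x - mu) / sigma)^3) / L
  F
}

# A window whose channels all carry the same trace.
make_window <- function(x, fs = 1000, n_channels = 6, stage = "raw",
                        label = "no") {
  emgtaste:::new_window(
    matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE), fs,
    label = label,
    provenance = list(participant = "P01", session = "S1", taste = label,
                      trial = 1L, window = 1L),
    stage = stage
  )
}

# A window with independent random channels.
random_window <- function(fs = 1000, n_channels = 6, stage = "notched") {
  emgtaste:::new_window(
    matrix(rnorm(n_channels * fs, sd = 50), nrow = n_channels), fs,
    label = "no",
    provenance = list(participant = "P01", session = "S1", taste = "no",
                      trial = 1L, window = 1L),
    stage = stage
  )
}

# Synthetic feature table built directly (no signal generation): class
# structure planted in chosen feature types.
make_feature_table <- function(n_per_class, classes, n_channels = 1,
                               informative_types = integer(0), shift = 2,
                               participants = "P01") {
  n <- n_per_class * length(classes)
  label <- rep(classes, each = n_per_class)
  cols <- as.vector(t(outer(seq_len(n_channels), 1:21,
                            function(c, k) sprintf("ch%d_F%d", c, k))))
  mat <- matrix(rnorm(n * length(cols)), nrow = n,
                dimnames = list(NULL, cols))
  for (ty in informative_types) {
    for (ch in seq_len(n_channels)) {
      mat[, sprintf("ch%d_F%d", ch, ty)] <-
        mat[, sprintf("ch%d_F%d", ch, ty)] + shift * as.integer(factor(label))
    }
  }
  df <- as.data.frame(mat)
  df$label <- label
  df$participant <- rep_len(participants, n)
  df$session <- "S1"
  df
}

band_profile_zero <- function(tastes = taste_labels()) {
  stats::setNames(rep(list(rep(0, 13)), length(tastes)), tastes)
}

# Contrast-amplified class profiles: same shape family as the defaults with
# the per-taste tilts raised to a power, widening class separation.
separable_profiles <- function(gamma = 2, tastes = taste_labels()) {
  p <- default_band_profiles(tastes)
  base <- c(450, 550, 500, 400, 300, 225, 175, 140, 110, 62, 38, 25, 20)
  lapply(p, function(v) base * (v / base)^gamma)
}
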