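#' Write one trial recording as CSV
#'
#' Columns are `time_s` followed by `ch1..chN` in microvolts, one row per
#' sample.
#'
#' @param recording A `raw_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(recording, path) {
  n_ch <- nrow(recording$samples)
  df <- data.frame(time_s = (seq_len(ncol(recording$samples)) - 1) / recording$fs)
  for (ch in seq_len(n_ch)) df[[sprintf("ch%d", ch)]] <- recording$samples[ch, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read one trial recording from CSV
#'
#' Expects the schema written by [write_trial_csv()]: a `time_s` column with
#' uniform spacing `1/fs`, followed by `ch1..chN`. Malformed input (missing
#' channel columns, non-numeric cells, non-monotone time) is rejected with a
#' labelled error naming the offending column or lines.
#'
#' @param path CSV file path.
#' @param n_channels Expected channel count (default 6).
#' @param participant_id,session_id,taste,trial Optional provenance to attach.
#' @return A `raw_recording`.
#' @export
read_trial_csv <- function(path, n_channels = 6, participant_id = NA,
                           session_id = NA, taste = NA, trial = NA) {
  if (!file.exists(path)) stop_emg("file not found: %s", path)
  if (file.size(path) == 0) stop_emg("empty file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_emg("no data rows in %s", path)
  expected <- c("time_s", sprintf("ch%d", seq_len(n_channels)))
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0)
    stop_emg("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  for (col in expected) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | !is.finite(v))
    if (length(bad) > 0)
      stop_emg("non-numeric value(s) in column '%s' of %s at data line(s) %s",
               col, path, paste(head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop_emg("time_s column in %s is not strictly increasing", path)
  if (max(dt) - min(dt) > 1e-9 * max(dt, 1))
    stop_emg("time_s column in %s is not uniformly spaced", path)
  fs <- 1 / median(dt)
  samples <- t(as.matrix(df[sprintf("ch%d", seq_len(n_channels))]))
  dimnames(samples) <- NULL
  new_raw_recording(samples, fs, participant_id, session_id, taste,
                    duration = nrow(df) / fs, trial = trial)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(strip_classes(cfg), auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Write a synthetic dataset to disk
#'
#' One CSV per trial plus a JSON manifest recording the provenance grid, the
#' per-trial seeds, the full generator-configuration snapshot and its hash
#' (sufficient to regenerate the dataset bitwise).
#'
#' @param dataset A `semg_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame with the `file` column filled, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset$manifest
  for (i in seq_len(nrow(manifest))) {
    fn <- sprintf("%s_%s_%s_t%d.csv", manifest$participant[i],
                  manifest$session[i], manifest$taste[i], manifest$trial[i])
    write_trial_csv(dataset$recordings[[i]], file.path(dir, fn))
    manifest$file[i] <- fn
  }
  meta <- list(schema_version = 1L,
               config = unclass(dataset$config),
               config_hash = config_hash(dataset$config),
               trials = manifest)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing trial CSVs and `manifest.json`.
#' @return A `semg_dataset` (without generator profile metadata).
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_emg("no manifest.json in %s", dir)
  meta <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  manifest <- meta$trials
  n_ch <- meta$config$n_channels %||% 6
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) stop_emg("manifest references missing file %s", f)
    read_trial_csv(f, n_channels = n_ch,
                   participant_id = manifest$participant[i],
                   session_id = manifest$session[i],
                   taste = manifest$taste[i], trial = manifest$trial[i])
  })
  structure(list(recordings = recordings, manifest = manifest,
                 profiles = NULL, config = meta$config),
            class = "semg_dataset")
}

#' Write / read a feature table as CSV
#'
#' @param data Feature table data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the feature table (read).
#' @export
write_feature_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop_emg("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_dataset_table(df)
  df
}
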