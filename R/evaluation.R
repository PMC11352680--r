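#' Evaluation configuration
#'
#' Settings for the cross-validated random-forest experiments.
#'
#' @param n_folds Number of cross-validation folds (default 5).
#' @param rf_n_trees Trees per forest (default 100).
#' @param rf_max_features Feature-subsampling rule at each split: `"sqrt"`
#'   (default) or an explicit integer.
#' @param seed Integer seed fixing fold assignment and forest training.
#' @param fold_scheme `"stratified_random"` (default): folds stratified by
#'   class at the window level, matching the usual protocol for this kind of
#'   dataset. `"by_session"`: whole participant-sessions assigned to folds,
#'   which avoids leaking within-trial correlation across the train/test
#'   split at the cost of unbalanced classes per fold.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_folds = 5, rf_n_trees = 100, rf_max_features = "sqrt",
                        seed = 1L,
                        fold_scheme = c("stratified_random", "by_session")) {
  if (n_folds < 2) stop_emg("n_folds must be at least 2")
  if (rf_n_trees < 1) stop_emg("rf_n_trees must be at least 1")
  structure(list(n_folds = as.integer(n_folds),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_max_features = rf_max_features,
                 seed = as.integer(seed),
                 fold_scheme = match.arg(fold_scheme)),
            class = "eval_config")
}

validate_dataset_table <- function(data) {
  cols <- feature_columns(data)
  if (length(cols) == 0) stop_emg("no feature columns (ch{c}_F{n}) found")
  if (!"label" %in% names(data)) stop_emg("dataset table needs a 'label' column")
  if (nrow(data) == 0) stop_emg("empty dataset: no feature rows")
  if (any(!is.finite(as.matrix(data[cols]))))
    stop_emg("dataset table contains missing or non-finite feature values")
  cols
}

assign_folds <- function(data, config) {
  n <- nrow(data)
  fold <- integer(n)
  if (config$fold_scheme == "by_session") {
    unit <- interaction(data$participant, data$session, drop = TRUE)
    levs <- sample(levels(unit))
    fold_of_unit <- rep_len(seq_len(config$n_folds), length(levs))
    fold <- fold_of_unit[match(unit, levs)]
  } else {
    for (cl in unique(data$label)) {
      idx <- which(data$label == cl)
      if (length(idx) < config$n_folds)
        stop_emg(paste0("class '%s' has only %d sample(s), fewer than %d folds; ",
                        "use stratified folds on more data"),
                 cl, length(idx), config$n_folds)
      fold[sample(idx)] <- rep_len(seq_len(config$n_folds), length(idx))
    }
  }
  fold
}

rf_mtry <- function(config, n_features) {
  if (identical(config$rf_max_features, "sqrt")) {
    max(1L, floor(sqrt(n_features)))
  } else {
    min(as.integer(config$rf_max_features), n_features)
  }
}

#' Stratified k-fold cross-validation with a random forest
#'
#' Assigns windows to `n_folds` folds (stratified by taste label under the
#' default scheme), trains a random forest on the training folds and scores
#' the held-out fold, rotating through all folds. Reports per-fold and mean
#' accuracy plus the row-normalized confusion matrix accumulated over all
#' test folds. Fully reproducible for a fixed `(data, config)` pair.
#'
#' @param data Feature table (see [extract_feature_table()]).
#' @param config An [eval_config()].
#' @param feature_cols Optional subset of feature columns to use (defaults to
#'   all `ch{c}_F{n}` columns).
#' @return An object of class `eval_report`: `fold_accuracy`, `mean_accuracy`,
#'   `confusion` (rows sum to 1), `n`, `classes`, `config`.
#' @export
five_fold_cv <- function(data, config = eval_config(), feature_cols = NULL) {
  all_cols <- validate_dataset_table(data)
  cols <- feature_cols %||% all_cols
  if (!all(cols %in% names(data))) stop_emg("unknown feature columns requested")
  y <- factor(data$label)
  classes <- levels(y)
  x <- as.matrix(data[cols])

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  fold <- assign_folds(data, config)

  k <- config$n_folds
  acc <- numeric(k)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  for (i in seq_len(k)) {
    test <- fold == i
    if (!all(classes %in% y[!test]))
      stop_emg("class absent from training fold %d; use stratified folds or more data", i)
    rf <- randomForest::randomForest(
      x = x[!test, , drop = FALSE], y = y[!test],
      ntree = config$rf_n_trees, mtry = rf_mtry(config, ncol(x)))
    pred <- predict(rf, x[test, , drop = FALSE])
    acc[i] <- mean(pred == y[test])
    conf <- conf + table(factor(y[test], classes), factor(pred, classes))
  }
  row_sums <- rowSums(conf)
  conf_norm <- sweep(conf, 1, ifelse(row_sums > 0, row_sums, 1), `/`)
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusion = conf_norm, n = nrow(data), classes = classes,
                 n_features = length(cols), config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation, random forest (%d trees), %d samples, %d features\n",
              x$config$n_folds, x$config$rf_n_trees, x$n, x$n_features))
  cat(sprintf("  fold accuracies: %s\n",
              paste(format(round(x$fold_accuracy, digits)), collapse = " ")))
  cat(sprintf("  mean accuracy:   %.*f\n", digits, x$mean_accuracy))
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object, ...)
  cat("  normalized confusion matrix (rows = truth):\n")
  print(round(object$confusion, 3))
  invisible(object)
}

#' @export
plot.eval_report <- function(x, ...) {
  k <- length(x$classes)
  graphics::image(1:k, 1:k, t(x$confusion[k:1, ]), axes = FALSE,
                  xlab = "predicted", ylab = "truth",
                  main = sprintf("Normalized confusion matrix (acc %.3f)",
                                 x$mean_accuracy), ...)
  graphics::axis(1, at = 1:k, labels = x$classes)
  graphics::axis(2, at = 1:k, labels = rev(x$classes))
  for (i in 1:k) for (j in 1:k)
    graphics::text(j, k + 1 - i, sprintf("%.2f", x$confusion[i, j]))
  invisible(x)
}

#' Incremental feature-type sweep
#'
#' Shuffles the 21 feature types into a random order fixed by `order_seed`,
#' then evaluates cross-validated accuracy on the first `k` types (each type
#' contributing its column from every channel) for `k = 1..21`, tracing how
#' accuracy grows as features accumulate.
#'
#' @param data Feature table.
#' @param order_seed Integer seed fixing the feature order.
#' @param config An [eval_config()].
#' @return Object of class `sweep_curve`: data frame with columns
#'   `n_features`, `feature_added`, `accuracy`, plus the order as an
#'   attribute.
#' @export
feature_sweep <- function(data, order_seed = 1L, config = eval_config()) {
  validate_dataset_table(data)
  types <- feature_types()
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(order_seed))
  ord <- sample(types$index)
  channels <- sort(unique(as.integer(sub("^ch([0-9]+)_.*$", "\\1",
                                         feature_columns(data)))))
  res <- lapply(seq_along(ord), function(k) {
    sel <- ord[seq_len(k)]
    cols <- as.vector(outer(channels, sel, function(c, n) sprintf("ch%d_F%d", c, n)))
    rep <- five_fold_cv(data, config, feature_cols = cols)
    data.frame(n_features = k, feature_added = types$name[ord[k]],
               accuracy = rep$mean_accuracy)
  })
  out <- do.call(rbind, res)
  attr(out, "order") <- ord
  class(out) <- c("sweep_curve", "data.frame")
  out
}

#' @export
plot.sweep_curve <- function(x, ...) {
  graphics::plot(x$n_features, x$accuracy, type = "b", pch = 16,
                 xlab = "number of feature types", ylab = "mean CV accuracy",
                 main = "Accuracy vs number of features", ...)
  invisible(x)
}

#' Participant-subset grouping experiment
#'
#' Evaluates cross-validated accuracy on every non-empty subset of
#' participants (2^P - 1 subsets for P participants) and summarises the mean
#' accuracy per subset size. When participants differ spectrally
#' (heterogeneity > 0), pooling more participants increases within-class
#' variance and accuracy declines with subset size; with exchangeable
#' participants the curve is flat.
#'
#' @param data Feature table with a `participant` column.
#' @param config An [eval_config()].
#' @return Object of class `grouping_result`: list with `summary` (data frame
#'   `size`, `n_subsets`, `n_evaluated`, `mean_accuracy`) and `details` (one
#'   row per subset with its accuracy).
#' @export
participant_grouping <- function(data, config = eval_config()) {
  validate_dataset_table(data)
  parts <- sort(unique(data$participant))
  P <- length(parts)
  if (P < 1) stop_emg("no participants in dataset")
  if (P > 12)
    stop_emg("refusing %d participants: 2^%d - 1 subsets is impractical (limit 12)", P, P)
  details <- list()
  for (size in seq_len(P)) {
    subsets <- combn(parts, size, simplify = FALSE)
    for (s in subsets) {
      sub <- data[data$participant %in% s, , drop = FALSE]
      acc <- tryCatch(
        five_fold_cv(sub, config)$mean_accuracy,
        error = function(e) {
          message(sprintf("skipping subset {%s}: %s",
                          paste(s, collapse = ","), conditionMessage(e)))
          NA_real_
        })
      details[[length(details) + 1]] <-
        data.frame(size = size, subset = paste(s, collapse = "+"),
                   n = nrow(sub), accuracy = acc)
    }
  }
  details <- do.call(rbind, details)
  summary <- do.call(rbind, lapply(seq_len(P), function(size) {
    d <- details[details$size == size, ]
    data.frame(size = size, n_subsets = nrow(d),
               n_evaluated = sum(!is.na(d$accuracy)),
               mean_accuracy = mean(d$accuracy, na.rm = TRUE))
  }))
  structure(list(summary = summary, details = details,
                 n_participants = P, config = config),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("Participant grouping over %d participants (%d subset datasets)\n",
              x$n_participants, nrow(x$details)))
  print(transform(x$summary, mean_accuracy = round(mean_accuracy, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.grouping_result <- function(x, ...) {
  graphics::plot(x$summary$size, x$summary$mean_accuracy, type = "b", pch = 16,
                 xlab = "participants per dataset", ylab = "mean CV accuracy",
                 main = "Accuracy vs participant-group size", ...)
  invisible(x)
}

#' Paired evaluation of two stimulation scenarios
#'
#' Runs the same cross-validation protocol on two datasets sharing a label
#' set (e.g. electronically evoked versus actual tastants over the four-state
#' set) and returns the side-by-side reports with their confusion matrices.
#'
#' @param dataset_a,dataset_b Feature tables with identical label sets.
#' @param config An [eval_config()].
#' @return Object of class `scenario_comparison`: list of two `eval_report`s
#'   (`a`, `b`).
#' @export
scenario_compare <- function(dataset_a, dataset_b, config = eval_config()) {
  la <- sort(unique(as.character(dataset_a$label)))
  lb <- sort(unique(as.character(dataset_b$label)))
  if (!identical(la, lb))
    stop_emg("mismatched label sets: {%s} vs {%s}",
             paste(la, collapse = ","), paste(lb, collapse = ","))
  structure(list(a = five_fold_cv(dataset_a, config),
                 b = five_fold_cv(dataset_b, config)),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario A:\n")
  print(x$a)
  cat("Scenario B:\n")
  print(x$b)
  invisible(x)
}
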