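#' Cross-validation configuration
#'
#' @param k Number of folds.
#' @param stratified Balance class counts across folds (per-class fold
#'   counts differ by at most 1), keeping every class present in every
#'   training split.
#' @param seed Seed for the fold assignment.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(k = 5L, stratified = TRUE, seed = 1L) {
  if (!is_count(k, min = 2L)) abort("k must be an integer >= 2", class = "mammoqc_config_error")
  structure(list(k = as.integer(k), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Partition samples into k cross-validation folds
#'
#' Folds are disjoint, cover all indices and differ in size by at most one;
#' with stratification the per-class counts per fold also differ by at most
#' one. The assignment is reproducible from `cfg$seed`.
#'
#' @param labels Positioning labels (codes or names), one per sample.
#' @param cfg An [eval_config()].
#' @return A list of `k` integer index vectors.
#' @export
make_folds <- function(labels, cfg = eval_config()) {
  y <- label_code(labels)
  n <- length(y)
  k <- cfg$k
  if (n < k) abort(sprintf("need at least k = %d samples, got %d", k, n),
                   class = "mammoqc_config_error")
  folds <- vector("list", k)
  with_seed(cfg$seed, {
    if (cfg$stratified) {
      offset <- 0L
      for (cls in sort(unique(y))) {
        idx <- sample(which(y == cls))
        assign_to <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        for (f in seq_len(k)) {
          folds[[f]] <- c(folds[[f]], idx[assign_to == f])
        }
        offset <- (offset + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      assign_to <- ((seq_len(n) - 1L) %% k) + 1L
      for (f in seq_len(k)) folds[[f]] <- idx[assign_to == f]
    }
  })
  lapply(folds, sort)
}

#' Build a 3 x 3 confusion matrix
#'
#' Rows are true classes, columns predicted classes, both ordered
#' poor / average / excellent.
#'
#' @param truth,predicted Label vectors (codes or names) of equal length.
#' @return An integer matrix of class `confusion_matrix3`.
#' @export
confusion_matrix3 <- function(truth, predicted) {
  tt <- factor(label_code(truth), levels = 1:3, labels = label_names)
  pp <- factor(label_code(predicted), levels = 1:3, labels = label_names)
  cm <- unclass(table(truth = tt, predicted = pp))
  structure(cm, class = c("confusion_matrix3", class(cm)))
}

#' Accuracy and macro-averaged recall / precision / F1 from a confusion matrix
#'
#' Per-class recall is `TP / (TP + FN)`, precision `TP / (TP + FP)`, F1
#' their harmonic mean; each macro metric is the unweighted mean over the
#' three classes, with zero-denominator per-class ratios contributing 0.
#' Macro averaging (rather than micro, which equals accuracy) is what makes
#' the metrics informative on heavily imbalanced positioning data.
#'
#' @param cm 3 x 3 count matrix, rows = truth, columns = predicted.
#' @return A list of class `metric_report` with `macro` (one-row tibble:
#'   `accuracy`, `recall`, `precision`, `f1`) and `per_class` (three-row
#'   tibble with class-wise values and counts).
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(3L, 3L)) || any(cm < 0)) {
    abort("cm must be a 3 x 3 non-negative count matrix", class = "mammoqc_input_error")
  }
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix", class = "mammoqc_input_error")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  recall <- safe_div(tp, support)
  precision <- safe_div(tp, predicted)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  structure(
    list(
      macro = tibble::tibble(accuracy = sum(tp) / total, recall = mean(recall),
                             precision = mean(precision), f1 = mean(f1)),
      per_class = tibble::tibble(class = label_names, support = as.integer(support),
                                 recall = recall, precision = precision, f1 = f1)
    ),
    class = "metric_report"
  )
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.metric_report <- function(x, ...) {
  m <- x$macro
  cat(sprintf("accuracy %.4f | macro recall %.4f | macro precision %.4f | macro F1 %.4f\n",
              m$accuracy, m$recall, m$precision, m$f1))
  invisible(x)
}

#' Fivefold cross-validation with a summed confusion matrix
#'
#' For each fold, trains a classifier on the remaining folds, predicts the
#' held-out fold and accumulates the counts; the per-fold confusion matrices
#' are summed into a single matrix from which all metrics are computed.
#'
#' @param data A tibble (or data frame) with a `patch` list-column of image
#'   patches and a `label` column of positioning labels.
#' @param cfg An [eval_config()].
#' @param training A [training_config()]; each fold trains with
#'   `seed = training$seed + fold`.
#' @param trainer Function `(patches, labels, cfg) -> model` whose model
#'   supports `predict(model, patches)` returning a tibble with a `label`
#'   column. Defaults to [train_classifier()]; injectable so reference
#'   classifiers can stand in during testing.
#' @return A list of class `cv_result` with `confusion` (summed
#'   [confusion_matrix3()]), `metrics` (a [compute_metrics()] report),
#'   `folds` (per-fold tibble: `fold`, `n_test`, `accuracy`) and the
#'   configs.
#' @export
cross_validate <- function(data, cfg = eval_config(),
                           training = training_config(),
                           trainer = train_classifier) {
  if (!is.data.frame(data) || is.null(data$patch) || is.null(data$label)) {
    abort("`data` needs a `patch` list-column and a `label` column",
          class = "mammoqc_input_error")
  }
  y <- label_code(data$label)
  folds <- make_folds(y, cfg)
  cm_sum <- matrix(0L, 3L, 3L)
  fold_rows <- vector("list", cfg$k)
  for (f in seq_len(cfg$k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    tcfg <- training
    tcfg$seed <- training$seed + f
    model <- tryCatch(
      trainer(data$patch[train_idx], y[train_idx], tcfg),
      error = function(e) {
        abort(sprintf("training failed in fold %d: %s", f, conditionMessage(e)),
              class = "mammoqc_training_error", parent = e)
      })
    pred <- predict(model, data$patch[test_idx])$label
    cm_f <- confusion_matrix3(y[test_idx], pred)
    cm_sum <- cm_sum + unclass(cm_f)
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = length(test_idx),
                                     accuracy = mean(pred == y[test_idx]))
  }
  cm <- structure(cm_sum, dimnames = list(truth = label_names,
                                          predicted = label_names),
                  class = c("confusion_matrix3", "matrix", "array"))
  structure(
    list(confusion = cm, metrics = compute_metrics(cm),
         folds = dplyr::bind_rows(fold_rows), eval_config = cfg,
         training_config = training),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold, n = %d\n", x$eval_config$k, sum(x$confusion)))
  print(unclass(x$confusion))
  print(x$metrics)
  invisible(x)
}
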