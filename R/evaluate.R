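#' Split design: stratified holdout plus cross-validation folds
#'
#' @param test_fraction fraction sequestered as the untouched holdout
#'   (default 0.10, applied exactly per class).
#' @param stratified stratify by class (default TRUE).
#' @param n_folds number of cross-validation folds over the development
#'   set (default 5).
#' @param seed integer seed.
#' @return list of class `"split_spec"`.
#' @export
split_spec <- function(test_fraction = 0.10, stratified = TRUE, n_folds = 5,
                       seed = 1) {
  if (!is_scalar_num(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1)
    stopf("test_fraction must lie strictly between 0 and 1")
  stopifnot(is_count(n_folds, min = 2L))
  structure(list(test_fraction = test_fraction,
                 stratified = isTRUE(stratified),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "split_spec")
}

#' Create a stratified holdout and disjoint cross-validation folds
#'
#' The holdout is drawn per class (exact `test_fraction`, rounded); the
#' remaining development samples are assigned to `n_folds` disjoint,
#' exhaustive, class-stratified folds. Deterministic given `spec$seed`.
#'
#' @param labels vector of class labels, one per sample.
#' @param spec a [split_spec()].
#' @return list with `holdout` (indices), `dev` (indices) and `folds`
#'   (list of index vectors partitioning `dev`).
#' @export
make_splits <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  y <- factor(labels)
  with_seed(spec$seed, {
    holdout <- integer(0)
    groups <- if (spec$stratified) split(seq_along(y), y)
              else list(all = seq_along(y))
    for (idx in groups) {
      n_test <- round(spec$test_fraction * length(idx))
      holdout <- c(holdout, sample(idx, n_test))
    }
    holdout <- sort(holdout)
    dev <- setdiff(seq_along(y), holdout)
    folds <- vector("list", spec$n_folds)
    dev_groups <- if (spec$stratified) split(dev, y[dev]) else list(all = dev)
    for (idx in dev_groups) {
      if (length(idx) < spec$n_folds)
        stopf("class with %d development samples cannot fill %d folds",
              length(idx), spec$n_folds)
      idx <- sample(idx)
      assign_to <- rep_len(seq_len(spec$n_folds), length(idx))
      for (f in seq_len(spec$n_folds))
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    folds <- lapply(folds, sort)
    list(holdout = holdout, dev = dev, folds = folds)
  })
}

#' Score predictions against true labels
#'
#' Computes accuracy, macro F1 (unweighted mean of per-class F1, zero when
#' a class has no predictions and no recall), and the row-normalized
#' confusion matrix (rows = true classes).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param label_alphabet class labels defining matrix order; defaults to
#'   the union of observed labels.
#' @return list of class `"evaluation_report"` with `accuracy`,
#'   `macro_f1`, `confusion`, `per_class_f1`.
#' @export
evaluate_predictions <- function(y_true, y_pred, label_alphabet = NULL) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred differ in length")
  if (is.null(label_alphabet))
    label_alphabet <- sort(unique(c(as.character(y_true),
                                    as.character(y_pred))))
  bad <- setdiff(unique(as.character(y_pred)), label_alphabet)
  if (length(bad))
    stopf("prediction outside the label alphabet: %s",
          paste(bad, collapse = ", "))
  bad_t <- setdiff(unique(as.character(y_true)), label_alphabet)
  if (length(bad_t))
    stopf("true label outside the label alphabet: %s",
          paste(bad_t, collapse = ", "))
  yt <- factor(as.character(y_true), levels = label_alphabet)
  yp <- factor(as.character(y_pred), levels = label_alphabet)
  counts <- table(true = yt, pred = yp)
  acc <- sum(diag(counts)) / length(yt)
  f1 <- vapply(seq_along(label_alphabet), function(i) {
    tp <- counts[i, i]
    prec_den <- sum(counts[, i])
    rec_den <- sum(counts[i, ])
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  names(f1) <- label_alphabet
  row_n <- rowSums(counts)
  confusion <- sweep(unclass(counts), 1, pmax(row_n, 1), "/")
  structure(list(accuracy = acc, macro_f1 = mean(f1),
                 per_class_f1 = f1, confusion = confusion,
                 n = length(yt)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro F1 %.4f (n = %d)\n",
              x$accuracy, x$macro_f1, x$n))
  cat("row-normalized confusion matrix:\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Composite tuning objective
#'
#' Equal-weight combination `0.5 * macro_f1 + 0.5 * accuracy` used by the
#' hyperparameter search.
#'
#' @param macro_f1,accuracy scalars in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
composite_objective <- function(macro_f1, accuracy) {
  if (!is_scalar_num(macro_f1) || macro_f1 < 0 || macro_f1 > 1)
    stopf("macro_f1 must lie in [0, 1]")
  if (!is_scalar_num(accuracy) || accuracy < 0 || accuracy > 1)
    stopf("accuracy must lie in [0, 1]")
  0.5 * macro_f1 + 0.5 * accuracy
}
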