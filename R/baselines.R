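#' Hyperparameter search space for a baseline family
#'
#' Returns the tuning ranges used for the shallow classifiers:
#' * RF: `n_estimators` 50-500, `max_depth` 5-30, `min_samples_split`
#'   2-20, `min_samples_leaf` 1-10 (all integer);
#' * KNN: `n_neighbors` 1-30, `weights` in uniform/distance, Minkowski
#'   `p` 1-5;
#' * PLS-DA: `n_components` 2-20;
#' * XGBoost: `n_estimators` 50-500, `max_depth` 3-10, `learning_rate`
#'   0.01-0.3 (log scale), `subsample` 0.6-1.0, `colsample_bytree`
#'   0.6-1.0, `min_child_weight` 1-10, `gamma` 0-5.
#'
#' @param family one of `"RF"`, `"KNN"`, `"PLS-DA"`, `"XGBoost"`.
#' @return list of class `"search_space"`; each parameter entry has
#'   `type` (`"int"`, `"float"` or `"cat"`), bounds or `choices`, and a
#'   `log` flag.
#' @export
search_space <- function(family = c("RF", "KNN", "PLS-DA", "XGBoost")) {
  family <- match.arg(family)
  p_int <- function(lo, hi) list(type = "int", low = lo, high = hi, log = FALSE)
  p_flt <- function(lo, hi, log = FALSE)
    list(type = "float", low = lo, high = hi, log = log)
  p_cat <- function(...) list(type = "cat", choices = c(...))
  params <- switch(family,
    "RF" = list(n_estimators = p_int(50, 500), max_depth = p_int(5, 30),
                min_samples_split = p_int(2, 20),
                min_samples_leaf = p_int(1, 10)),
    "KNN" = list(n_neighbors = p_int(1, 30),
                 weights = p_cat("uniform", "distance"),
                 p = p_int(1, 5)),
    "PLS-DA" = list(n_components = p_int(2, 20)),
    "XGBoost" = list(n_estimators = p_int(50, 500), max_depth = p_int(3, 10),
                     learning_rate = p_flt(0.01, 0.3, log = TRUE),
                     subsample = p_flt(0.6, 1.0),
                     colsample_bytree = p_flt(0.6, 1.0),
                     min_child_weight = p_int(1, 10),
                     gamma = p_flt(0, 5)))
  structure(list(family = family, params = params), class = "search_space")
}

.validate_hyperparams <- function(space, hp) {
  for (nm in names(hp)) {
    spec <- space$params[[nm]]
    if (is.null(spec))
      stopf("unknown hyperparameter '%s' for %s", nm, space$family)
    v <- hp[[nm]]
    if (spec$type == "cat") {
      if (!v %in% spec$choices)
        stopf("%s %s='%s' not among allowed options {%s}", space$family, nm,
              v, paste(spec$choices, collapse = ", "))
    } else {
      if (!is_scalar_num(v) || v < spec$low || v > spec$high)
        stopf("%s %s=%s outside the tuning range %s-%s", space$family, nm,
              format(v), format(spec$low), format(spec$high))
      if (spec$type == "int" && v != round(v))
        stopf("%s %s must be an integer", space$family, nm)
    }
  }
  invisible(TRUE)
}

.default_hyperparams <- function(space) {
  lapply(space$params, function(p) {
    if (p$type == "cat") p$choices[[1]]
    else if (p$type == "int") as.integer(round((p$low + p$high) / 2))
    else if (p$log) exp((log(p$low) + log(p$high)) / 2)
    else (p$low + p$high) / 2
  })
}

#' Fit a shallow baseline classifier
#'
#' All baselines consume the same fused feature vectors as the CNN.
#' Implementations: RF via `ranger` (`min.node.size` = minimum size to
#' split, `min.bucket` = minimum terminal size), XGBoost via `xgboost`
#' (multi-class softprob), PLS-DA via `mixOmics::plsda` (one-hot latent
#' regression, arg-max decision), and a weighted-Minkowski k-nearest-
#' neighbour classifier (no installed package covers the distance-weighted
#' Minkowski variants, so the vote is computed here on top of a compiled
#' distance kernel).
#'
#' @param family one of `"RF"`, `"KNN"`, `"PLS-DA"`, `"XGBoost"`.
#' @param hyperparams named list; missing entries fall back to mid-range
#'   defaults. Out-of-range values are rejected with the offending bound.
#' @param features numeric matrix, samples in rows.
#' @param labels class labels.
#' @param seed seed for the stochastic learners (RF, XGBoost).
#' @return list of class `"specfuse_baseline"` with a
#'   [predict.specfuse_baseline()] method.
#' @export
fit_baseline <- function(family, hyperparams = list(), features, labels,
                         seed = 1) {
  space <- search_space(family)
  family <- space$family
  .validate_hyperparams(space, hyperparams)
  hp <- utils::modifyList(.default_hyperparams(space), hyperparams)
  features <- as.matrix(features)
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  fit <- switch(family,
    "RF" = {
      colnames(features) <- paste0("f", seq_len(ncol(features)))
      ranger::ranger(x = features, y = y,
                     num.trees = hp$n_estimators,
                     max.depth = hp$max_depth,
                     min.node.size = hp$min_samples_split,
                     min.bucket = hp$min_samples_leaf,
                     probability = TRUE, num.threads = 1, seed = seed)
    },
    "KNN" = list(x = features, y = y, k = hp$n_neighbors,
                 weights = hp$weights, p = hp$p),
    "PLS-DA" = {
      ncomp <- min(hp$n_components, nrow(features) - 1, ncol(features))
      colnames(features) <- paste0("f", seq_len(ncol(features)))
      mixOmics::plsda(features, y, ncomp = ncomp)
    },
    "XGBoost" = {
      dtrain <- xgboost::xgb.DMatrix(features, label = as.integer(y) - 1L)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = hp$max_depth,
                      eta = hp$learning_rate,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      min_child_weight = hp$min_child_weight,
                      gamma = hp$gamma,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0))
    })
  structure(list(family = family, fit = fit, classes = levels(y),
                 hyperparams = hp, n_features = ncol(features)),
            class = "specfuse_baseline")
}

#' Predict with a fitted baseline
#'
#' @param object a `"specfuse_baseline"`.
#' @param features numeric matrix, samples in rows.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of predicted labels, or a probability/score matrix with
#'   one column per class.
#' @export
predict.specfuse_baseline <- function(object, features,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  features <- as.matrix(features)
  if (ncol(features) != object$n_features)
    stopf("features have %d columns; the model was fitted with %d",
          ncol(features), object$n_features)
  prob <- switch(object$family,
    "RF" = {
      colnames(features) <- paste0("f", seq_len(ncol(features)))
      predict(object$fit, data = features, num.threads = 1)$predictions
    },
    "KNN" = .knn_prob(object$fit, features),
    "PLS-DA" = {
      colnames(features) <- paste0("f", seq_len(ncol(features)))
      pr <- predict(object$fit, newdata = features, dist = "max.dist")
      sc <- pr$predict[, , dim(pr$predict)[3]]
      if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1,
                                         dimnames = list(NULL, names(sc)))
      sc[, object$classes, drop = FALSE]
    },
    "XGBoost" = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(features))
      if (is.null(dim(p)))
        p <- matrix(p, ncol = length(object$classes), byrow = TRUE)
      dimnames(p) <- list(NULL, object$classes)
      p
    })
  prob <- prob[, object$classes, drop = FALSE]
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

# Distance-weighted Minkowski KNN vote shares.
.knn_prob <- function(fit, newdata) {
  D <- cpp_minkowski(newdata, fit$x, fit$p)
  k <- min(fit$k, ncol(D))
  classes <- levels(fit$y)
  out <- matrix(0, nrow(newdata), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ])[seq_len(k)]
    w <- if (fit$weights == "distance") 1 / (D[i, ord] + 1e-12) else rep(1, k)
    tab <- tapply(w, fit$y[ord], sum, default = 0)
    out[i, names(tab)] <- tab / sum(w)
  }
  out
}
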