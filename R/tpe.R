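# Independent univariate Tree-structured Parzen Estimator.
#
# Observed trials are split into a "good" set (top gamma quantile of the
# objective) and a "bad" set; per-parameter Parzen mixtures l(x) and g(x)
# are fitted over each set (Gaussian kernels for numeric parameters,
# smoothed category frequencies for categorical ones, each mixed with a
# uniform prior component), candidates are drawn from l and ranked by the
# density ratio l/g, and the best candidate is evaluated next.

.tpe_unit <- function(v, p) {
  if (p$log) (log(v) - log(p$low)) / (log(p$high) - log(p$low))
  else (v - p$low) / (p$high - p$low)
}

.tpe_from_unit <- function(u, p) {
  v <- if (p$log) exp(log(p$low) + u * (log(p$high) - log(p$low)))
       else p$low + u * (p$high - p$low)
  v <- min(max(v, p$low), p$high)
  if (p$type == "int") as.integer(round(v)) else v
}

.tpe_mix_density <- function(x, obs, bw) {
  # Parzen mixture over `obs` plus a uniform prior component on [0, 1]
  if (length(obs) == 0) return(1)
  kern <- vapply(x, function(xx) mean(dnorm(xx, mean = obs, sd = bw)),
                 numeric(1))
  (length(obs) * kern + 1) / (length(obs) + 1)
}

.tpe_sample_param <- function(p, good, bad, n_cand) {
  if (p$type == "cat") {
    kc <- length(p$choices)
    cg <- table(factor(good, levels = p$choices))
    cb <- table(factor(bad, levels = p$choices))
    pg <- (cg + 1) / sum(cg + 1)
    pb <- (cb + 1) / sum(cb + 1)
    cand <- sample(p$choices, n_cand, replace = TRUE, prob = pg)
    list(cand = cand,
         score = log(pg[cand]) - log(pb[cand]))
  } else {
    ug <- .tpe_unit(good, p)
    ub <- .tpe_unit(bad, p)
    bw_of <- function(u) {
      if (length(u) < 2) return(0.25)
      max(1.06 * sd(u) * length(u)^(-0.2), 0.05)
    }
    bwg <- bw_of(ug)
    bwb <- bw_of(ub)
    cand_u <- if (length(ug)) {
      centres <- sample(ug, n_cand, replace = TRUE)
      pmin(pmax(rnorm(n_cand, centres, bwg), 0), 1)
    } else runif(n_cand)
    cand <- vapply(cand_u, .tpe_from_unit, if (p$type == "int") 1L else 1.0,
                   p = p)
    cand_u <- vapply(cand, .tpe_unit, numeric(1), p = p)  # after rounding
    list(cand = cand,
         score = log(.tpe_mix_density(cand_u, ug, bwg)) -
                 log(.tpe_mix_density(cand_u, ub, bwb)))
  }
}

.tpe_random_config <- function(space) {
  lapply(space$params, function(p) {
    if (p$type == "cat") sample(p$choices, 1)
    else .tpe_from_unit(runif(1), p)
  })
}

.tpe_propose <- function(space, trials, values, gamma = 0.25,
                         n_cand = 24) {
  n <- length(values)
  n_good <- max(1L, ceiling(gamma * n))
  ord <- order(values, decreasing = TRUE)
  good_idx <- ord[seq_len(n_good)]
  bad_idx <- ord[-seq_len(n_good)]
  cand_score <- rep(0, n_cand)
  config_cand <- vector("list", length(space$params))
  names(config_cand) <- names(space$params)
  for (nm in names(space$params)) {
    p <- space$params[[nm]]
    good <- vapply(trials[good_idx], function(tr) tr[[nm]],
                   if (p$type == "cat") character(1) else numeric(1))
    bad <- vapply(trials[bad_idx], function(tr) tr[[nm]],
                  if (p$type == "cat") character(1) else numeric(1))
    sp <- .tpe_sample_param(p, good, bad, n_cand)
    config_cand[[nm]] <- sp$cand
    cand_score <- cand_score + as.numeric(sp$score)
  }
  best <- which.max(cand_score)
  lapply(config_cand, function(v) {
    x <- v[[best]]
    if (is.numeric(x) && x == round(x) && !is.character(x)) x else x
  })
}

#' Tune baseline hyperparameters with a Tree-structured Parzen Estimator
#'
#' Maximizes the composite objective `0.5 * macro_f1 + 0.5 * accuracy`,
#' averaged over stratified cross-validation folds of the development set.
#' The first trials are sampled uniformly from the search space; later
#' trials are proposed by the TPE density-ratio rule.
#'
#' @param family baseline family (see [search_space()]).
#' @param space a `"search_space"`; defaults to the family's ranges.
#' @param features development feature matrix, samples in rows.
#' @param labels development labels.
#' @param n_trials number of configurations evaluated (default 50).
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for sampling and fold assignment.
#' @return list with `best_params`, `best_value`, and `trials` (a data
#'   frame logging every configuration and its objective).
#' @export
tune_hyperparameters <- function(family, space = search_space(family),
                                 features, labels, n_trials = 50,
                                 folds = 5, seed = 1) {
  stopifnot(inherits(space, "search_space"), is_count(n_trials))
  features <- as.matrix(features)
  if (nrow(features) == 0) stopf("empty development set")
  y <- factor(labels)
  if (length(y) != nrow(features))
    stopf("labels and features disagree in length")
  fold_id <- with_seed(child_seed(seed, "folds"), {
    id <- integer(length(y))
    for (idx in split(seq_along(y), y))
      id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    id
  })
  objective <- function(hp) {
    vals <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (!any(tr) || !any(!tr)) return(NA_real_)
      fit <- fit_baseline(family, hp, features[tr, , drop = FALSE], y[tr],
                          seed = child_seed(seed, paste0("fit", f)))
      pred <- predict(fit, features[!tr, , drop = FALSE])
      rep <- evaluate_predictions(y[!tr], pred, levels(y))
      composite_objective(rep$macro_f1, rep$accuracy)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  n_startup <- min(10L, max(2L, n_trials %/% 4L))
  trials <- vector("list", n_trials)
  values <- numeric(n_trials)
  with_seed(child_seed(seed, "tpe"), {
    for (t in seq_len(n_trials)) {
      hp <- if (t <= n_startup || t <= 2) .tpe_random_config(space)
            else .tpe_propose(space, trials[seq_len(t - 1)],
                              values[seq_len(t - 1)])
      trials[[t]] <- hp
      values[t] <- objective(hp)
    }
  })
  best <- which.max(values)
  log_df <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    row <- as.data.frame(trials[[t]], stringsAsFactors = FALSE)
    row$objective <- values[t]
    row$trial <- t
    row
  }))
  list(best_params = trials[[best]], best_value = values[best],
       trials = log_df)
}
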