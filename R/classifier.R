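#' Confusion-matrix and ranking metrics for binary classification
#'
#' Computes accuracy, sensitivity, specificity, precision and F1-score at a
#' decision threshold (ADHD = 1 is the positive class), plus the AUC by the
#' rank (Mann-Whitney) formulation: the probability that a random positive
#' outranks a random negative, with ties counting one half.
#'
#' @param labels 0/1 vector of true classes.
#' @param scores numeric prediction scores.
#' @param threshold decision threshold for the confusion-matrix metrics.
#' @return Named list `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`. `auc` is `NA` when one class is absent.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  auc <- if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: one class absent")
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sensitivity <- if (n1 > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  list(auc = auc,
       accuracy = (tp + tn) / length(labels),
       sensitivity = sensitivity,
       specificity = if (n0 > 0) tn / (tn + fp) else NA_real_,
       precision = precision,
       f1 = f1)
}

#' Fit a gradient-boosted tree classifier
#'
#' Thin wrapper over `xgboost::xgb.train` with binary logistic loss and the
#' library's default hyperparameters.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y 0/1 labels.
#' @param nrounds number of boosting rounds.
#' @param params extra xgboost parameters (merged over the defaults).
#' @param seed integer seed fixing the tree construction.
#' @return The fitted `xgb.Booster`.
#' @export
fit_boosted <- function(x, y, nrounds = 100, params = list(), seed = 0) {
  ## exact greedy splitting: for cohort-sized tables the histogram sketch
  ## buys nothing and its bin-edge thresholds generalize poorly at margins
  base <- list(objective = "binary:logistic", nthread = 1,
               tree_method = "exact",
               seed = as.integer(seed %% .Machine$integer.max))
  dm <- xgboost::xgb.DMatrix(data = x, label = y)
  xgboost::xgb.train(params = utils::modifyList(base, params),
                     data = dm, nrounds = nrounds, verbose = 0)
}

#' Split-gain variable importance of fitted boosters
#'
#' Sums the split gain of each variable over all trees of each booster and
#' averages across boosters, yielding the aggregate contribution of each
#' variable to the ensemble; variables never used to split have gain 0.
#'
#' @param models a fitted `xgb.Booster` or a list of them.
#' @param feature_names full feature-name vector (so unused features appear
#'   with zero gain).
#' @return Data frame `variable`, `gain`, sorted by decreasing gain.
#' @export
variable_importance <- function(models, feature_names = NULL) {
  if (inherits(models, "xgb.Booster")) models <- list(models)
  if (!length(models)) stop("no fitted models supplied")
  acc <- list()
  for (m in models) {
    imp <- safe_importance(m, feature_names %||% "f0")
    raw <- stats::setNames(imp$Gain, imp$Feature)
    for (f in names(raw)) acc[[f]] <- (acc[[f]] %||% 0) + raw[[f]]
  }
  gains <- vapply(acc, identity, 0) / length(models)
  if (!is.null(feature_names)) {
    full <- stats::setNames(rep(0, length(feature_names)), feature_names)
    full[names(gains)] <- gains
    gains <- full
  }
  out <- data.frame(variable = names(gains), gain = unname(gains),
                    stringsAsFactors = FALSE)
  out[order(-out$gain), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## xgb.importance of the installed xgboost crashes on single-feature models;
## in that degenerate case all gain belongs to the lone feature
safe_importance <- function(model, feature_names) {
  tryCatch(
    xgboost::xgb.importance(model = model),
    error = function(e) data.frame(Feature = feature_names,
                                   Gain = 1 / length(feature_names)))
}

## per-class balanced fold assignment; classes with leftover samples place
## them on the folds currently holding the fewest, so total fold sizes differ
## by at most one (e.g. 43/44 held out of 216)
make_stratified_folds <- function(labels, n_folds, max_tries = 100) {
  n <- length(labels)
  for (tries in seq_len(max_tries)) {
    fold <- integer(n)
    totals <- integer(n_folds)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      m <- length(idx)
      sizes <- rep(m %/% n_folds, n_folds)
      extra <- m %% n_folds
      if (extra > 0) {
        ord <- order(totals + runif(n_folds) * 0.5)
        sizes[ord[seq_len(extra)]] <- sizes[ord[seq_len(extra)]] + 1L
      }
      fold[idx] <- sample(rep(seq_len(n_folds), sizes))
      totals <- totals + sizes
    }
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(labels[fold != k])) >= 2
    }, TRUE))
    if (ok) return(fold)
  }
  stop("could not draw folds with both classes in every training set")
}

make_plain_folds <- function(n, n_folds, labels, max_tries = 100) {
  for (tries in seq_len(max_tries)) {
    fold <- sample(rep_len(seq_len(n_folds), n))
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(labels[fold != k])) >= 2 && any(fold == k)
    }, TRUE))
    if (ok) return(fold)
  }
  stop("could not draw folds with both classes in every training set")
}

#' Repeated stratified cross-validation of the biomarker classifier
#'
#' For each repeat, draws a fresh stratified `n_folds`-fold partition; within
#' each fold, variable filtering ([filter_variables()]) and median imputation
#' are fitted on the training portion only (no leakage), a gradient-boosted
#' classifier is trained, and the held-out samples are scored. Held-out
#' scores are pooled per repeat into one set of metrics, and the aggregate
#' report gives the mean and percentile 95% CI over repeats. Deterministic
#' for a fixed `seed`.
#'
#' @param ft a `feature_table` with a `label` column (or a list with `x` and
#'   `labels`).
#' @param n_repeats number of repeats (the study design uses 500).
#' @param n_folds number of folds.
#' @param seed base random seed.
#' @param stratified stratify folds by class.
#' @param filter_alpha Mann-Whitney alpha for within-fold filtering; `NA`
#'   disables filtering.
#' @param nrounds boosting rounds per fit.
#' @param params extra xgboost parameters.
#' @param keep_models keep fitted boosters of the first repeat (for
#'   importance inspection).
#' @return An object of class `eval_report`: `per_repeat` (data frame of
#'   per-repeat metrics), `summary` (mean and 2.5/97.5 percentiles per
#'   metric), `importance` (aggregated split gain), `config`.
#' @export
run_repeated_cv <- function(ft, n_repeats = 500, n_folds = 5, seed = 1,
                            stratified = TRUE, filter_alpha = 0.05,
                            nrounds = 100, params = list(),
                            keep_models = FALSE) {
  if (inherits(ft, "feature_table") || is.data.frame(ft)) {
    x <- feature_matrix(ft)
    labels <- ft$label
  } else {
    x <- ft$x
    labels <- ft$labels
  }
  stopifnot(length(unique(labels)) >= 2, n_folds >= 2, n_repeats >= 1)
  bad <- colnames(x)[apply(x, 2, function(v) any(!is.finite(v) & !is.na(v)))]
  if (length(bad)) stop("non-finite feature values in: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  metric_names <- c("auc", "accuracy", "sensitivity", "specificity",
                    "precision", "f1")
  per_repeat <- matrix(NA_real_, n_repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  gain_acc <- stats::setNames(rep(0, ncol(x)), colnames(x))
  n_models <- 0L
  first_models <- list()
  for (rep_i in seq_len(n_repeats)) {
    set.seed((seed * 1009L + rep_i) %% 2147483647L)
    fold <- if (stratified) {
      make_stratified_folds(labels, n_folds)
    } else {
      make_plain_folds(length(labels), n_folds, labels)
    }
    scores <- rep(NA_real_, length(labels))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      te <- !tr
      keep <- if (is.na(filter_alpha)) {
        seq_len(ncol(x))
      } else {
        suppressWarnings(
          filter_variables(x[tr, , drop = FALSE], labels[tr], filter_alpha))
      }
      imp <- impute_median(x[tr, keep, drop = FALSE],
                           x[te, keep, drop = FALSE])
      model <- fit_boosted(imp$train, labels[tr], nrounds = nrounds,
                           params = params,
                           seed = seed * 7919L + rep_i * 97L + k)
      scores[te] <- stats::predict(model, xgboost::xgb.DMatrix(imp$test))
      g <- safe_importance(model, colnames(x)[keep])
      gain_acc[g$Feature] <- gain_acc[g$Feature] + g$Gain
      n_models <- n_models + 1L
      if (keep_models && rep_i == 1L) first_models[[k]] <- model
    }
    per_repeat[rep_i, ] <- unlist(classification_metrics(labels, scores))
  }
  per_repeat <- as.data.frame(per_repeat)
  summary <- data.frame(
    metric = metric_names,
    mean = colMeans(per_repeat),
    ci_lower = apply(per_repeat, 2, stats::quantile, 0.025),
    ci_upper = apply(per_repeat, 2, stats::quantile, 0.975),
    row.names = NULL)
  importance <- data.frame(variable = names(gain_acc),
                           gain = unname(gain_acc) / n_models,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$gain), , drop = FALSE]
  rownames(importance) <- NULL
  structure(list(per_repeat = per_repeat, summary = summary,
                 importance = importance,
                 models = if (keep_models) first_models,
                 config = list(n_repeats = n_repeats, n_folds = n_folds,
                               seed = seed, stratified = stratified,
                               filter_alpha = filter_alpha,
                               nrounds = nrounds)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV x %d repeats\n",
              x$config$n_folds, x$config$n_repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", s$metric[i], s$mean[i],
                s$ci_lower[i], s$ci_upper[i]))
  }
  cat("  top variables: ",
      paste(utils::head(x$importance$variable[x$importance$gain > 0], 5),
            collapse = ", "), "\n")
  invisible(x)
}
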