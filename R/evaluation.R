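#' Classification metrics from a confusion table
#'
#' Patient is the positive class. Undefined ratios (zero denominators) are
#' reported as `NA`, not 0.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion table")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(tp, tp + fn)
  prec <- rat(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(accuracy = (tp + tn) / total, sensitivity = sens,
       specificity = rat(tn, tn + fp), precision = prec, f1 = f1)
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann–Whitney statistic: the probability that a random positive scores above
#' a random negative, with ties contributing 1/2.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split plans
#'
#' Repeated random splits at a fixed test proportion (default 45/345,
#' the standard 300-train / 45-test split scaled to the cohort), stratified by
#' class, with every repeat's seed derived from a master seed.
#'
#' @param labels 0/1 cohort labels.
#' @param n_repeats Number of repeats (default 10).
#' @param test_fraction Test proportion (default 45/345).
#' @param seed Master seed.
#' @return List of plans, each with `repeat_index`, `train`, `test`, `seed`.
#' @export
make_split_plans <- function(labels, n_repeats = 10L,
                             test_fraction = 45 / 345, seed = 1L) {
  set.seed(seed)
  plan_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  lapply(seq_len(n_repeats), function(i) {
    set.seed(plan_seeds[i])
    test <- stratified_holdout(labels, test_fraction)
    list(repeat_index = i, train = setdiff(seq_along(labels), test),
         test = test, seed = plan_seeds[i])
  })
}

#' Repeated random-split evaluation
#'
#' For each repeat: stratified split, feature standardization fitted on the
#' training subjects only, GCN training with an internal validation split,
#' then evaluation on the held-out test subjects with accuracy, AUC,
#' sensitivity, specificity, F1 and precision. Reports per-repeat and mean
#' metrics; every seed derives from `seed`.
#'
#' @param dataset List of `brain_graph` samples (unstandardized).
#' @param n_repeats Number of random splits (default 10).
#' @param model_cfg,train_cfg Model / training configurations.
#' @param test_fraction Test proportion (default 45/345).
#' @param seed Master seed.
#' @param keep_models Keep the trained model of every repeat (for saliency).
#' @return A list of class `metrics_report` with `per_repeat` (data.frame),
#'   `mean` (named list), `plans`, and optionally `models`.
#' @export
repeated_split_eval <- function(dataset, n_repeats = 10L,
                                model_cfg = model_config(),
                                train_cfg = train_config(),
                                test_fraction = 45 / 345, seed = 1L,
                                keep_models = FALSE) {
  labels <- vapply(dataset, `[[`, integer(1), "label")
  plans <- make_split_plans(labels, n_repeats, test_fraction, seed)
  rows <- vector("list", n_repeats)
  models <- if (keep_models) vector("list", n_repeats) else NULL
  for (i in seq_len(n_repeats)) {
    pl <- plans[[i]]
    sc <- zscore_features(dataset, pl$train)
    tc <- train_cfg
    tc$seed <- pl$seed
    model <- train_gcn(sc$dataset, pl$train, model_cfg, tc)
    if (keep_models) {
      models[[i]] <- list(model = model, plan = pl, scaler = sc$scaler)
    }
    probs <- predict_proba(model, sc$dataset[pl$test])
    pred <- as.integer(probs >= 0.5)
    truth <- labels[pl$test]
    tp <- sum(pred == 1L & truth == 1L); fp <- sum(pred == 1L & truth == 0L)
    tn <- sum(pred == 0L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
    m <- confusion_metrics(tp, fp, tn, fn)
    rows[[i]] <- data.frame(
      repeat_index = i, accuracy = m$accuracy,
      auc = auc_rank(truth, probs), sensitivity = m$sensitivity,
      specificity = m$specificity, f1 = m$f1, precision = m$precision,
      tp = tp, fp = fp, tn = tn, fn = fn, best_epoch = model$best_epoch
    )
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "auc", "sensitivity", "specificity",
                   "f1", "precision")
  means <- as.list(colMeans(per_repeat[metric_cols], na.rm = TRUE))
  structure(list(per_repeat = per_repeat, mean = means, plans = plans,
                 models = models, seed = seed),
            class = "metrics_report")
}

#' Sparsity sweep
#'
#' Rebuilds the binarized graphs at each retained-edge fraction (default 5% to
#' 50% in 5% steps) and runs [repeated_split_eval()] at each, returning a
#' per-sparsity summary table.
#'
#' @param derived_list Per-subject [subject_derived()] outputs.
#' @param labels Cohort labels.
#' @param spec Graph-type spec (its `sparsity` field is overridden).
#' @param sparsities Sweep grid.
#' @param ... Passed to [repeated_split_eval()].
#' @return A list with `table` (one row per sparsity: mean metrics) and
#'   `reports`.
#' @export
sparsity_sweep <- function(derived_list, labels, spec,
                           sparsities = seq(0.05, 0.50, by = 0.05), ...) {
  reports <- lapply(sparsities, function(sp) {
    spec$sparsity <- sp
    ds <- build_graph_dataset(derived_list, labels, spec)
    repeated_split_eval(ds, ...)
  })
  tab <- do.call(rbind, lapply(seq_along(sparsities), function(i)
    data.frame(sparsity = sparsities[i], as.data.frame(reports[[i]]$mean))))
  list(table = tab, reports = reports)
}

#' Welch two-sample t statistic from summary data
#'
#' Unequal-variance form: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`. Computed
#' from the printed group summaries (mean, SD, n), as used for demographic
#' group comparisons.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return The t statistic.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  (mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
}

#' Continuity-corrected chi-squared statistic of a 2x2 table
#'
#' Yates-corrected Pearson chi-squared with expected counts from the margins:
#' `sum((max(|O - E| - 0.5, 0))^2 / E)`, df = 1.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = categories
#'   (table `rbind(c(a, b), c(c, d))`).
#' @return The chi-squared statistic.
#' @export
chi2_yates <- function(a, b, c, d) {
  o <- rbind(c(a, b), c(c, d))
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) stop("zero margin")
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
}
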