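test_that("confusion metrics: perfect, degenerate and hand-computed cases", {
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(unlist(perfect) == 1))

  degen <- confusion_metrics(0, 0, 10, 10)
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$specificity, 1)
  expect_true(is.na(degen$precision))

  m <- confusion_metrics(8, 3, 9, 5)
  expect_equal(m$accuracy, 17 / 25)
  expect_equal(m$sensitivity, 8 / 13)
  expect_equal(m$specificity, 9 / 12)
  expect_equal(m$precision, 8 / 11)
  expect_equal(m$f1, 2 * (8 / 11) * (8 / 13) / (8 / 11 + 8 / 13))

  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("rank AUC: separation, ties, exhaustive pairwise oracle", {
  expect_equal(auc_rank(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)

  set.seed(91)
  lab <- rep(0:1, each = 500)
  expect_lt(abs(auc_rank(lab, rnorm(1000)) - 0.5), 0.06)

  lab6 <- c(0, 0, 0, 1, 1, 1)
  sc6 <- c(0.1, 0.4, 0.4, 0.4, 0.7, 0.9)   # one cross-class tie
  expect_equal(auc_rank(lab6, sc6), auc_oracle(lab6, sc6))
  for (i in 1:20) {
    lab_r <- sample(0:1, 8, replace = TRUE)
    if (length(unique(lab_r)) < 2) next
    sc_r <- sample(seq(0, 1, 0.25), 8, replace = TRUE)
    expect_equal(auc_rank(lab_r, sc_r), auc_oracle(lab_r, sc_r))
  }
  expect_error(auc_rank(rep(1, 4), rnorm(4)), "classes")
})

test_that("summary-data Welch t: demographic reproduction, antisymmetry, oracle", {
  expect_equal(welch_t(12.84, 2.83, 205, 10.69, 3.32, 140), 6.260,
               tolerance = 0.02)
  expect_equal(welch_t(5, 1, 30, 5, 1, 30), 0)
  expect_equal(welch_t(12.84, 2.83, 205, 10.69, 3.32, 140),
               -welch_t(10.69, 3.32, 140, 12.84, 2.83, 205))

  x <- c(1.2, 3.4, 2.2, 4.8); y <- c(0.7, 1.9, 1.1, 2.0, 1.4)
  got <- welch_t(mean(x), sd(x), 4, mean(y), sd(y), 5)
  ref <- unname(t.test(x, y, var.equal = FALSE)$statistic)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("Yates chi-squared: demographic reproduction, invariances, oracle", {
  expect_equal(chi2_yates(110, 95, 95, 45), 6.378, tolerance = 0.01)
  # perfectly proportional table: correction floors at zero
  expect_equal(chi2_yates(20, 40, 10, 20), 0)
  expect_equal(chi2_yates(110, 95, 95, 45), chi2_yates(95, 45, 110, 95))
  expect_equal(chi2_yates(110, 95, 95, 45), chi2_yates(95, 110, 45, 95))

  set.seed(93)
  for (i in 1:10) {
    tab <- matrix(sample(5:60, 4), 2)
    got <- chi2_yates(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- unname(suppressWarnings(chisq.test(tab, correct = TRUE)$statistic))
    expect_equal(got, ref, tolerance = 1e-10)
  }
  expect_error(chi2_yates(0, 0, 3, 4), "margin")
})

test_that("split plans: disjoint, exhaustive, stratified, reproducible", {
  labels <- rep(c(0L, 1L), c(30, 20))
  plans <- make_split_plans(labels, n_repeats = 5, seed = 7)
  for (pl in plans) {
    expect_length(intersect(pl$train, pl$test), 0L)
    expect_setequal(c(pl$train, pl$test), seq_along(labels))
    expect_true(all(table(labels[pl$test]) >= 1))
    expect_true(all(table(labels[pl$train]) >= 1))
  }
  plans2 <- make_split_plans(labels, n_repeats = 5, seed = 7)
  expect_identical(plans, plans2)
  expect_false(identical(plans[[1]]$test, plans[[2]]$test))
})

test_that("repeated-split evaluation: means, leakage audit, determinism", {
  ds <- random_graph_dataset(20, 12, 3, seed = 97)
  cfg <- model_config(hidden_dim = 6, pool_ratio = 0.8)
  tc <- train_config(learning_rate = 1e-2, batch_size = 10, max_epochs = 3,
                     patience = 1, seed = 1)
  rep1 <- repeated_split_eval(ds, n_repeats = 3, model_cfg = cfg,
                              train_cfg = tc, test_fraction = 0.25, seed = 5)
  expect_equal(nrow(rep1$per_repeat), 3L)
  for (col in c("accuracy", "auc", "sensitivity", "specificity")) {
    vals <- rep1$per_repeat[[col]]
    expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
    expect_equal(rep1$mean[[col]], mean(vals, na.rm = TRUE))
  }
  # confusion counts add up to the test-set size in every repeat
  n_test <- vapply(rep1$plans, function(p) length(p$test), integer(1))
  expect_equal(rep1$per_repeat$tp + rep1$per_repeat$fp +
                 rep1$per_repeat$tn + rep1$per_repeat$fn, n_test)

  rep2 <- repeated_split_eval(ds, n_repeats = 3, model_cfg = cfg,
                              train_cfg = tc, test_fraction = 0.25, seed = 5)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
})

test_that("sparsity sweep: default grid, monotone edge counts, sweep table", {
  expect_length(seq(0.05, 0.50, by = 0.05), 10L)

  set.seed(99)
  m <- random_sym_matrix(30)
  counts <- vapply(seq(0.05, 0.5, by = 0.05), function(p)
    sum(suppressWarnings(proportional_binarize(m, p))$values) / 2, numeric(1))
  expect_true(all(diff(counts) > 0))

  atlas <- tiny_atlas(10L)
  cfg <- tiny_config(n_control = 8L, n_patient = 8L, seed = 43)
  co <- simulate_cohort(atlas, cfg)
  derived <- cohort_derived(co)
  spec <- braingcn:::graph_type_spec(10L, "FBM", "fMRI", 0.5)
  sw <- suppressWarnings(sparsity_sweep(
    derived, co$labels, spec, sparsities = c(0.5, 0.6),
    n_repeats = 2,
    model_cfg = model_config(hidden_dim = 4, pool_ratio = 0.8),
    train_cfg = train_config(learning_rate = 1e-2, batch_size = 8,
                             max_epochs = 2, patience = 1),
    test_fraction = 0.25, seed = 3))
  expect_equal(sw$table$sparsity, c(0.5, 0.6))
  expect_true(all(sw$table$accuracy >= 0 & sw$table$accuracy <= 1))
})

test_that("null cohorts are exchangeable for a downstream classifier", {
  skip_if_not_installed("e1071")
  atlas <- tiny_atlas(12L)
  cfg <- cohort_config(n_control = 30, n_patient = 30, seed = 13,
                       n_timepoints = 60)
  co <- simulate_cohort(atlas, cfg)
  # node features only (no graphs needed for this property)
  feats <- t(vapply(co$subjects, function(s)
    c(roi_mean_volume(s, "gm"), roi_mean_volume(s, "wm")), numeric(24)))
  mean_acc <- function(labels, split_seed) {
    set.seed(split_seed)
    mean(vapply(1:20, function(i) {
      test <- c(sample(which(labels == 0), 8),
                sample(which(labels == 1), 8))
      train <- setdiff(seq_len(60), test)
      fit <- e1071::svm(feats[train, ], factor(labels[train]),
                        kernel = "linear")
      mean(predict(fit, feats[test, ]) == factor(labels[test]))
    }, numeric(1)))
  }
  observed <- mean_acc(co$labels, split_seed = 17)
  # the 20 random splits share subjects, so the observed mean accuracy is
  # compared against a label-permutation null with the same split scheme
  # rather than against independent-trial binomial bounds
  set.seed(19)
  null_dist <- vapply(1:30, function(b)
    mean_acc(sample(co$labels), split_seed = 17 + b), numeric(1))
  expect_gte(observed, quantile(null_dist, 0.025) - 1e-9)
  expect_lte(observed, quantile(null_dist, 0.975) + 1e-9)
})
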