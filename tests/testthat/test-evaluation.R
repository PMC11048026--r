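test_that("Mann-Whitney AUC equals explicit pair counting", {
  expect_equal(mann_whitney_auc(c(1, 2), c(1.5, 3)), 0.75)
  expect_equal(mann_whitney_auc(1, 1), 0.5) # full tie
  expect_equal(mann_whitney_auc(c(0, 0.1), c(5, 6)), 1)
  expect_error(mann_whitney_auc(numeric(0), 1), "non-empty")

  # exact equivalence with brute force on 100 random instances (with ties)
  with_seed(42, {
    for (i in 1:100) {
      n0 <- sample(1:50, 1)
      n1 <- sample(1:50, 1)
      t0 <- sample(seq(0, 5, by = 0.5), n0, replace = TRUE)
      t1 <- sample(seq(0.25, 5, by = 0.5), n1, replace = TRUE) +
        sample(c(0, 0.25), n1, replace = TRUE)
      expect_identical(mann_whitney_auc(t0, t1), brute_force_auc(t0, t1))
    }
  })
})

test_that("ROC staircase has exact endpoints, monotonicity and area", {
  with_seed(17, {
    for (i in 1:100) {
      t0 <- rnorm(sample(5:40, 1))
      t1 <- rnorm(sample(5:40, 1), mean = runif(1, 0, 2))
      if (i %% 3 == 0) { # inject ties
        t0 <- round(t0)
        t1 <- round(t1)
      }
      roc <- roc_points(t0, t1)
      expect_equal(roc$fpr[1], 0)
      expect_equal(roc$tpr[1], 0)
      expect_equal(roc$fpr[nrow(roc)], 1)
      expect_equal(roc$tpr[nrow(roc)], 1)
      expect_true(all(diff(roc$fpr) >= 0))
      expect_true(all(diff(roc$tpr) >= 0))
      expect_equal(taskmo:::trapezoid_area(roc), mann_whitney_auc(t0, t1),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC estimator agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  with_seed(23, {
    t0 <- rnorm(80)
    t1 <- rnorm(60, 1)
    ours <- mann_whitney_auc(t0, t1)
    ref <- as.numeric(pROC::auc(
      response = rep(c(0, 1), c(80, 60)), predictor = c(t0, t1),
      direction = "<", quiet = TRUE
    ))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("bootstrap CI is seeded, ordered and shrinks with sample size", {
  with_seed(31, {
    t0s <- rnorm(2000)
    t1s <- rnorm(2000, 1.2)
  })
  ci_small <- auc_confidence_interval(t0s[1:20], t1s[1:20], seed = 5)
  ci_big <- auc_confidence_interval(t0s, t1s, seed = 5)
  expect_lt(diff(ci_big), diff(ci_small))
  expect_identical(auc_confidence_interval(t0s[1:50], t1s[1:50], seed = 9),
                   auc_confidence_interval(t0s[1:50], t1s[1:50], seed = 9))
  # perfectly separated: upper bound 1
  ci_sep <- auc_confidence_interval(rnorm(100), rnorm(100) + 50, seed = 2)
  expect_equal(ci_sep[["high"]], 1)
  expect_error(auc_confidence_interval(rnorm(5), rnorm(50)), "at least 10")
})

test_that("train/val/test split is disjoint, stratified and seeded", {
  ds <- make_task_dataset(task16(), 100, seed = 50)
  sp <- train_val_test_split(ds, c(train = 100, val = 40, test = 40), seed = 3)
  ia <- attr(sp$train, "split_indices")
  ib <- attr(sp$val, "split_indices")
  ic <- attr(sp$test, "split_indices")
  expect_length(intersect(ia, ib), 0)
  expect_length(intersect(ia, ic), 0)
  expect_length(intersect(ib, ic), 0)
  for (part in sp) {
    expect_equal(sum(part$labels == 0), sum(part$labels == 1))
  }
  sp2 <- train_val_test_split(ds, c(train = 100, val = 40, test = 40), seed = 3)
  expect_identical(attr(sp2$train, "split_indices"), ia)
  expect_error(
    train_val_test_split(ds, c(train = 150, val = 40, test = 40), seed = 1),
    "only"
  )
  expect_error(
    train_val_test_split(ds, c(train = 99, val = 40, test = 40), seed = 1),
    "even"
  )
})

test_that("learning curve bookkeeping: rows, constant HO reference, failures", {
  task <- task16()
  lc <- learning_curve_experiment(
    task, observers = c("ho_sample", "pca_svm"),
    sizes = c(40, 80), repeats = 2, seed = 6, n_val = 40, n_test = 200,
    observer_args = list(pca_svm = list(
      config = cdae_config(1, 4, 5),
      C_grid = c(1, 10), sigma_grid = c(1, 5)
    ))
  )
  expect_equal(nrow(lc$results), 2 * 2 * 2) # observers x sizes x repeats
  expect_true(all(c("observer", "size", "rep", "auc", "fit_seconds", "seed")
                  %in% names(lc$results)))
  # the HO reference is a single constant, independent of training size
  expect_length(lc$ho_reference$auc_empirical, 1)
  expect_equal(lc$ho_reference$auc_analytic, 0.9, tolerance = 0.05)
  expect_true(all(is.finite(lc$results$auc)))
  expect_error(
    learning_curve_experiment(task, "ho_sample", sizes = c(80, 40), repeats = 1),
    "increasing"
  )
})
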