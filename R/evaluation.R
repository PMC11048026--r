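#' Mann-Whitney AUC estimator
#'
#' The nonparametric AUC: the fraction of (signal-absent, signal-present)
#' score pairs with the signal-present score higher, ties counted one half.
#' Computed via midranks, which equals brute-force pair counting exactly and
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param t_absent,t_present test statistics of the two classes (non-empty).
#' @return AUC in [0, 1].
#' @export
mann_whitney_auc <- function(t_absent, t_present) {
  n0 <- length(t_absent)
  n1 <- length(t_present)
  if (n0 == 0 || n1 == 0) stop_taskmo("both classes must be non-empty")
  r <- rank(c(t_absent, t_present), ties.method = "average")
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Empirical ROC curve points
#'
#' Sweeps the decision threshold over the pooled unique score values
#' (rule: positive when score >= threshold) and returns the (FPR, TPR)
#' staircase including the (0,0) and (1,1) endpoints. Its trapezoidal area
#' equals [mann_whitney_auc()].
#'
#' @param t_absent,t_present test statistics of the two classes.
#' @return data frame with `fpr` and `tpr`, monotone nondecreasing.
#' @export
roc_points <- function(t_absent, t_present) {
  if (length(t_absent) == 0 || length(t_present) == 0) {
    stop_taskmo("both classes must be non-empty")
  }
  thr <- sort(unique(c(t_absent, t_present)), decreasing = TRUE)
  fpr <- vapply(thr, function(th) mean(t_absent >= th), numeric(1))
  tpr <- vapply(thr, function(th) mean(t_present >= th), numeric(1))
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(fpr = 1, tpr = 1))
  }
  out
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Hanley-McNeil standard error of an AUC estimate
#'
#' Classic binormal-free approximation to the sampling SD of the
#' Mann-Whitney AUC, used for binomial-type confidence bands around an
#' analytic AUC.
#'
#' @param auc the AUC.
#' @param n0,n1 class sample sizes.
#' @return standard error.
#' @export
auc_se_hanley <- function(auc, n0, n1) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
         (n0 * n1))
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval from resampling each class independently with
#' replacement; reproducible for a fixed seed.
#'
#' @param t_absent,t_present test statistics (>= 10 per class).
#' @param level confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return named numeric `c(low, high)`.
#' @export
auc_confidence_interval <- function(t_absent, t_present, level = 0.95,
                                    n_boot = 1000, seed = 1) {
  if (length(t_absent) < 10 || length(t_present) < 10) {
    stop_taskmo("at least 10 samples per class are required for a bootstrap CI")
  }
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mann_whitney_auc(
        sample(t_absent, replace = TRUE),
        sample(t_present, replace = TRUE)
      )
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- quantile(aucs, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Evaluate scores against labels into an ROC summary
#'
#' @param scores test statistics.
#' @param labels 0/1 labels.
#' @param ci compute a bootstrap confidence interval.
#' @param seed bootstrap seed.
#' @return an `roc_result` list: `auc`, `roc`, `n_absent`, `n_present`,
#'   optional `ci`.
#' @export
evaluate_scores <- function(scores, labels, ci = FALSE, seed = 1) {
  t0 <- scores[labels == 0]
  t1 <- scores[labels == 1]
  out <- list(
    auc = mann_whitney_auc(t0, t1),
    roc = roc_points(t0, t1),
    n_absent = length(t0), n_present = length(t1)
  )
  if (ci) out$ci <- auc_confidence_interval(t0, t1, seed = seed)
  structure(out, class = "roc_result")
}

#' Class-stratified train/validation/test split
#'
#' Partitions a dataset into three disjoint class-balanced subsets. Sizes are
#' image counts; the defaults give validation and test sets of 200 image
#' pairs each and assign the rest to training.
#'
#' @param ds a `detection_dataset`.
#' @param sizes named vector/list with `train`, `val`, `test` image counts
#'   (each must be even to balance classes; `train = NA` takes the
#'   remainder).
#' @param seed split seed.
#' @return list of three `detection_dataset`s (`train`, `val`, `test`), each
#'   carrying its index set as attribute `split_indices`.
#' @export
train_val_test_split <- function(ds, sizes = c(train = NA, val = 400, test = 400),
                                 seed = 1) {
  n <- ncol(ds$images)
  sz <- as.list(sizes)
  fixed <- sum(unlist(sz[c("val", "test")]))
  if (is.na(sz$train)) sz$train <- n - fixed
  tot <- sz$train + sz$val + sz$test
  if (tot > n) {
    stop_taskmo(sprintf("requested %d images but the dataset has only %d", tot, n))
  }
  per_class <- lapply(sz, function(s) {
    if (s %% 2 != 0) stop_taskmo("split sizes must be even for class balance")
    s / 2
  })
  i0 <- which(ds$labels == 0)
  i1 <- which(ds$labels == 1)
  parent_id <- paste0("split-", ds$provenance$seed %||% 0, "-", n)
  with_seed(derive_seed(seed, "split"), {
    i0 <- sample(i0)
    i1 <- sample(i1)
    take <- function(k0) {
      idx <- c(i0[seq_len(k0)], i1[seq_len(k0)])
      i0 <<- i0[-seq_len(k0)]
      i1 <<- i1[-seq_len(k0)]
      sort(idx)
    }
    idx_tr <- take(per_class$train)
    idx_va <- take(per_class$val)
    idx_te <- take(per_class$test)
    out <- list(
      train = dataset_subset(ds, idx_tr),
      val = dataset_subset(ds, idx_va),
      test = dataset_subset(ds, idx_te)
    )
    for (nm in names(out)) {
      attr(out[[nm]], "split_indices") <- switch(nm, train = idx_tr,
                                                 val = idx_va, test = idx_te)
      attr(out[[nm]], "split_parent") <- parent_id
    }
    out
  })
}

#' Learning-curve experiment over observers and training-set sizes
#'
#' For each observer, training size and repeat, a fresh training subset is
#' drawn (validation and test sets stay fixed and are never used for
#' training), the observer is fitted, and its AUC on the shared test set is
#' recorded together with the fitting time (logged, never asserted). The
#' Hotelling reference is computed once (known covariance when available,
#' otherwise from a fixed training set) and reported as a constant line.
#'
#' @param task a task definition from [detection_task()].
#' @param observers character vector of observer names; see [fit_any_observer()]
#'   for the registry (`"ho_sample"`, `"cnn"`, `"slnn"`, `"cdae_svm"`,
#'   `"pca_svm"`).
#' @param sizes training-set sizes in images.
#' @param repeats repeats per size with fresh data and seeds.
#' @param seed master seed.
#' @param n_val,n_test validation/test images.
#' @param observer_args named list of per-observer argument lists.
#' @return a `learning_curve`: list with `results` (tidy data frame:
#'   observer, size, rep, auc, fit_seconds, seed) and `ho_reference`.
#' @export
learning_curve_experiment <- function(task, observers = c("cdae_svm", "cnn"),
                                      sizes = c(100, 200, 500, 1000, 2500, 5000),
                                      repeats = 5, seed = 1,
                                      n_val = 400, n_test = 400,
                                      observer_args = list()) {
  if (any(diff(sizes) <= 0)) stop_taskmo("sizes must be strictly increasing")
  test_ds <- make_task_dataset(task, n_test / 2, derive_seed(seed, "lc-test"))
  val_ds <- make_task_dataset(task, n_val / 2, derive_seed(seed, "lc-val"))
  ho_ref <- ho_reference_auc(task, test_ds)
  results <- data.frame()
  for (obs_name in observers) {
    for (sz in sizes) {
      for (r in seq_len(repeats)) {
        sseed <- derive_seed(seed, sprintf("lc-%s-%d-%d", obs_name, sz, r))
        train_ds <- make_task_dataset(task, sz / 2, sseed)
        t0 <- proc.time()[["elapsed"]]
        auc <- tryCatch({
          fit <- fit_any_observer(obs_name, train_ds, val_ds, seed = sseed,
                                  args = observer_args[[obs_name]] %||% list())
          sc <- fit$score(test_ds)
          mann_whitney_auc(sc[test_ds$labels == 0], sc[test_ds$labels == 1])
        }, error = function(e) {
          warning(sprintf("observer %s failed at size %d rep %d: %s",
                          obs_name, sz, r, conditionMessage(e)))
          NA_real_
        })
        results <- rbind(results, data.frame(
          observer = obs_name, size = sz, rep = r, auc = auc,
          fit_seconds = proc.time()[["elapsed"]] - t0, seed = sseed
        ))
      }
    }
  }
  structure(
    list(results = results, ho_reference = ho_ref, sizes = sizes,
         repeats = repeats, seed = seed),
    class = "learning_curve"
  )
}
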