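## RBF-kernel SVM classification stage. The kernel convention is
## k(x, y) = exp(-||x - y||^2 / (2 sigma^2)), i.e. libsvm gamma = 1/(2 sigma^2),
## so reported kernel widths are directly interpretable length scales.

sigma_to_gamma <- function(sigma) 1 / (2 * sigma^2)

## Fit an RBF SVM and return a scorer oriented so larger decision values
## favor class 1.
fit_rbf_svm <- function(features, labels, C, sigma) {
  fit <- e1071::svm(
    x = features, y = factor(labels, levels = c(0, 1)),
    kernel = "radial", gamma = sigma_to_gamma(sigma), cost = C, scale = FALSE
  )
  pr <- predict(fit, features, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  flip <- if (colnames(dv)[1] == "0/1") -1 else 1
  list(fit = fit, flip = flip)
}

svm_decision_values <- function(model, features) {
  pr <- predict(model$fit, features, decision.values = TRUE)
  model$flip * as.numeric(attr(pr, "decision.values"))
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Grid search for RBF-SVM hyperparameters by stratified cross-validated AUC
#'
#' Evaluates every (C, sigma) pair by stratified k-fold cross-validation
#' scored with the AUC of the decision values, selects the best pair
#' (ties broken toward the smallest C, then the smallest sigma: small C
#' costs fewer support vectors) and refits it on all data.
#'
#' @param features `n x d` feature matrix.
#' @param labels 0/1 labels (both classes required).
#' @param C_grid,sigma_grid candidate penalty parameters and kernel widths.
#' @param seed seed for the fold assignment.
#' @param cv_folds number of folds (default 5).
#' @return list with `model` (refit on all data; use
#'   [svm_scores()]), `config` (list `C`, `sigma`), and `cv_table` (mean CV
#'   AUC per grid point).
#' @export
svm_grid_search <- function(features, labels,
                            C_grid = 10^seq(-1, 7, by = 1),
                            sigma_grid = 10^seq(-2, 2, by = 1),
                            seed = 1, cv_folds = 5) {
  features <- as.matrix(features)
  if (length(unique(labels)) < 2) {
    stop_taskmo("both classes must be present for SVM fitting")
  }
  if (length(C_grid) == 0 || length(sigma_grid) == 0) {
    stop_taskmo("hyperparameter grids must be non-empty")
  }
  folds <- stratified_folds(labels, cv_folds, derive_seed(seed, "svm-folds"))
  grid <- expand.grid(C = sort(C_grid), sigma = sort(sigma_grid))
  grid <- grid[order(grid$C, grid$sigma), ]
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      te <- !tr
      if (length(unique(labels[te])) < 2) return(NA_real_)
      m <- fit_rbf_svm(features[tr, , drop = FALSE], labels[tr],
                       grid$C[g], grid$sigma[g])
      sc <- svm_decision_values(m, features[te, , drop = FALSE])
      mann_whitney_auc(sc[labels[te] == 0], sc[labels[te] == 1])
    }, numeric(1))
    cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc) # first max: smallest C, then smallest sigma
  model <- fit_rbf_svm(features, labels, grid$C[best], grid$sigma[best])
  list(
    model = model,
    config = list(C = grid$C[best], sigma = grid$sigma[best],
                  cv_auc = cv_auc[best], cv_folds = cv_folds),
    cv_table = cbind(grid, cv_auc = cv_auc)
  )
}

#' Decision values of a fitted SVM model
#'
#' @param model the `model` element returned by [svm_grid_search()].
#' @param features `n x d` feature matrix.
#' @return numeric decision values; larger favors class 1.
#' @export
svm_scores <- function(model, features) {
  svm_decision_values(model, as.matrix(features))
}

#' Fit the self-supervised model observer (CDAE features + RBF SVM)
#'
#' The two-stage observer: (1) self-supervised pretext training of a
#' convolutional denoising autoencoder on the training images with labels
#' never consumed; (2) latent features are standardized per dimension and an
#' RBF-kernel SVM is selected by cross-validated grid search on the labeled
#' training features. PCA features can be substituted for the encoder to
#' obtain the linear baseline observer.
#'
#' @param train_ds labeled training `detection_dataset` (the CDAE stage uses
#'   only its images).
#' @param val_ds held-out dataset for CDAE early stopping.
#' @param config a [cdae_config()].
#' @param train_cfg a [cdae_train_config()].
#' @param C_grid,sigma_grid SVM hyperparameter grids.
#' @param seed master seed.
#' @param features `"cdae"` or `"pca"` (PCA baseline with `latent_units`
#'   components).
#' @param svm_select_n if not `NULL`, hyperparameter selection runs on a
#'   class-stratified subset of this many training images (the final model is
#'   always refit on all training data). Mirrors protocols that tune the
#'   classifier on a separate, smaller labeled set.
#' @return an `ssl_observer`.
#' @export
fit_ssl_observer <- function(train_ds, val_ds, config = cdae_config(),
                             train_cfg = cdae_train_config(),
                             C_grid = 10^seq(-1, 7, by = 1),
                             sigma_grid = 10^seq(-2, 2, by = 1),
                             seed = 1, features = c("cdae", "pca"),
                             svm_select_n = NULL) {
  features <- match.arg(features)
  assert_disjoint(train_ds, val_ds, c("training", "validation"))
  extractor <- if (features == "cdae") {
    model <- build_cdae(train_ds$grid, config, seed = derive_seed(seed, "ssl-cdae"))
    tc <- train_cfg
    tc$seed <- derive_seed(seed, "ssl-train")
    train_cdae(model, train_ds$images, val_ds$images, tc)
  } else {
    fit_pca(train_ds$images, k = config$latent_units)
  }
  feats <- if (features == "cdae") {
    encode(extractor, train_ds$images)
  } else {
    predict(extractor, train_ds$images)
  }
  mu <- colMeans(feats)
  sig <- apply(feats, 2, sd)
  sig[sig < 1e-12] <- 1
  fz <- sweep(sweep(feats, 2, mu), 2, sig, "/")
  labels <- train_ds$labels
  sel <- seq_along(labels)
  if (!is.null(svm_select_n) && svm_select_n < length(labels)) {
    k <- floor(svm_select_n / 2)
    sel <- with_seed(derive_seed(seed, "svm-select"), {
      sort(c(sample(which(labels == 0), k), sample(which(labels == 1), k)))
    })
  }
  gs <- svm_grid_search(fz[sel, , drop = FALSE], labels[sel],
                        C_grid, sigma_grid,
                        seed = derive_seed(seed, "ssl-svm"))
  if (length(sel) < length(labels)) { # refit the selected pair on all data
    gs$model <- fit_rbf_svm(fz, labels, gs$config$C, gs$config$sigma)
  }
  structure(
    list(
      feature_kind = features, extractor = extractor, svm = gs$model,
      svm_config = gs$config, cv_table = gs$cv_table,
      standardize = list(mean = mu, sd = sig),
      provenance = list(config = config, seed = seed,
                        n_train = ncol(train_ds$images))
    ),
    class = "ssl_observer"
  )
}

#' Score images with a fitted self-supervised observer
#'
#' Encodes images, applies the stored standardization, and returns the SVM
#' decision value, usable directly as an ROC test statistic.
#'
#' @param obs an `ssl_observer`.
#' @param images `M x n` matrix or `detection_dataset`.
#' @return numeric decision values (larger favors signal present).
#' @export
ssl_observer_score <- function(obs, images) {
  stopifnot(inherits(obs, "ssl_observer"))
  if (inherits(images, "detection_dataset")) images <- images$images
  feats <- if (obs$feature_kind == "cdae") {
    encode(obs$extractor, images)
  } else {
    predict(obs$extractor, images)
  }
  fz <- sweep(sweep(feats, 2, obs$standardize$mean), 2, obs$standardize$sd, "/")
  svm_scores(obs$svm, fz)
}
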