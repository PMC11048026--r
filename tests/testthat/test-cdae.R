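test_that("pixel corruption has the right marginal rate and edge cases", {
  x <- with_seed(1, matrix(runif(4096 * 4, 0.2, 0.9), 4096, 4))
  expect_identical(corrupt_inputs(x, 0, seed = 1), x)
  expect_equal(corrupt_inputs(x, 1, seed = 1), x * 0)
  xc <- corrupt_inputs(x, 0.2, seed = 2)
  frac <- mean(xc == 0)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / length(x)))
  expect_identical(corrupt_inputs(x, 0.2, seed = 2), xc)
  expect_error(corrupt_inputs(x, 1.2, seed = 1), "rate")
})

test_that("CDAE config enforces the architecture search bounds", {
  expect_error(cdae_config(depth = 9), "depth")
  expect_error(cdae_config(filters = 6), "filters")
  expect_error(cdae_config(latent_units = 40), "latent")
  expect_error(cdae_config(lambda = -0.1), "lambda")
  # the shipped default is the selected architecture
  cfg <- cdae_config()
  expect_equal(cfg$depth, 1L)
  expect_equal(cfg$filters, 16L)
  expect_equal(cfg$latent_units, 25L)
  expect_equal(cfg$lambda, 0.001)
})

test_that("encoder and decoder have the contracted shapes and ranges", {
  grid <- pixel_grid(12, 12, 1)
  model <- build_cdae(grid, cdae_config(2, 4, 7), seed = 1)
  x <- with_seed(2, matrix(runif(144 * 6), 144, 6))
  model$trained <- TRUE
  feats <- encode(model, x)
  expect_equal(dim(feats), c(6, 7))
  rec <- reconstruct(model, x)
  expect_equal(dim(rec), c(144, 6)) # spatial size preserved
  expect_true(all(rec > 0 & rec < 1)) # sigmoid-bounded output
  # identical inputs give identical features; zero image stays finite
  expect_identical(encode(model, x[, c(1, 1)])[1, ], encode(model, x[, c(1, 1)])[2, ])
  expect_true(all(is.finite(encode(model, matrix(0, 144, 1)))))
})

test_that("encoding requires a trained model and [0,1] inputs are enforced", {
  grid <- pixel_grid(8, 8, 1)
  model <- build_cdae(grid, cdae_config(1, 4, 3), seed = 1)
  x <- matrix(runif(64 * 4), 64, 4)
  expect_error(encode(model, x), "trained")
  expect_error(
    train_cdae(model, x * 3, x, cdae_train_config(max_epochs = 1)),
    "\\[0, 1\\]"
  )
})

test_that("pretext training reduces validation reconstruction loss on a toy", {
  grid <- pixel_grid(8, 8, 1)
  # rank-1 ensemble: scaled copies of one pattern
  base <- with_seed(3, runif(64, 0.1, 0.9))
  amp <- with_seed(4, runif(60, 0.5, 1))
  x <- outer(base, amp)
  model <- build_cdae(grid, cdae_config(1, 4, 3, corruption_rate = 0.1), seed = 2)
  model <- train_cdae(model, x[, 1:45], x[, 46:60],
                      cdae_train_config(max_epochs = 30, patience = 5, seed = 3))
  h <- model$history
  expect_gt(nrow(h), 2)
  expect_lt(min(h$val_loss), h$val_loss[1])
  # training never sees labels: the API has no label argument (signature check)
  expect_false("labels" %in% names(formals(train_cdae)))
})

test_that("training is deterministic for a fixed seed", {
  grid <- pixel_grid(8, 8, 1)
  x <- with_seed(5, matrix(runif(64 * 30), 64, 30))
  fit <- function() {
    m <- build_cdae(grid, cdae_config(1, 4, 3), seed = 9)
    m <- train_cdae(m, x[, 1:24], x[, 25:30],
                    cdae_train_config(max_epochs = 4, patience = Inf, seed = 9))
    m$history$val_loss
  }
  expect_identical(fit(), fit())
})

test_that("stronger weight decay yields smaller converged weight norms", {
  grid <- pixel_grid(8, 8, 1)
  x <- with_seed(6, matrix(runif(64 * 40, 0.1, 0.9), 64, 40))
  norms <- vapply(c(0, 1e-3, 1e-1), function(lam) {
    m <- build_cdae(grid, cdae_config(1, 4, 3, lambda = lam), seed = 4)
    m <- train_cdae(m, x[, 1:32], x[, 33:40],
                    cdae_train_config(max_epochs = 40, patience = Inf, seed = 4))
    taskmo:::weight_sq_norm(m$net)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("lambda = 0 objective equals the pure reconstruction loss", {
  grid <- pixel_grid(6, 6, 1)
  x <- with_seed(7, matrix(runif(36 * 10, 0.2, 0.8), 36, 10))
  m0 <- build_cdae(grid, cdae_config(1, 4, 2, corruption_rate = 0, lambda = 0), seed = 5)
  fw <- taskmo:::nn_forward(m0$net, x)
  lf <- taskmo:::bce_with_logits(fw$out, x)
  # with lambda 0 the penalty vanishes; with perfect binary reconstruction
  # the cross-entropy attains 0
  expect_equal(lf$loss + 0 * taskmo:::weight_sq_norm(m0$net), lf$loss)
  z <- matrix(c(-1e3, 1e3), 2, 1)[, 1, drop = FALSE] # logits -> probs 0 and 1
  expect_equal(taskmo:::bce_with_logits(z, c(0, 1))$loss, 0)
})

test_that("PCA components are orthonormal and capture degenerate structure", {
  # points on a 1-D line through the mean
  dir_ <- with_seed(8, rnorm(30))
  dir_ <- dir_ / sqrt(sum(dir_^2))
  x <- outer(dir_, seq(-2, 2, length.out = 25)) + 0.5
  p <- fit_pca(x, 2)
  expect_gt(p$sdev[1]^2 / sum(p$sdev^2), 0.999)
  G <- crossprod(p$components)
  expect_lt(max(abs(G - diag(2))), 1e-8)
  sc <- predict(p, x)
  expect_equal(dim(sc), c(25, 2))
  expect_error(fit_pca(x, 26), "exceeds")
})

test_that("Bayesian architecture search honors bounds, seeds and trivial spaces", {
  grid <- pixel_grid(8, 8, 1)
  x <- with_seed(9, matrix(runif(64 * 40, 0.1, 0.9), 64, 40))
  fast <- cdae_train_config(max_epochs = 2, patience = Inf, seed = 1)

  one <- cdae_bayesian_search(
    x, grid, trials = 1, seed = 2,
    depth_range = c(1, 1), filters_set = 4, latent_range = c(3, 3),
    train_cfg = fast
  )
  expect_equal(nrow(one$log), 1)
  expect_equal(one$best$depth, 1L)
  expect_equal(one$best$latent_units, 3L)

  res <- cdae_bayesian_search(
    x, grid, trials = 6, seed = 3,
    depth_range = c(1, 2), filters_set = c(4, 8), latent_range = c(2, 4),
    train_cfg = fast
  )
  expect_true(all(res$log$depth %in% 1:2))
  expect_true(all(res$log$filters %in% c(4, 8)))
  expect_true(all(res$log$latent_units %in% 2:4))
  res2 <- cdae_bayesian_search(
    x, grid, trials = 6, seed = 3,
    depth_range = c(1, 2), filters_set = c(4, 8), latent_range = c(2, 4),
    train_cfg = fast
  )
  expect_identical(res$log, res2$log) # seeded determinism
})

test_that("a 25-mode variance-ranked subspace cannot carry this task's information", {
  # Closed-form information ceiling for variance-driven bottleneck features:
  # rank Fourier modes by noise power (= PCA order for the stationary field)
  # and accumulate the ideal-observer SNR^2 restricted to the top 25. On the
  # default task this ceiling sits far below the full Hotelling AUC, which
  # is why a 25-latent-unit self-supervised observer cannot track the HO on
  # full-rank stationary Gaussian backgrounds.
  task <- default_ske_task()
  g <- task$grid
  S <- taskmo:::background_spectrum(g, task$background)
  st <- Mod(fft(ske_profile(g, task$signal)))^2
  snr2_full <- sum(st / S) / g$n_pixels
  auc_full <- pnorm(sqrt(snr2_full) / sqrt(2))
  ord <- order(as.vector(S), decreasing = TRUE)
  snr2_25 <- sum((as.vector(st)[ord] / as.vector(S)[ord])[1:25]) / g$n_pixels
  auc_25 <- pnorm(sqrt(snr2_25) / sqrt(2))
  expect_equal(auc_full, 0.90, tolerance = 1e-3) # calibrated operating point
  expect_lt(auc_25, 0.70)                        # bottleneck ceiling
  expect_lt(auc_25, auc_full - 0.05)
})
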