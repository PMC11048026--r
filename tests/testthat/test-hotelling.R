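test_that("class moments recover degenerate and known-covariance cases", {
  grid <- pixel_grid(4, 4, 1)
  # constant images per class: zero covariance, exact mean difference
  imgs <- cbind(matrix(0.2, 16, 3), matrix(0.7, 16, 3))
  ds <- list(images = imgs, labels = rep(c(0L, 1L), each = 3))
  m <- estimate_class_moments(ds)
  expect_equal(m$K0, matrix(0, 16, 16))
  expect_equal(m$K1, matrix(0, 16, 16))
  expect_equal(m$delta_mean, rep(0.5, 16))
  expect_equal(m$pooled, (m$K0 + m$K1) / 2)

  expect_error(
    estimate_class_moments(list(images = imgs, labels = rep(0L, 6))),
    "both classes"
  )
})

test_that("moments of white-noise images match sigma^2 I within 3 SE", {
  n <- 20000
  M <- 16
  imgs <- with_seed(8, matrix(rnorm(M * n, 0, 2), M, n))
  ds <- list(images = imgs, labels = rep(c(0L, 1L), n / 2))
  m <- estimate_class_moments(ds)
  se_diag <- 4 * sqrt(2 / (n / 2))
  se_off <- 4 * sqrt(1 / (n / 2))
  expect_lt(max(abs(diag(m$K0) - 4)), 3 * se_diag)
  expect_lt(max(abs(m$K0 - diag(diag(m$K0)))), 3.7 * se_off)
})

test_that("Hotelling template solves the pooled system", {
  # identity pooled covariance: w = delta
  mom <- structure(
    list(pooled = diag(2), delta_mean = c(0.3, -1)),
    class = "class_moments"
  )
  w <- ho_template(mom, ridge = 0)
  expect_equal(w$w, c(0.3, -1))

  # 2-pixel toy: K = diag(2, 1), delta = (1, 1) -> w = (0.5, 1)
  mom$pooled <- diag(c(2, 1))
  mom$delta_mean <- c(1, 1)
  expect_equal(ho_template(mom, ridge = 0)$w, c(0.5, 1))

  # known-covariance form
  w2 <- ho_template(list(K = diag(c(2, 1)), delta_mean = c(1, 1)))
  expect_equal(w2$w, c(0.5, 1))
  expect_equal(w2$source, "known-K-HO")

  # large ridge: direction approaches delta
  mom$pooled <- matrix(c(4, 1, 1, 2), 2)
  mom$delta_mean <- c(1, 2)
  wr <- ho_template(mom, ridge = 1e6)$w
  expect_equal(wr / sqrt(sum(wr^2)), c(1, 2) / sqrt(5), tolerance = 1e-4)

  # singular matrix at zero ridge errors with advice
  mom$pooled <- matrix(1, 2, 2)
  mom$delta_mean <- c(1, 0)
  expect_error(ho_template(mom, ridge = 0), "ridge")
})

test_that("linear observer application is linear and shape-checked", {
  w <- linear_observer(c(0, 1, 0, 0))
  imgs <- matrix(1:16, 4, 4)
  expect_equal(apply_linear_observer(w, imgs), c(2, 6, 10, 14))
  expect_equal(apply_linear_observer(w, 3 * imgs), 3 * c(2, 6, 10, 14))
  expect_error(apply_linear_observer(w, matrix(1, 5, 2)), "does not match")

  # paired noiseless insertion: t difference equals w' signal
  sig <- c(1, -2, 0.5, 3)
  bg <- matrix(rnorm(4 * 10), 4, 10)
  wr <- linear_observer(rnorm(4))
  d <- apply_linear_observer(wr, bg + sig) - apply_linear_observer(wr, bg)
  expect_equal(d, rep(sum(wr$w * sig), 10))
})

test_that("analytic detectability matches closed forms", {
  expect_equal(analytic_detectability(diag(4), rep(0, 4)),
               list(snr = 0, auc = 0.5))
  s <- c(2, 0, 0, 0) # ||s||^2 = 4, K = I -> SNR 2
  r <- analytic_detectability(diag(4), s)
  expect_equal(r$snr, 2)
  expect_equal(r$auc, pnorm(sqrt(2)))
  expect_equal(pnorm(sqrt(2)), 0.92135, tolerance = 1e-5)
  # homogeneity
  expect_equal(analytic_detectability(diag(4), 2 * s)$snr, 4)
  expect_error(analytic_detectability(matrix(c(1, 2, 2, 1), 2), c(1, 0)),
               "positive definite")
})

test_that("spectral and dense known-covariance observers agree", {
  task <- task16()
  sig <- ske_profile(task$grid, task$signal)
  sp <- ho_known_spectral(task$grid, task$background, sig)
  K <- analytic_background_covariance(task$grid, task$background)
  dense <- analytic_detectability(K, as.vector(sig))
  expect_equal(sp$snr, dense$snr, tolerance = 1e-10)
  w_dense <- solve(K, as.vector(sig))
  expect_equal(sp$observer$w, w_dense, tolerance = 1e-8)
})

test_that("adding a constant to all images leaves AUC unchanged", {
  task <- task16()
  ds <- make_task_dataset(task, 200, seed = 9)
  ho <- ho_known_spectral(task$grid, task$background,
                          ske_profile(task$grid, task$signal))
  t1 <- apply_linear_observer(ho$observer, ds$images)
  t2 <- apply_linear_observer(ho$observer, ds$images + 0.37)
  a1 <- mann_whitney_auc(t1[ds$labels == 0], t1[ds$labels == 1])
  a2 <- mann_whitney_auc(t2[ds$labels == 0], t2[ds$labels == 1])
  expect_equal(a1, a2)
})

test_that("sample HO converges toward the known-covariance HO", {
  task <- task8()
  test_ds <- make_task_dataset(task, 1000, seed = 10)
  known <- ho_reference_auc(task, test_ds)
  aucs <- vapply(c(100, 500, 2500), function(n_pairs) {
    tr <- make_task_dataset(task, n_pairs, seed = 11)
    obs <- ho_template(estimate_class_moments(tr))
    t_all <- apply_linear_observer(obs, test_ds)
    mann_whitney_auc(t_all[test_ds$labels == 0], t_all[test_ds$labels == 1])
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.02)) # nondecreasing within noise
  expect_lt(known$auc_empirical - aucs[3], 0.02)
})
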