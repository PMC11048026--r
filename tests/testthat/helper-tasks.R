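# Shared small tasks and fixtures, all generated in code.

# 16x16 correlated-Gaussian SKE task, mid-difficulty for the ideal linear
# observer (amplitude chosen so the analytic AUC is ~0.9 at the default
# noise level).
task16 <- function(amplitude = -10) {
  grid <- pixel_grid(16, 16, 0.7)
  detection_task(
    grid,
    background_spec("correlated-gaussian", mean_level = -850, noise_sd = 23.81),
    signal_spec_ske(amplitude = amplitude, radius = 4, z = 4),
    "SKE"
  )
}

# 8x8 task with a 2 mm nodule (fits the small grid).
task8 <- function(amplitude = -19) {
  grid <- pixel_grid(8, 8, 0.7)
  detection_task(
    grid,
    background_spec("correlated-gaussian", mean_level = -850, noise_sd = 23.81),
    signal_spec_ske(amplitude = amplitude, radius = 2, z = 4),
    "SKE"
  )
}

# Tiny separable two-class dataset of constant images (0.2 vs 0.8 plus a
# trace of noise), for classifier sanity checks.
toy_separable_dataset <- function(grid = pixel_grid(8, 8, 1), n_per_class = 20,
                                  seed = 7) {
  M <- grid$n_pixels
  imgs <- with_seed(seed, {
    cbind(
      matrix(0.2 + rnorm(M * n_per_class, 0, 0.01), M, n_per_class),
      matrix(0.8 + rnorm(M * n_per_class, 0, 0.01), M, n_per_class)
    )
  })
  imgs <- pmin(pmax(imgs, 0), 1)
  structure(
    list(
      images = imgs,
      labels = rep(c(0L, 1L), each = n_per_class),
      angles = rep(NA_real_, 2 * n_per_class),
      grid = grid,
      provenance = list(paradigm = "toy", seed = seed)
    ),
    class = "detection_dataset"
  )
}

# Brute-force AUC by pair counting (independent oracle for the estimator).
brute_force_auc <- function(t0, t1) {
  s <- 0
  for (a in t0) for (b in t1) s <- s + (b > a) + 0.5 * (b == a)
  s / (length(t0) * length(t1))
}
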