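#' Bundle a detection task definition
#'
#' A task is a grid, a stochastic background model, a signal specification
#' and a paradigm; together with a seed it fully determines every generated
#' dataset.
#'
#' @param grid a [pixel_grid()].
#' @param background a [background_spec()].
#' @param signal a signal spec matching `paradigm`.
#' @param paradigm `"SKE"` or `"SKS"`.
#' @return a `detection_task`.
#' @export
detection_task <- function(grid, background, signal, paradigm = c("SKE", "SKS")) {
  paradigm <- match.arg(paradigm)
  structure(list(grid = grid, background = background, signal = signal,
                 paradigm = paradigm),
            class = "detection_task")
}

## Noise SD (HU) of the default 64x64 correlated background, calibrated once
## so that the known-covariance Hotelling observer reaches AUC 0.90 on the
## default SKE nodule task (see the methods vignette).
default_noise_sd_ske <- 23.81

#' Default SKE nodule detection task
#'
#' 64 x 64 grid at 0.7 mm/pixel; correlated-Gaussian background with mean
#' -850 HU (lung parenchyma) and the default reconstruction-like spectrum; a
#' compact nodule signal of radius 4 mm, exponent 4 and additive contrast
#' -20 HU (a ground-glass-opacity-like attenuation of about -870 HU against
#' the parenchyma). The noise level is calibrated so the ideal linear
#' observer sits at AUC 0.90, a mid-difficulty task.
#'
#' @param noise_sd background noise SD in HU.
#' @param amplitude signal contrast in HU.
#' @return a `detection_task`.
#' @export
default_ske_task <- function(noise_sd = default_noise_sd_ske, amplitude = -20) {
  grid <- pixel_grid(64, 64, 0.7)
  detection_task(
    grid,
    background_spec("correlated-gaussian", mean_level = -850, noise_sd = noise_sd),
    signal_spec_ske(amplitude = amplitude, radius = 4, z = 4),
    "SKE"
  )
}

#' Default SKS rotated-ellipse detection task
#'
#' Same background as [default_ske_task()]; the signal is an anisotropic
#' Gaussian (sigma_x = 5, sigma_y = 1.5 pixels) whose orientation is drawn
#' uniformly from {0, 45, 90, 135} degrees per signal-present image.
#'
#' @param noise_sd background noise SD in HU.
#' @param amplitude signal contrast in HU.
#' @return a `detection_task`.
#' @export
default_sks_task <- function(noise_sd = default_noise_sd_ske, amplitude = -20) {
  grid <- pixel_grid(64, 64, 0.7)
  detection_task(
    grid,
    background_spec("correlated-gaussian", mean_level = -850, noise_sd = noise_sd),
    signal_spec_sks(amplitude = amplitude, sigma_x = 5, sigma_y = 1.5,
                    angle_set = c(0, 45, 90, 135)),
    "SKS"
  )
}

#' Generate a dataset from a task definition
#'
#' @param task a [detection_task()].
#' @param n_pairs background realizations (dataset has `2 * n_pairs` images).
#' @param seed master seed.
#' @return a `detection_dataset`.
#' @export
make_task_dataset <- function(task, n_pairs, seed) {
  build_detection_dataset(task$grid, task$background, task$signal,
                          n_pairs = n_pairs, paradigm = task$paradigm,
                          seed = seed)
}

## Mean signal image in HU (angle-averaged under SKS).
task_mean_signal <- function(task) {
  if (task$paradigm == "SKE") {
    ske_profile(task$grid, task$signal)
  } else {
    profs <- lapply(task$signal$angle_set,
                    function(a) sks_profile(task$grid, task$signal, a))
    Reduce(`+`, profs) / length(profs)
  }
}

#' Known-covariance Hotelling reference for a task
#'
#' Uses the closed-form background covariance (spectral form) and the mean
#' signal to build the known-covariance HO, reporting its empirical AUC on a
#' test set and, for SKE signals, the analytic AUC. For the lumpy background
#' (no closed form) the reference falls back to a sample HO estimated from a
#' fixed 2000-pair training set.
#'
#' @param task a [detection_task()].
#' @param test_ds test `detection_dataset`.
#' @param seed seed for the fallback fixed training set.
#' @return list with `auc_empirical`, `auc_analytic` (NA when not exact),
#'   `snr`, `observer`.
#' @export
ho_reference_auc <- function(task, test_ds, seed = 99991) {
  sig <- task_mean_signal(task)
  if (task$background$kind %in% c("white", "correlated-gaussian")) {
    ho <- ho_known_spectral(task$grid, task$background, sig)
    t_all <- apply_linear_observer(ho$observer, test_ds)
    list(
      auc_empirical = mann_whitney_auc(t_all[test_ds$labels == 0],
                                       t_all[test_ds$labels == 1]),
      auc_analytic = if (task$paradigm == "SKE") ho$auc else NA_real_,
      snr = ho$snr,
      observer = ho$observer
    )
  } else {
    train_ds <- make_task_dataset(task, 2000, derive_seed(seed, "ho-fixed"))
    mom <- estimate_class_moments(train_ds)
    obs <- ho_template(mom)
    t_all <- apply_linear_observer(obs, test_ds)
    list(
      auc_empirical = mann_whitney_auc(t_all[test_ds$labels == 0],
                                       t_all[test_ds$labels == 1]),
      auc_analytic = NA_real_, snr = NA_real_, observer = obs
    )
  }
}

#' Fit any registered observer by name
#'
#' Uniform front-end used by the learning-curve experiment and the command
#' line. Registered names:
#' `"ho_sample"` (regularized sample Hotelling), `"ho_known"`
#' (known-covariance Hotelling from the dataset's generating provenance),
#' `"cnn"`, `"slnn"` (supervised observers), `"cdae_svm"` (self-supervised
#' observer) and `"pca_svm"` (linear baseline).
#'
#' @param name observer name.
#' @param train_ds,val_ds training and validation datasets.
#' @param seed master seed for this fit.
#' @param args named list of overrides: `config` ([cnn_config()] or
#'   [cdae_config()]), `train` ([train_config()] or [cdae_train_config()]),
#'   `C_grid`, `sigma_grid`, `ridge`.
#' @return list with `fit` (the underlying object) and `score(ds)` returning
#'   test statistics.
#' @export
fit_any_observer <- function(name, train_ds, val_ds = NULL, seed = 1,
                             args = list()) {
  score_wrap <- function(fn, fit) {
    list(fit = fit, score = function(ds) {
      imgs <- if (inherits(ds, "detection_dataset")) ds$images else ds
      fn(imgs)
    })
  }
  switch(name,
    "ho_sample" = {
      mom <- estimate_class_moments(train_ds)
      obs <- ho_template(mom, ridge = args$ridge)
      score_wrap(function(x) apply_linear_observer(obs, x), obs)
    },
    "ho_known" = {
      pv <- train_ds$provenance
      task <- detection_task(train_ds$grid, pv$background, pv$signal, pv$paradigm)
      ho <- ho_known_spectral(train_ds$grid, pv$background, task_mean_signal(task))
      score_wrap(function(x) apply_linear_observer(ho$observer, x), ho)
    },
    "cnn" = ,
    "slnn" = {
      cfg <- args$train %||% train_config()
      cfg$seed <- seed
      obs <- build_supervised_observer(
        name, train_ds$grid,
        config = args$config %||% cnn_config(), seed = seed
      )
      obs <- train_supervised(obs, train_ds, val_ds, cfg)
      score_wrap(function(x) score_observer(obs, x), obs)
    },
    "cdae_svm" = ,
    "pca_svm" = {
      obs <- fit_ssl_observer(
        train_ds, val_ds,
        config = args$config %||% cdae_config(),
        train_cfg = args$train %||% cdae_train_config(),
        C_grid = args$C_grid %||% 10^seq(-1, 7, by = 1),
        sigma_grid = args$sigma_grid %||% 10^seq(-2, 2, by = 1),
        seed = seed,
        features = if (name == "cdae_svm") "cdae" else "pca",
        svm_select_n = args$svm_select_n
      )
      score_wrap(function(x) ssl_observer_score(obs, x), obs)
    },
    stop_taskmo("unknown observer name: ", name)
  )
}
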