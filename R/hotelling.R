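#' Per-class first and second moments of a detection dataset
#'
#' Computes unbiased sample means and covariances of the signal-absent and
#' signal-present classes, the inputs to the Hotelling template. Covariances
#' are explicitly symmetrized to remove floating-point asymmetry.
#'
#' @param ds a `detection_dataset` (or any list with `images` matrix columns
#'   and 0/1 `labels`) with at least 2 images per class.
#' @return a `class_moments` object: `mean0`, `mean1`, `K0`, `K1`, `n0`,
#'   `n1`, `delta_mean = mean1 - mean0` and `pooled = (K0 + K1) / 2`.
#' @export
estimate_class_moments <- function(ds) {
  i0 <- which(ds$labels == 0)
  i1 <- which(ds$labels == 1)
  if (length(i0) < 2 || length(i1) < 2) {
    stop_taskmo("both classes need at least 2 samples to estimate moments")
  }
  x0 <- t(ds$images[, i0, drop = FALSE])
  x1 <- t(ds$images[, i1, drop = FALSE])
  fast_cov <- function(x) { # unbiased sample covariance via BLAS
    xc <- sweep(x, 2, colMeans(x))
    crossprod(xc) / (nrow(x) - 1)
  }
  K0 <- fast_cov(x0)
  K1 <- fast_cov(x1)
  K0 <- (K0 + t(K0)) / 2
  K1 <- (K1 + t(K1)) / 2
  structure(
    list(
      mean0 = colMeans(x0), mean1 = colMeans(x1),
      K0 = K0, K1 = K1, n0 = length(i0), n1 = length(i1),
      delta_mean = colMeans(x1) - colMeans(x0),
      pooled = (K0 + K1) / 2
    ),
    class = "class_moments"
  )
}

#' Hotelling observer template
#'
#' The Hotelling observer is the ideal linear observer: its template is the
#' population Fisher discriminant `w = ((K0 + K1)/2 + ridge I)^-1 delta`,
#' where `K0`/`K1` are the class covariances and `delta` the class-mean
#' difference. A ridge stabilizes the inversion when the covariance is
#' estimated from fewer samples than pixels (an accurate unregularized
#' estimate needs on the order of ten times `M^2` samples).
#'
#' @param moments either a `class_moments` object (sample-estimated form) or
#'   a list with elements `K` (known `M x M` covariance) and `delta_mean`
#'   (known-covariance oracle form).
#' @param ridge non-negative ridge added as `ridge * I`; `NULL` uses the
#'   default `1e-3 * trace(K) / M` for sample moments and `0` for a known
#'   covariance.
#' @return a `linear_observer` with fields `w`, `source`, `ridge`.
#' @export
ho_template <- function(moments, ridge = NULL) {
  if (inherits(moments, "class_moments")) {
    K <- moments$pooled
    source <- "sample-HO"
    if (is.null(ridge)) ridge <- 1e-3 * sum(diag(K)) / nrow(K)
  } else {
    stopifnot(is.matrix(moments$K), !is.null(moments$delta_mean))
    K <- (moments$K + t(moments$K)) / 2
    source <- "known-K-HO"
    if (is.null(ridge)) ridge <- 0
  }
  if (ridge < 0) stop_taskmo("ridge must be >= 0")
  Kr <- K + diag(ridge, nrow(K))
  w <- tryCatch(
    solve(Kr, moments$delta_mean),
    error = function(e) {
      stop_taskmo(
        "pooled covariance is singular at ridge = ", format(ridge),
        "; increase the ridge or use a shrinkage estimate (", conditionMessage(e), ")"
      )
    }
  )
  linear_observer(as.numeric(w), source = source, ridge = ridge)
}

#' Construct a linear observer from an explicit template
#'
#' @param w template vector (length `M`).
#' @param source provenance tag, e.g. `"sample-HO"`, `"known-K-HO"`,
#'   `"other"`.
#' @param ridge ridge used in the inversion that produced `w`, if any.
#' @return a `linear_observer`.
#' @export
linear_observer <- function(w, source = "other", ridge = 0) {
  if (!all(is.finite(w))) stop_taskmo("observer template has non-finite entries")
  structure(list(w = as.numeric(w), source = source, ridge = ridge),
            class = "linear_observer")
}

#' Apply a linear observer to images
#'
#' Computes the scalar test statistic `t_i = w' f_i` for each image.
#'
#' @param obs a `linear_observer`.
#' @param images matrix `M x n` of vectorized images (or a
#'   `detection_dataset`).
#' @return numeric vector of `n` test statistics.
#' @export
apply_linear_observer <- function(obs, images) {
  stopifnot(inherits(obs, "linear_observer"))
  if (inherits(images, "detection_dataset")) images <- images$images
  if (is.vector(images)) images <- matrix(images, ncol = 1)
  if (nrow(images) != length(obs$w)) {
    stop_taskmo(sprintf(
      "image size (%d pixels) does not match template length (%d)",
      nrow(images), length(obs$w)
    ))
  }
  as.numeric(crossprod(obs$w, images))
}

#' Closed-form detectability of a known signal in known Gaussian noise
#'
#' For equal-covariance Gaussian classes differing by a known signal `s`, the
#' Hotelling test statistic achieves `SNR = sqrt(s' K^-1 s)` and
#' `AUC = Phi(SNR / sqrt(2))`. This is the exact oracle the empirical
#' observers are validated against.
#'
#' @param K positive-definite `M x M` covariance.
#' @param s signal vector of length `M`.
#' @return list with `snr` and `auc`.
#' @export
analytic_detectability <- function(K, s) {
  s <- as.numeric(s)
  stopifnot(is.matrix(K), nrow(K) == length(s))
  ch <- tryCatch(chol(K), error = function(e) {
    stop_taskmo("covariance must be positive definite: ", conditionMessage(e))
  })
  z <- backsolve(ch, s, transpose = TRUE)
  snr <- sqrt(sum(z^2))
  list(snr = snr, auc = pnorm(snr / sqrt(2)))
}

#' Known-covariance Hotelling observer for a synthetic task (spectral form)
#'
#' For the FFT-synthesized correlated-Gaussian (or white) background the
#' covariance is circulant, so the template `K^-1 s` is computed exactly in
#' the Fourier domain without forming the `M x M` matrix: the filter divides
#' the signal transform by the noise power spectrum. Returns the observer and
#' the analytic SNR/AUC for an SKE signal.
#'
#' @param grid a [pixel_grid()].
#' @param bg_spec a [background_spec()] of kind white or correlated-gaussian.
#' @param signal signal image (matrix) or vector in HU (for SKS, use the
#'   angle-averaged signal).
#' @return list with `observer` (a `linear_observer`), `snr`, `auc`.
#' @export
ho_known_spectral <- function(grid, bg_spec, signal) {
  S <- background_spectrum(grid, bg_spec)
  s_img <- matrix(as.numeric(signal), grid$n_rows, grid$n_cols)
  st <- fft(s_img)
  w <- Re(fft(st / S, inverse = TRUE)) / (grid$n_rows * grid$n_cols)
  snr2 <- sum(Mod(st)^2 / S) / (grid$n_rows * grid$n_cols)
  list(
    observer = linear_observer(as.vector(w), source = "known-K-HO"),
    snr = sqrt(snr2),
    auc = pnorm(sqrt(snr2) / sqrt(2))
  )
}
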