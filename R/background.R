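#' Stochastic background specification
#'
#' Backgrounds are stationary random fields standing in for anatomical CT
#' texture under a background-known-statistically (BKS) paradigm. Three kinds
#' are supported:
#'
#' * `"white"` — i.i.d. Gaussian pixel noise;
#' * `"correlated-gaussian"` — stationary Gaussian field synthesized by FFT
#'   spectral filtering of white noise, with a radially symmetric power
#'   spectrum `S(f) = f^alpha * exp(-(f/f_c)^2)` mixed with a white floor.
#'   Different `(alpha, f_c)` emulate the noise textures of different
#'   reconstruction regularizations: the default `alpha = 0` is a low-pass
#'   spectrum typical of regularized (iterative) low-dose reconstructions,
#'   while `alpha = 1` gives a ramp-like mid-frequency texture closer to
#'   filtered backprojection. The second-order statistics are known in
#'   closed form, enabling an exact ideal-linear-observer oracle;
#' * `"lumpy"` — Poisson-count Gaussian blobs added to white noise, a
#'   classic lumpy-background texture model (no closed-form covariance
#'   implemented).
#'
#' @param kind one of `"white"`, `"correlated-gaussian"`, `"lumpy"`.
#' @param mean_level background mean in HU.
#' @param noise_sd marginal pixel standard deviation in HU (>= 0).
#' @param spectrum_params list with `alpha` (spectral exponent), `f_c`
#'   (Gaussian roll-off in cycles/pixel) and `floor` (fraction of variance in
#'   a flat white component, keeping the spectrum positive at DC).
#' @param lump_params list with `mean_count`, `width` (pixels) and
#'   `magnitude` (HU) for the lumpy kind.
#' @return an object of class `background_spec`.
#' @export
background_spec <- function(kind = c("correlated-gaussian", "white", "lumpy"),
                            mean_level = -850, noise_sd = 60,
                            spectrum_params = list(alpha = 0, f_c = 0.3, floor = 0.1),
                            lump_params = list(mean_count = 20, width = 3, magnitude = 30)) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop_taskmo("noise_sd must be >= 0")
  sp <- modifyList(list(alpha = 0, f_c = 0.3, floor = 0.1), spectrum_params)
  if (sp$floor <= 0 || sp$floor > 1) stop_taskmo("spectrum floor must be in (0, 1]")
  structure(
    list(
      kind = kind, mean_level = mean_level, noise_sd = noise_sd,
      spectrum_params = sp, lump_params = lump_params
    ),
    class = "background_spec"
  )
}

## Per-frequency power spectrum array (n_rows x n_cols, unshifted FFT order)
## of the zero-mean noise component, scaled so that the marginal pixel
## variance equals noise_sd^2 (variance = mean over frequencies of S).
background_spectrum <- function(grid, spec) {
  if (!spec$kind %in% c("white", "correlated-gaussian")) {
    stop_taskmo("spectrum only defined for white and correlated-gaussian kinds")
  }
  nr <- grid$n_rows
  nc <- grid$n_cols
  if (spec$kind == "white") {
    return(matrix(spec$noise_sd^2, nr, nc))
  }
  fr <- ifelse(seq_len(nr) - 1 < nr / 2, seq_len(nr) - 1, seq_len(nr) - 1 - nr) / nr
  fc_ <- ifelse(seq_len(nc) - 1 < nc / 2, seq_len(nc) - 1, seq_len(nc) - 1 - nc) / nc
  f <- sqrt(outer(fr^2, fc_^2, `+`))
  p <- spec$spectrum_params
  shaped <- f^p$alpha * exp(-(f / p$f_c)^2)
  shaped[1, 1] <- 0
  shaped <- shaped / mean(shaped)
  S <- spec$noise_sd^2 * ((1 - p$floor) * shaped + p$floor)
  S
}

#' Sample stationary background realizations
#'
#' Draws `n` independent realizations of the background field. The
#' correlated-Gaussian kind filters white noise in the Fourier domain with
#' the square root of the target power spectrum, so realizations are
#' (circularly) stationary with second-order statistics known in closed form;
#' see [analytic_background_covariance()].
#'
#' @param grid a [pixel_grid()].
#' @param spec a [background_spec()].
#' @param n number of realizations (>= 1).
#' @param seed RNG seed; fixed seed gives bit-identical stacks.
#' @return numeric array `n_rows x n_cols x n` of intensities in HU.
#' @export
sample_backgrounds <- function(grid, spec, n, seed) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(spec, "background_spec"))
  if (n < 1) stop_taskmo("n must be >= 1")
  nr <- grid$n_rows
  nc <- grid$n_cols
  with_seed(seed, {
    out <- switch(spec$kind,
      "white" = array(rnorm(nr * nc * n, 0, spec$noise_sd), c(nr, nc, n)),
      "correlated-gaussian" = {
        H <- sqrt(background_spectrum(grid, spec))
        ## batched 2D FFT filtering: transform along rows for all images at
        ## once (mvfft), transpose, transform along columns, filter, invert
        fft2_batch <- function(x, inverse = FALSE) {
          # x: nr x (nc*n); 2D transform applied per nr x nc slice
          y <- stats::mvfft(x, inverse = inverse)           # along dim 1
          y <- array(y, c(nr, nc, n))
          y <- aperm(y, c(2, 1, 3))
          y <- stats::mvfft(matrix(y, nc, nr * n), inverse = inverse)
          aperm(array(y, c(nc, nr, n)), c(2, 1, 3))
        }
        w <- matrix(rnorm(nr * nc * n), nr, nc * n)
        wt <- fft2_batch(w)
        wt <- wt * as.vector(H) # recycles H over the n slices
        a <- Re(fft2_batch(matrix(wt, nr, nc * n), inverse = TRUE)) / (nr * nc)
        array(a, c(nr, nc, n))
      },
      "lumpy" = {
        lp <- spec$lump_params
        a <- array(rnorm(nr * nc * n, 0, spec$noise_sd), c(nr, nc, n))
        rows <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
        cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
        for (i in seq_len(n)) {
          k <- stats::rpois(1, lp$mean_count)
          if (k > 0) {
            cr <- runif(k, 0, nr - 1)
            cc <- runif(k, 0, nc - 1)
            for (j in seq_len(k)) {
              a[, , i] <- a[, , i] + lp$magnitude *
                exp(-((rows - cr[j])^2 + (cols - cc[j])^2) / (2 * lp$width^2))
            }
          }
        }
        a
      },
      stop_taskmo("unknown background kind: ", spec$kind)
    )
    out + spec$mean_level
  })
}

#' Closed-form covariance of a stationary background
#'
#' Returns the exact `M x M` pixel covariance of the zero-mean noise
#' component, derived from the generating power spectrum. For the
#' FFT-synthesized correlated-Gaussian field the covariance is circulant in
#' both dimensions (hence block-Toeplitz with Toeplitz blocks); for white
#' noise it is `noise_sd^2 * I`. This is the oracle input for the
#' known-covariance Hotelling observer.
#'
#' @param grid a [pixel_grid()].
#' @param spec a [background_spec()] of kind white or correlated-gaussian.
#' @return symmetric positive semi-definite `M x M` matrix (HU^2).
#' @export
analytic_background_covariance <- function(grid, spec) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(spec, "background_spec"))
  if (spec$kind == "lumpy") {
    stop_taskmo("no closed-form covariance for the lumpy background kind")
  }
  M <- grid$n_pixels
  if (spec$kind == "white") {
    return(diag(spec$noise_sd^2, M))
  }
  nr <- grid$n_rows
  nc <- grid$n_cols
  S <- background_spectrum(grid, spec)
  acov <- Re(fft(S, inverse = TRUE)) / (nr * nc) # autocovariance over wrapped lags
  xy <- grid_coords(grid)
  dr <- outer(xy[, 1], xy[, 1], `-`) %% nr
  dc <- outer(xy[, 2], xy[, 2], `-`) %% nc
  K <- matrix(acov[cbind(as.vector(dr) + 1L, as.vector(dc) + 1L)], M, M)
  (K + t(K)) / 2
}

#' Radially averaged empirical power spectrum of an image stack
#'
#' Averages per-image periodograms over realizations and bins them by radial
#' spatial frequency; used to validate that synthesized backgrounds carry
#' their target noise power spectrum.
#'
#' @param stack array `n_rows x n_cols x n` (the per-image mean over the
#'   stack is removed before the transform).
#' @param n_bins number of radial frequency bins.
#' @return data frame with `freq` (cycles/pixel, bin center) and `power`.
#' @export
radial_power_spectrum <- function(stack, n_bins = 16) {
  nr <- dim(stack)[1]
  nc <- dim(stack)[2]
  n <- dim(stack)[3]
  P <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    x <- stack[, , i]
    x <- x - mean(x)
    P <- P + Mod(fft(x))^2 / (nr * nc)
  }
  P <- P / n
  fr <- ifelse(seq_len(nr) - 1 < nr / 2, seq_len(nr) - 1, seq_len(nr) - 1 - nr) / nr
  fc_ <- ifelse(seq_len(nc) - 1 < nc / 2, seq_len(nc) - 1, seq_len(nc) - 1 - nc) / nc
  f <- sqrt(outer(fr^2, fc_^2, `+`))
  bins <- cut(as.vector(f), breaks = seq(0, 0.5, length.out = n_bins + 1),
              include.lowest = TRUE)
  data.frame(
    freq = tapply(as.vector(f), bins, mean),
    power = tapply(as.vector(P), bins, mean)
  )
}
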