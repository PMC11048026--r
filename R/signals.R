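#' Signal-known-exactly (SKE) nodule profile specification
#'
#' Rotationally symmetric nodule profile
#' `A_s * (1 - d^2 / R^2)^z` for `d <= R` and exactly 0 outside, where `d` is
#' the distance from the signal center. The amplitude is a CT contrast in
#' Hounsfield units added to the background; a ground-glass-opacity-like
#' nodule has an absolute attenuation near -870 HU, i.e. a contrast of about
#' -20 HU against a -850 HU lung parenchyma background.
#'
#' @param amplitude peak contrast `A_s` in HU.
#' @param radius signal radius `R` in mm.
#' @param z profile exponent (> 0); larger values concentrate the profile.
#' @param center signal center as (row, col) in 0-based pixel coordinates,
#'   or `NULL` for the grid center.
#' @return an object of class `signal_spec_ske`.
#' @export
signal_spec_ske <- function(amplitude = -20, radius = 4, z = 4, center = NULL) {
  if (radius <= 0) stop_taskmo("signal radius must be > 0")
  if (z <= 0) stop_taskmo("profile exponent z must be > 0")
  structure(
    list(amplitude = amplitude, radius = radius, z = z, center = center),
    class = c("signal_spec_ske", "signal_spec")
  )
}

#' Signal-known-statistically (SKS) elliptical profile specification
#'
#' Anisotropic Gaussian profile
#' `A_s * exp(-(R_phi (r - r_c))' D^-1 (R_phi (r - r_c)))` with
#' `D = diag(sigma_x^2, sigma_y^2)` and `R_phi` the rotation by angle `phi`.
#' The orientation is the statistically varying component: each
#' signal-present image draws `phi` uniformly from `angle_set`.
#'
#' @param amplitude peak contrast `A_s` in HU.
#' @param sigma_x,sigma_y profile widths along the two principal axes,
#'   in pixels (> 0).
#' @param angle_set candidate rotation angles in degrees.
#' @param center signal center as (row, col) 0-based pixels, `NULL` = grid
#'   center.
#' @return an object of class `signal_spec_sks`.
#' @export
signal_spec_sks <- function(amplitude = -20, sigma_x = 5, sigma_y = 1.5,
                            angle_set = c(0, 45, 90, 135), center = NULL) {
  if (sigma_x <= 0 || sigma_y <= 0) stop_taskmo("sigma_x and sigma_y must be > 0")
  if (length(angle_set) < 1) stop_taskmo("angle_set must be non-empty")
  structure(
    list(
      amplitude = amplitude, sigma_x = sigma_x, sigma_y = sigma_y,
      angle_set = as.numeric(angle_set), center = center
    ),
    class = c("signal_spec_sks", "signal_spec")
  )
}

#' Render the SKE nodule profile on a grid
#'
#' Evaluates the compact-support nodule profile at every pixel. The radius is
#' given in mm and converted through the grid's pixel spacing; the profile is
#' identically zero beyond the radius.
#'
#' @param grid a [pixel_grid()].
#' @param spec a [signal_spec_ske()].
#' @return numeric matrix (`n_rows` x `n_cols`) of signal contrast in HU.
#' @examples
#' img <- ske_profile(pixel_grid(), signal_spec_ske(amplitude = -870))
#' min(img) # -870 at the center pixel
#' @export
ske_profile <- function(grid, spec) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(spec, "signal_spec_ske"))
  r_px <- spec$radius / grid$pixel_spacing
  if (r_px < 1) {
    stop_taskmo(sprintf(
      "signal radius %.3g mm is below one pixel spacing (%.3g mm): unresolvable",
      spec$radius, grid$pixel_spacing
    ))
  }
  ctr <- spec$center %||% grid_center(grid)
  xy <- grid_coords(grid)
  d2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
  u <- 1 - d2 / r_px^2
  v <- ifelse(u > 0, spec$amplitude * u^spec$z, 0)
  matrix(v, grid$n_rows, grid$n_cols)
}

#' Render the SKS elliptical profile at a given orientation
#'
#' @param grid a [pixel_grid()].
#' @param spec a [signal_spec_sks()].
#' @param angle rotation angle in degrees; must belong to `spec$angle_set`.
#' @return numeric matrix of signal contrast in HU.
#' @export
sks_profile <- function(grid, spec, angle) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(spec, "signal_spec_sks"))
  if (!any(abs(spec$angle_set - angle) < 1e-9)) {
    stop_taskmo("angle must belong to the spec's angle_set")
  }
  ctr <- spec$center %||% grid_center(grid)
  xy <- grid_coords(grid)
  dx <- xy[, 1] - ctr[1]
  dy <- xy[, 2] - ctr[2]
  th <- angle * pi / 180
  ## rotate the offset into the ellipse frame
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  q <- u^2 / spec$sigma_x^2 + v^2 / spec$sigma_y^2
  matrix(spec$amplitude * exp(-q), grid$n_rows, grid$n_cols)
}

## Signal image for a spec; SKS requires an angle.
signal_image <- function(grid, spec, angle = NULL) {
  if (inherits(spec, "signal_spec_ske")) {
    ske_profile(grid, spec)
  } else {
    sks_profile(grid, spec, angle)
  }
}

## Support radius in pixels (SKE exact; SKS effective 3-sigma extent).
signal_extent_px <- function(grid, spec) {
  if (inherits(spec, "signal_spec_ske")) {
    spec$radius / grid$pixel_spacing
  } else {
    3 * max(spec$sigma_x, spec$sigma_y) # 3-sigma support: <1e-4 relative truncation
  }
}
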