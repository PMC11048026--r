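#' Pixel grid for a detection task
#'
#' Defines the image raster the task lives on: its size in pixels and the
#' physical pixel spacing, which converts signal extents given in millimetres
#' (e.g. a nodule radius) into pixels. The default 64 x 64 grid at
#' 0.7 mm/pixel corresponds to a typical chest-CT reconstruction
#' field-of-view; the number of image pixels `M = n_rows * n_cols` sets the
#' dimension of every image vector and covariance matrix downstream.
#'
#' @param n_rows,n_cols grid size in pixels.
#' @param pixel_spacing physical pixel spacing in mm/pixel (> 0).
#' @return an object of class `pixel_grid`.
#' @examples
#' g <- pixel_grid()
#' g$n_pixels
#' @export
pixel_grid <- function(n_rows = 64L, n_cols = 64L, pixel_spacing = 0.7) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (pixel_spacing <= 0) stop_taskmo("pixel_spacing must be > 0")
  structure(
    list(
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      pixel_spacing = pixel_spacing,
      n_pixels = as.integer(n_rows) * as.integer(n_cols)
    ),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf(
    "<pixel_grid> %d x %d pixels, %.3g mm/pixel\n",
    x$n_rows, x$n_cols, x$pixel_spacing
  ))
  invisible(x)
}

## 0-based pixel coordinates of every pixel, as a (M x 2) matrix of
## (row, col), in column-major order matching the image vectorization.
grid_coords <- function(grid) {
  r <- rep(seq_len(grid$n_rows) - 1L, times = grid$n_cols)
  c_ <- rep(seq_len(grid$n_cols) - 1L, each = grid$n_rows)
  cbind(row = r, col = c_)
}

## Geometric center of the grid in 0-based pixel coordinates.
grid_center <- function(grid) {
  c((grid$n_rows - 1) / 2, (grid$n_cols - 1) / 2)
}
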