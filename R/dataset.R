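#' Default HU display window mapped onto [0, 1]
#'
#' Images are stored on a normalized intensity scale: a fixed affine window
#' maps `[lo, hi]` HU onto `[0, 1]` with clipping. The window is recorded in
#' the dataset provenance so the map is invertible (up to clipping).
#' @export
default_hu_window <- c(lo = -1000, hi = 500)

hu_to_unit <- function(x, window) {
  pmin(pmax((x - window[["lo"]]) / (window[["hi"]] - window[["lo"]]), 0), 1)
}

unit_to_hu <- function(x, window) {
  x * (window[["hi"]] - window[["lo"]]) + window[["lo"]]
}

#' Assemble a labeled binary detection dataset
#'
#' Builds a paired signal-present/signal-absent ensemble: `n_pairs`
#' backgrounds are sampled, each appears once unaltered (label 0) and once
#' with the signal added in HU before normalization (label 1). Under the SKS
#' paradigm the orientation of each signal-present image is drawn uniformly
#' and independently from the spec's angle set and recorded per image.
#' Intensities are then mapped to `[0, 1]` through the affine HU window.
#'
#' @param grid a [pixel_grid()].
#' @param bg_spec a [background_spec()].
#' @param sig_spec a [signal_spec_ske()] or [signal_spec_sks()]; must match
#'   `paradigm`.
#' @param n_pairs number of background realizations (half the dataset size).
#' @param paradigm `"SKE"` or `"SKS"`.
#' @param seed master seed; background and angle streams are derived from it.
#' @param window affine normalization window in HU.
#' @return a `detection_dataset`: list with `images` (matrix `M x n`, columns
#'   are vectorized images in `[0,1]`), `labels` (0/1), `angles` (per-image
#'   SKS angle or `NA`), `grid`, and `provenance`.
#' @export
build_detection_dataset <- function(grid, bg_spec, sig_spec, n_pairs,
                                    paradigm = c("SKE", "SKS"), seed,
                                    window = default_hu_window) {
  paradigm <- match.arg(paradigm)
  if (n_pairs < 1) stop_taskmo("n_pairs must be >= 1")
  if (paradigm == "SKE" && !inherits(sig_spec, "signal_spec_ske")) {
    stop_taskmo("SKE paradigm requires a signal_spec_ske")
  }
  if (paradigm == "SKS" && !inherits(sig_spec, "signal_spec_sks")) {
    stop_taskmo("SKS paradigm requires a signal_spec_sks")
  }
  ctr <- sig_spec$center %||% grid_center(grid)
  ext <- signal_extent_px(grid, sig_spec)
  if (ctr[1] - ext < -0.5 || ctr[1] + ext > grid$n_rows - 0.5 ||
      ctr[2] - ext < -0.5 || ctr[2] + ext > grid$n_cols - 0.5) {
    stop_taskmo("signal support extends beyond the image grid")
  }

  bg <- sample_backgrounds(grid, bg_spec, n_pairs, derive_seed(seed, "backgrounds"))
  M <- grid$n_pixels

  if (paradigm == "SKE") {
    angles <- rep(NA_real_, n_pairs)
    sig_mat <- matrix(as.vector(ske_profile(grid, sig_spec)), M, n_pairs)
  } else {
    angles <- with_seed(
      derive_seed(seed, "angles"),
      sample(sig_spec$angle_set, n_pairs, replace = TRUE)
    )
    profiles <- vapply(
      sig_spec$angle_set,
      function(a) as.vector(sks_profile(grid, sig_spec, a)),
      numeric(M)
    )
    sig_mat <- profiles[, match(angles, sig_spec$angle_set), drop = FALSE]
  }

  bg_mat <- matrix(bg, M, n_pairs)
  images_hu <- cbind(bg_mat, bg_mat + sig_mat)
  labels <- rep(c(0L, 1L), each = n_pairs)
  structure(
    list(
      images = hu_to_unit(images_hu, window),
      labels = labels,
      angles = c(rep(NA_real_, n_pairs), angles),
      grid = grid,
      provenance = list(
        background = bg_spec, signal = sig_spec, paradigm = paradigm,
        n_pairs = as.integer(n_pairs), seed = as.integer(seed),
        window = window
      )
    ),
    class = "detection_dataset"
  )
}

#' @export
print.detection_dataset <- function(x, ...) {
  cat(sprintf(
    "<detection_dataset> %d images (%d x %d), %s paradigm, %d signal-present\n",
    ncol(x$images), x$grid$n_rows, x$grid$n_cols,
    x$provenance$paradigm, sum(x$labels == 1)
  ))
  invisible(x)
}

## Subset a dataset by image index, keeping provenance.
dataset_subset <- function(ds, idx) {
  out <- ds
  out$images <- ds$images[, idx, drop = FALSE]
  out$labels <- ds$labels[idx]
  out$angles <- ds$angles[idx]
  out$provenance$subset_of <- ncol(ds$images)
  out
}

#' Write a detection dataset to a single-file container
#'
#' Serializes the full dataset (images, labels, angles, grid, provenance) to
#' a single uncompressed RDS container so that a read-back is bit-identical,
#' and writes a human-readable JSON sidecar with the provenance next to it.
#'
#' @param ds a `detection_dataset`.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_detection_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "detection_dataset"))
  saveRDS(ds, path, compress = FALSE)
  meta <- ds$provenance
  meta$background <- unclass(meta$background)
  meta$signal <- unclass(meta$signal)
  meta$n_images <- ncol(ds$images)
  jsonlite::write_json(
    meta, paste0(tools::file_path_sans_ext(path), ".meta.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE
  )
  invisible(path)
}

#' Read a detection dataset written by [write_detection_dataset()]
#'
#' @param path container path.
#' @return the `detection_dataset`, validated for internal consistency.
#' @export
read_detection_dataset <- function(path) {
  if (!file.exists(path)) stop_taskmo("dataset file not found: ", path)
  ds <- tryCatch(readRDS(path), error = function(e) {
    stop_taskmo("corrupt dataset container '", path, "': ", conditionMessage(e))
  })
  if (!inherits(ds, "detection_dataset")) {
    stop_taskmo("file '", path, "' does not contain a detection_dataset")
  }
  n <- ncol(ds$images)
  if (length(ds$labels) != n || length(ds$angles) != n) {
    stop_taskmo(sprintf(
      "inconsistent dataset: %d images but %d labels / %d angle records",
      n, length(ds$labels), length(ds$angles)
    ))
  }
  if (nrow(ds$images) != ds$grid$n_pixels) {
    stop_taskmo("image size does not match the recorded pixel grid")
  }
  ds
}

#' Export dataset images as a multi-page TIFF stack
#'
#' Writes the normalized `[0,1]` images as a 32-bit float TIFF stack for
#' visual inspection in external viewers. This export is lossy in precision
#' (float32); the RDS container is the exact roundtrip format.
#'
#' @param ds a `detection_dataset`.
#' @param path output `.tif` path.
#' @param indices which images to export (default: all).
#' @return `path`, invisibly.
#' @export
export_tiff <- function(ds, path, indices = seq_len(ncol(ds$images))) {
  imgs <- lapply(indices, function(i) {
    matrix(ds$images[, i], ds$grid$n_rows, ds$grid$n_cols)
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}
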