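#' Hounsfield-unit window
#'
#' The attenuation window used to segment tissue on CT. The default,
#' -190..-30 HU, is the standard epicardial-fat display threshold.
#'
#' @param lo,hi Window bounds in HU, inclusive; `lo <= hi`.
#' @return An `hu_window` object.
#' @export
hu_window <- function(lo = -190, hi = -30) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    abort("hu_window requires finite bounds with lo <= hi.",
          class = "fathom_config_error")
  }
  structure(list(lo = lo, hi = hi), class = "hu_window")
}

#' @export
print.hu_window <- function(x, ...) {
  cat(sprintf("<hu_window> [%g, %g] HU\n", x$lo, x$hi))
  invisible(x)
}

validate_patch <- function(patch) {
  if (!is.matrix(patch) || !is.numeric(patch) || length(patch) == 0) {
    abort("a patch must be a nonempty numeric matrix.",
          class = "fathom_input_error")
  }
  if (!all(is.finite(patch))) {
    abort("patch values must all be finite.", class = "fathom_input_error")
  }
  invisible(patch)
}

#' Mask a patch by an HU window
#'
#' Flags every pixel whose attenuation lies inside the window, endpoints
#' inclusive. This is the fat-segmentation step: with the default window the
#' true pixels are the fat-attenuation pixels.
#'
#' @param patch A numeric HU matrix.
#' @param window An [hu_window()].
#' @return A logical matrix of the same shape.
#' @export
mask_hu <- function(patch, window = hu_window()) {
  validate_patch(patch)
  patch >= window$lo & patch <= window$hi
}

#' Tile patches into one large patch
#'
#' Row-major tiling: patch `k` (1-based) occupies tile row
#' `(k - 1) %/% grid_cols` and tile column `(k - 1) %% grid_cols`. Thirty-six
#' 32x32 patches with `grid_cols = 6` tile into one 192x192 patch.
#'
#' @param patches A list of equally shaped numeric matrices (or a cohort
#'   `values` list-column).
#' @param grid_cols Number of tiles per row; must divide `length(patches)`.
#' @return A single numeric matrix.
#' @export
concatenate_patches <- function(patches, grid_cols = 6L) {
  if (length(patches) == 0) {
    abort("no patches to concatenate.", class = "fathom_input_error")
  }
  purrr::walk(patches, validate_patch)
  dims <- vapply(patches, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all patches must share the same shape.", class = "fathom_input_error")
  }
  if (length(patches) %% grid_cols != 0) {
    abort("number of patches must be divisible by grid_cols.",
          class = "fathom_input_error")
  }
  n_tile_rows <- length(patches) %/% grid_cols
  do.call(rbind, lapply(seq_len(n_tile_rows), function(tr) {
    do.call(cbind, patches[(tr - 1L) * grid_cols + seq_len(grid_cols)])
  }))
}

#' Convert a binary mask to a planar point cloud
#'
#' One point per true pixel, at 0-based `(x, y) = (column, row)` pixel
#' coordinates. An empty mask yields an empty cloud.
#'
#' @param mask A logical matrix.
#' @return A tibble with columns `x` and `y`.
#' @export
points_from_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("mask must be a logical matrix.", class = "fathom_input_error")
  }
  idx <- which(mask, arr.ind = TRUE)
  tibble::tibble(x = as.numeric(idx[, "col"] - 1L),
                 y = as.numeric(idx[, "row"] - 1L))
}

#' Validate (and deduplicate) a point cloud
#'
#' @param points A data frame with numeric columns `x` and `y`.
#' @return A tibble with duplicate points removed (with a warning if any
#'   were present).
#' @export
as_point_cloud <- function(points) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    abort("a point cloud needs numeric columns x and y.",
          class = "fathom_input_error")
  }
  pts <- tibble::as_tibble(points)[, c("x", "y")]
  if (!all(vapply(pts, is.numeric, logical(1))) ||
      !all(is.finite(pts$x), is.finite(pts$y))) {
    abort("point coordinates must be finite numerics.",
          class = "fathom_input_error")
  }
  dedup <- dplyr::distinct(pts)
  if (nrow(dedup) < nrow(pts)) {
    warn(sprintf("dropped %d duplicate point(s).", nrow(pts) - nrow(dedup)))
  }
  dedup
}

# ---- plain-text I/O -------------------------------------------------------

#' Read / write HU patches as numeric CSV grids
#'
#' Grids are stored row-major, comma-separated, without a header.
#'
#' @param path File path.
#' @param patch A numeric matrix.
#' @return `read_patch_csv()` returns a numeric matrix.
#' @export
read_patch_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  validate_patch(m)
}

#' @rdname read_patch_csv
#' @export
write_patch_csv <- function(patch, path) {
  validate_patch(patch)
  utils::write.table(patch, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write HU patches as 16-bit TIFF
#'
#' The stored integer is `HU + offset` (default offset 1024, so the valid CT
#' range maps to 0..4095).
#'
#' @param path File path.
#' @param patch A numeric HU matrix.
#' @param offset Linear offset between stored integers and HU.
#' @return `read_patch_tiff()` returns a numeric HU matrix.
#' @export
read_patch_tiff <- function(path, offset = 1024) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O.",
          class = "fathom_config_error")
  }
  stored <- tiff::readTIFF(path, as.is = TRUE)
  validate_patch(stored - offset)
}

#' @rdname read_patch_tiff
#' @export
write_patch_tiff <- function(patch, path, offset = 1024) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O.",
          class = "fathom_config_error")
  }
  validate_patch(patch)
  stored <- patch + offset
  if (any(stored < 0 | stored > 65535)) {
    abort("patch values out of 16-bit range after offset.",
          class = "fathom_input_error")
  }
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as a 0/1 CSV grid, or a point cloud as x/y TSV
#'
#' @param mask A logical matrix.
#' @param points A point-cloud tibble.
#' @param path File path.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.table(mask * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
write_points_tsv <- function(points, path) {
  readr::write_tsv(points[, c("x", "y")], path, progress = FALSE)
  invisible(path)
}
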