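#' Voxel grids and region-of-interest masks
#'
#' A `voxel_grid` is a 3D scalar volume (PET in SUV units, MR in arbitrary
#' intensity, or a grey-level volume after normalisation) together with its
#' voxel spacing and physical origin. Voxel centres sit at
#' `origin + (k + 0.5) * spacing` for 0-based index `k`, with a half-open
#' extent convention, so shape arithmetic under resampling is unambiguous.
#'
#' @param values Numeric 3D array.
#' @param spacing_mm Numeric length-3 vector of per-axis voxel size in mm.
#' @param origin_mm Numeric length-3 vector of per-axis offsets in mm.
#' @return A `voxel_grid` object (list with `values`, `spacing_mm`,
#'   `origin_mm`).
#' @examples
#' g <- voxel_grid(array(rnorm(8), c(2, 2, 2)), spacing_mm = c(1, 1, 2))
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be three positive finite numbers.")
  }
  if (any(!is.finite(values))) {
    abort("volume values must all be finite.")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = as.double(origin_mm)),
    class = "voxel_grid"
  )
}

#' @param mask Logical/0-1 3D array marking lesion voxels.
#' @param require_nonempty Error if no voxel is set (lesion masks must be
#'   nonempty).
#' @rdname voxel_grid
#' @export
roi_mask <- function(mask, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                     require_nonempty = TRUE) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) abort("`mask` must be a 3D array.")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    abort("mask values must be binary (0/1).")
  }
  m <- array(as.logical(mask), dim(mask))
  if (require_nonempty && !any(m)) abort("mask is empty: lesion masks need at least one voxel.")
  structure(
    list(values = m, spacing_mm = as.double(spacing_mm), origin_mm = as.double(origin_mm)),
    class = c("roi_mask", "voxel_grid")
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<%s> %s voxels, spacing %s mm\n",
    class(x)[1L],
    paste(dim(x$values), collapse = " x "),
    paste(format(x$spacing_mm, trim = TRUE), collapse = " x ")
  ))
  invisible(x)
}

# Check that a mask is aligned (shape + spacing) with its paired volume.
check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values))) {
    abort("mask and volume shapes differ.")
  }
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > 1e-9) {
    abort("mask and volume voxel spacings differ.")
  }
  invisible(TRUE)
}

# Bounding box of a mask in voxel indices (1-based, inclusive), optionally
# dilated by `margin` voxels and clipped to the grid.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("mask is empty.")
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(mask$values))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_to_bbox <- function(grid, bbox) {
  v <- grid$values[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2], bbox$lo[3]:bbox$hi[3], drop = FALSE]
  out <- grid
  out$values <- v
  out$origin_mm <- grid$origin_mm + (bbox$lo - 1L) * grid$spacing_mm
  out
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti that preserve voxel spacing. Feature extraction is
#' mm-dependent, so a file without usable spacing metadata is an error.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as_mask Read as a binary `roi_mask` instead of a `voxel_grid`.
#' @return `read_volume()` returns a `voxel_grid` (or `roi_mask`);
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such volume file: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    abort(sprintf("failed to read NIfTI volume '%s': %s", path, conditionMessage(e)))
  })
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- abs(as.double(sp))
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)  # single-slice files come back 2D
  if (length(d) != 3L) abort(sprintf("volume '%s' is not 3D.", path))
  sp <- c(sp, rep(1, 3))[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    abort(sprintf("volume '%s' has no usable voxel spacing metadata.", path))
  }
  vals <- array(as.double(img), d)
  if (as_mask) {
    roi_mask(vals > 0.5, spacing_mm = sp)
  } else {
    voxel_grid(vals, spacing_mm = sp)
  }
}

#' @param volume A `voxel_grid` or `roi_mask`.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  vals <- volume$values
  if (inherits(volume, "roi_mask")) vals <- array(as.integer(vals), dim(vals))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param table A data frame; first column must be `subject_id`.
#' @rdname read_volume
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (names(table)[1L] != "subject_id") {
    abort("tables must carry `subject_id` as their first column.")
  }
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_table <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"))
}
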