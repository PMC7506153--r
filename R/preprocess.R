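#' Resample a volume to isotropic voxel spacing
#'
#' Trilinear (for images) or nearest-neighbour (for masks) resampling onto an
#' isotropic grid, the standard harmonisation step before texture extraction.
#' Output voxel centres are at `origin + (k + 0.5) * target` under the
#' half-open extent convention, and the output shape per axis is
#' `ceiling(extent / target)`. Coordinates outside the input centre lattice are
#' clamped (edge replication).
#'
#' @param volume A `voxel_grid` (or `roi_mask` with `mode = "nearest"`).
#' @param target_spacing_mm Target isotropic spacing (mm), default 1.
#' @param mode `"linear"` (trilinear) or `"nearest"`. Masks must use
#'   `"nearest"` so the binary alphabet is preserved.
#' @return A resampled `voxel_grid` (or `roi_mask`).
#' @examples
#' g <- voxel_grid(array(1:16, c(4, 2, 2)), spacing_mm = c(0.5, 0.5, 2))
#' dim(resample_isotropic(g)$values)
#' @export
resample_isotropic <- function(volume, target_spacing_mm = 1,
                               mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_spacing_mm) || length(target_spacing_mm) != 1L ||
      !is.finite(target_spacing_mm) || target_spacing_mm <= 0) {
    abort("`target_spacing_mm` must be a single positive number.")
  }
  is_mask <- inherits(volume, "roi_mask")
  if (is_mask && mode != "nearest") {
    abort("masks must be resampled with mode = \"nearest\".")
  }
  dims <- dim(volume$values)
  extent <- dims * volume$spacing_mm
  out_dims <- as.integer(ceiling(extent / target_spacing_mm - 1e-9))
  out_dims <- pmax(out_dims, 1L)

  arr <- volume$values
  if (is_mask) arr <- array(as.double(arr), dims)
  for (axis in 1:3) {
    # continuous 0-based input index of each output voxel centre along `axis`
    centres <- (seq_len(out_dims[axis]) - 0.5) * target_spacing_mm
    idx <- centres / volume$spacing_mm[axis] - 0.5
    idx <- pmin(pmax(idx, 0), dims[axis] - 1)
    arr <- interp_axis(arr, idx, axis, mode)
  }
  dims_done <- dim(arr)
  stopifnot(identical(as.integer(dims_done), out_dims))
  if (is_mask) {
    roi_mask(arr > 0.5, spacing_mm = rep(target_spacing_mm, 3),
             origin_mm = volume$origin_mm, require_nonempty = FALSE)
  } else {
    voxel_grid(arr, spacing_mm = rep(target_spacing_mm, 3),
               origin_mm = volume$origin_mm)
  }
}

# 1D interpolation along `axis` at continuous 0-based positions `idx`,
# applied separably (trilinear = three 1D passes).
interp_axis <- function(arr, idx, axis, mode) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  n <- dim(a)[1L]
  if (mode == "nearest") {
    take <- pmin(pmax(floor(idx + 0.5), 0), n - 1) + 1
    out <- a[take, , , drop = FALSE]
  } else {
    lo <- floor(idx)
    w <- idx - lo
    lo <- pmin(lo, n - 1)
    hi <- pmin(lo + 1, n - 1)
    # recycling along the first (fastest-varying) dimension
    out <- a[lo + 1, , , drop = FALSE] * (1 - w) + a[hi + 1, , , drop = FALSE] * w
  }
  if (axis == 1L) out else aperm(out, order(perm))
}

#' Normalise grey levels to the 0-255 range
#'
#' Linear min-max rescaling over the whole volume: the minimum maps to 0, the
#' maximum to 255, and intermediate values are converted linearly and rounded
#' half away from zero, `x' = round(255 * (x - min) / (max - min))`.
#' Normalisation statistics are taken over the full volume (not the ROI) so
#' that within-lesion minima stay informative.
#'
#' @param volume A `voxel_grid`.
#' @return A `voxel_grid` with integer values in `[0, 255]`. A constant input
#'   volume maps entirely to 0 with a warning (division guard).
#' @examples
#' g <- voxel_grid(array(c(100, 356, 612, 200), c(4, 1, 1)))
#' normalize_grey(g)$values[2]  # 128
#' @export
normalize_grey <- function(volume) {
  v <- volume$values
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warn("constant volume: grey normalisation maps every voxel to 0.")
    out <- array(0, dim(v))
  } else {
    out <- round_half_away(255 * (v - rng[1]) / (rng[2] - rng[1]))
  }
  voxel_grid(out, spacing_mm = volume$spacing_mm, origin_mm = volume$origin_mm)
}
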