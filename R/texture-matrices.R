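# Grey-level discretisation and the co-occurrence / run-length matrices that
# the texture feature families are computed from. Directions are the four
# in-plane (axial) angles of the 2D convention the feature names use
# (angle0/45/90/135); matrices are accumulated across slices.

glcm_directions <- c("angle0", "angle45", "angle90", "angle135")

# Per-slice step for matrix m[r, c]: angle0 walks along columns, angle90 along
# rows, angle45 along (+1,+1) diagonals, angle135 along (+1,-1) diagonals.
direction_step <- function(direction) {
  switch(direction,
    angle0   = c(0L, 1L),
    angle45  = c(1L, 1L),
    angle90  = c(1L, 0L),
    angle135 = c(1L, -1L),
    abort(sprintf("unknown direction '%s'", direction))
  )
}

#' Discretise a volume into grey levels within a mask
#'
#' Equal-width binning of the masked intensity range into `L` levels `0 ..
#' L-1` (a constant region maps entirely to level 0). Co-occurrence and
#' run-length matrices are computed on the discretised levels; emphasis
#' formulas index levels from 1 (`i = level + 1`).
#'
#' @param volume A `voxel_grid`.
#' @param mask An `roi_mask` aligned with `volume`.
#' @param L Number of grey levels (>= 2), default 32.
#' @return A `grey_volume`: list with `levels` (3D integer array, `NA` outside
#'   the mask), `L`, `spacing_mm`.
#' @export
discretize <- function(volume, mask, L = 32L) {
  check_aligned(volume, mask)
  L <- as.integer(L)
  if (L < 2) abort("`L` must be at least 2.")
  if (!any(mask$values)) abort("mask is empty.")
  v <- volume$values
  inmask <- mask$values
  mn <- min(v[inmask])
  mx <- max(v[inmask])
  lev <- array(NA_integer_, dim(v))
  if (mx == mn) {
    lev[inmask] <- 0L
  } else {
    width <- (mx - mn) / L
    lev[inmask] <- pmin(as.integer(floor((v[inmask] - mn) / width)), L - 1L)
  }
  grey_volume(lev, L = as.integer(L), spacing_mm = volume$spacing_mm)
}

#' @param levels 3D integer array of levels in `[0, L-1]`, `NA` outside the
#'   region of interest.
#' @param spacing_mm Voxel spacing.
#' @rdname discretize
#' @export
grey_volume <- function(levels, L, spacing_mm = c(1, 1, 1)) {
  levels <- as.array(levels)
  if (length(dim(levels)) == 2L) dim(levels) <- c(dim(levels), 1L)
  if (length(dim(levels)) != 3L) abort("`levels` must be a 2D or 3D array.")
  obs <- levels[!is.na(levels)]
  if (length(obs) == 0L) abort("grey volume has no in-mask voxels.")
  if (any(obs < 0) || any(obs >= L)) abort("all masked levels must lie in [0, L-1].")
  structure(list(levels = levels, L = as.integer(L), spacing_mm = as.double(spacing_mm)),
            class = "grey_volume")
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered in-mask voxel pairs separated by `offset_voxels` steps along
#' an in-plane direction, accumulated over axial slices, symmetrised (both
#' orderings) and normalised to pair probabilities.
#'
#' @param grey A `grey_volume` from [discretize()].
#' @param direction One of `"angle0"`, `"angle45"`, `"angle90"`, `"angle135"`.
#' @param offset_voxels Pair distance in voxels (the catalogue uses 1, 4, 7).
#' @return A `cooc_matrix`: list with `g` (L x L probability matrix),
#'   `n_pairs`, `direction`, `offset`. When the mask admits no pair at this
#'   direction/offset the matrix is flagged degenerate (`n_pairs = 0`) and
#'   downstream features come out `NA`.
#' @export
glcm <- function(grey, direction = "angle0", offset_voxels = 1L) {
  step <- direction_step(direction)
  o <- as.integer(offset_voxels)
  if (o < 1) abort("`offset_voxels` must be a positive integer.")
  L <- grey$L
  counts <- numeric(L * L)
  dims <- dim(grey$levels)
  for (k in seq_len(dims[3])) {
    m <- grey$levels[, , k]
    cnt <- slice_pair_counts(m, step, o, L)
    if (!is.null(cnt)) counts <- counts + cnt
  }
  cm <- matrix(counts, L, L)
  cm <- cm + t(cm)  # symmetrise: count both orderings
  total <- sum(cm)
  structure(list(
    g = if (total > 0) cm / total else NULL,
    n_pairs = total, direction = direction, offset = o, L = L
  ), class = "cooc_matrix")
}

# Ordered pair counts (flattened L*L) within one slice, or NULL.
slice_pair_counts <- function(m, step, o, L) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- step[1] * o; dc <- step[2] * o
  rows <- seq_len(nr - abs(dr)); if (dr < 0) rows <- rows + abs(dr)
  cols <- seq_len(nc - abs(dc)); if (dc < 0) cols <- cols + abs(dc)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  a <- m[rows, cols, drop = FALSE]
  b <- m[rows + dr, cols + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  tabulate(a[ok] * L + b[ok] + 1L, nbins = L * L)
}

#' Grey-level run-length matrix
#'
#' For every in-slice line along `direction`, sampled every `step` voxels from
#' the line start (the "step" of the catalogue names), maximal runs of equal
#' grey level within the mask are counted into `p(i, j)`: grey index `i =
#' level + 1`, run length `j`. Out-of-mask voxels break runs.
#'
#' @inheritParams glcm
#' @param step Scan-lattice stride along the direction (catalogue uses 1, 4, 7).
#' @return A `runlength_table`: list with `p` (L x Nmax count matrix),
#'   `n_runs`, `n_scanned` (in-mask lattice points scanned), `direction`,
#'   `step`.
#' @export
rlm <- function(grey, direction = "angle0", step = 1L) {
  s <- as.integer(step)
  if (s < 1) abort("`step` must be a positive integer.")
  dims <- dim(grey$levels)
  L <- grey$L
  run_lv <- integer(0)
  run_ln <- integer(0)
  n_scanned <- 0L
  for (k in seq_len(dims[3])) {
    m <- grey$levels[, , k, drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, dims[1], dims[2])
    lines <- slice_lines(m, direction)
    v <- unlist(lapply(lines, function(x) {
      c(x[seq(1L, length(x), by = s)], NA_integer_)
    }), use.names = FALSE)
    if (length(v) == 0L) next
    n_scanned <- n_scanned + sum(!is.na(v))
    r <- rle(v)
    keep <- !is.na(r$values)
    run_lv <- c(run_lv, r$values[keep])
    run_ln <- c(run_ln, r$lengths[keep])
  }
  if (length(run_lv) == 0L) abort("mask admits no run at this direction/step.")
  nmax <- max(run_ln)
  p <- matrix(0, L, nmax)
  idx <- cbind(run_lv + 1L, run_ln)
  for (q in seq_len(nrow(idx))) p[idx[q, 1L], idx[q, 2L]] <- p[idx[q, 1L], idx[q, 2L]] + 1
  structure(list(p = p, n_runs = length(run_lv), n_scanned = n_scanned,
                 direction = direction, step = s, L = L),
            class = "runlength_table")
}

# Decompose one slice into the scan lines of a direction. Each voxel belongs
# to exactly one line; lines are walked in a fixed orientation (runs are
# orientation-invariant).
slice_lines <- function(m, direction) {
  switch(direction,
    angle0   = lapply(seq_len(nrow(m)), function(r) m[r, ]),
    angle90  = lapply(seq_len(ncol(m)), function(c) m[, c]),
    angle45  = split(m, col(m) - row(m)),
    angle135 = split(m, col(m) + row(m)),
    abort(sprintf("unknown direction '%s'", direction))
  )
}
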