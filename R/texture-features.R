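# The 396-feature radiomics catalogue: histogram (42), shape (9), Haralick
# (7 x 3 offsets), GLCM (7 base x 3 offsets x 6 direction variants) and
# run-length (11 base x 3 steps x 6 variants) families.

glcm_base_names <- c(
  "GLCMEnergy", "GLCMEntropy", "GLCMContrast", "GLCMCorrelation",
  "GLCMInverseDifferenceMoment", "GLCMClusterShade", "GLCMClusterProminence"
)

rlm_base_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
  "RunLengthNonuniformity", "RunPercentage", "LowGreyLevelRunEmphasis",
  "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
  "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
  "LongRunHighGreyLevelEmphasis"
)

haralick_base_names <- c(
  "HaralickSumAverage", "HaralickSumEntropy", "HaralickDifferenceEntropy",
  "HaralickIMC1", "HaralickIMC2", "HaralickAutocorrelation",
  "HaralickDissimilarity"
)

histogram_feature_names <- c(
  "MinIntensity", "MaxIntensity", "Range", "Mean", "Median", "Mode",
  "StdDev", "Variance", "MeanAbsoluteDeviation", "MedianAbsoluteDeviation",
  "Skewness", "Kurtosis", "Energy", "RootMeanSquare", "Entropy", "Uniformity",
  "CoefficientOfVariation", "InterquartileRange", "QuartileDispersion",
  "Percentile1", "Percentile99", "Percentile1To99Range", "MeanTopDecile",
  paste0("Percentile", seq(5, 95, by = 5))
)

shape_feature_names <- c(
  "Volume", "SurfaceArea", "SurfaceToVolumeRatio", "Sphericity",
  "Compactness1", "Compactness2", "SphericalDisproportion",
  "Maximum3DDiameter", "Elongation"
)

variant_suffixes <- function(offset) {
  c(paste0(c("angle0", "angle45", "angle90", "angle135", "AllDirection"),
           "_offset", offset),
    paste0("AllDirection_offset", offset, "_SD"))
}

#' The 396-name radiomic feature catalogue
#'
#' Histogram (42) + shape (9) + Haralick (7 features at offsets 1, 4, 7) +
#' GLCM (7 base features x offsets 1/4/7 x 6 direction variants) + run-length
#' (11 base features x steps 1/4/7 x 6 variants) = 396 per modality. Names
#' follow the `Family_variant_offsetK[_SD]` convention, e.g.
#' `GLCMEntropy_angle0_offset4`.
#'
#' @param offsets Voxel offsets / scan steps, default `c(1, 4, 7)`.
#' @return A tibble with columns `name`, `family`.
#' @examples
#' nrow(feature_catalog())  # 396
#' @export
feature_catalog <- function(offsets = c(1L, 4L, 7L)) {
  haralick <- unlist(lapply(offsets, function(o) paste0(haralick_base_names, "_offset", o)))
  glcm_names <- unlist(lapply(offsets, function(o) {
    as.vector(t(outer(glcm_base_names, variant_suffixes(o), paste, sep = "_")))
  }))
  rlm_names <- unlist(lapply(offsets, function(o) {
    as.vector(t(outer(rlm_base_names, variant_suffixes(o), paste, sep = "_")))
  }))
  tibble(
    name = c(histogram_feature_names, shape_feature_names, haralick, glcm_names, rlm_names),
    family = c(rep("histogram", length(histogram_feature_names)),
               rep("shape", length(shape_feature_names)),
               rep("haralick", length(haralick)),
               rep("glcm", length(glcm_names)),
               rep("rlm", length(rlm_names)))
  )
}

#' Co-occurrence matrix features
#'
#' The seven GLCM base features computed from a pair-probability matrix `g`
#' with 1-based grey indices `i = level + 1`: energy `sum(g^2)`, entropy
#' `-sum(g log2 g)` (bits), contrast (inertia), correlation, inverse
#' difference moment, cluster shade and cluster prominence. A matrix with
#' zero marginal variance has correlation 1 by convention.
#'
#' @param m A `cooc_matrix` from [glcm()].
#' @return Named numeric vector of 7 values (all `NA` for a degenerate
#'   matrix with no pairs).
#' @export
glcm_feature_set <- function(m) {
  out <- setNames(rep(NA_real_, 7L), glcm_base_names)
  if (is.null(m$g) || m$n_pairs == 0) return(out)
  g <- m$g
  L <- nrow(g)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(g)
  mu_x <- sum(seq_len(L) * px)
  var_x <- sum((seq_len(L) - mu_x)^2 * px)
  out["GLCMEnergy"] <- sum(g^2)
  out["GLCMEntropy"] <- glcm_entropy(m)
  out["GLCMContrast"] <- sum(g * (i - j)^2)
  out["GLCMCorrelation"] <- if (var_x < 1e-15) {
    1  # zero marginal variance: perfectly concentrated matrix
  } else {
    (sum(i * j * g) - mu_x^2) / var_x  # symmetric g: mu_x = mu_y
  }
  out["GLCMInverseDifferenceMoment"] <- sum(g / (1 + (i - j)^2))
  out["GLCMClusterShade"] <- sum((i + j - 2 * mu_x)^3 * g)
  out["GLCMClusterProminence"] <- sum((i + j - 2 * mu_x)^4 * g)
  out
}

#' @rdname glcm_feature_set
#' @export
glcm_energy <- function(m) {
  if (is.null(m$g)) return(NA_real_)
  sum(m$g^2)
}

#' @rdname glcm_feature_set
#' @export
glcm_entropy <- function(m) {
  if (is.null(m$g)) return(NA_real_)
  p <- m$g[m$g > 0]
  h <- -sum(p * log2(p))
  if (h == 0) 0 else h  # avoid IEEE negative zero for a single-outcome matrix
}

#' Haralick features of a direction-averaged co-occurrence matrix
#'
#' Sum average, sum entropy, difference entropy, the two information measures
#' of correlation, autocorrelation and dissimilarity, computed on the mean of
#' the four directional pair-probability matrices at one offset. Entropies are
#' in bits.
#'
#' @param g An L x L pair-probability matrix (already direction-averaged).
#' @return Named numeric vector of 7 values.
#' @export
haralick_feature_set <- function(g) {
  out <- setNames(rep(NA_real_, 7L), haralick_base_names)
  if (is.null(g)) return(out)
  L <- nrow(g)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  p_sum <- tapply(as.vector(g), as.vector(i + j), sum)
  p_diff <- tapply(as.vector(g), as.vector(abs(i - j)), sum)
  px <- rowSums(g)
  py <- colSums(g)
  hxy <- ent(g)
  pxy <- outer(px, py)
  pos <- g > 0 & pxy > 0
  hxy1 <- -sum(g[pos] * log2(pxy[pos]))
  hxy2 <- ent(pxy)
  hx <- ent(px)
  hy <- ent(py)
  out["HaralickSumAverage"] <- sum(as.numeric(names(p_sum)) * p_sum)
  out["HaralickSumEntropy"] <- ent(p_sum)
  out["HaralickDifferenceEntropy"] <- ent(p_diff)
  out["HaralickIMC1"] <- if (max(hx, hy) < 1e-15) 0 else (hxy - hxy1) / max(hx, hy)
  out["HaralickIMC2"] <- sqrt(pmax(1 - exp(-2 * log(2) * (hxy2 - hxy)), 0))
  out["HaralickAutocorrelation"] <- sum(i * j * g)
  out["HaralickDissimilarity"] <- sum(abs(i - j) * g)
  out
}

#' Run-length matrix features
#'
#' The eleven run-emphasis statistics of a grey-level run-length table with
#' grey index `i = level + 1` (so low/high-grey emphasis divides/multiplies by
#' `i^2` without a zero index) and run length `j`: SRE, LRE, GLN, RLN, RP,
#' LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE.
#'
#' @param t A `runlength_table` from [rlm()].
#' @return Named numeric vector of 11 values.
#' @export
rlm_feature_set <- function(t) {
  p <- t$p
  nr <- t$n_runs
  L <- nrow(p)
  N <- ncol(p)
  i <- matrix(seq_len(L), L, N)
  j <- matrix(seq_len(N), L, N, byrow = TRUE)
  s <- function(w) sum(p * w) / nr
  c(
    ShortRunEmphasis = s(1 / j^2),
    LongRunEmphasis = s(j^2),
    GreyLevelNonuniformity = sum(rowSums(p)^2) / nr,
    RunLengthNonuniformity = sum(colSums(p)^2) / nr,
    RunPercentage = nr / t$n_scanned,
    LowGreyLevelRunEmphasis = s(1 / i^2),
    HighGreyLevelRunEmphasis = s(i^2),
    ShortRunLowGreyLevelEmphasis = s(1 / (i^2 * j^2)),
    ShortRunHighGreyLevelEmphasis = s(i^2 / j^2),
    LongRunLowGreyLevelEmphasis = s(j^2 / i^2),
    LongRunHighGreyLevelEmphasis = s(i^2 * j^2)
  )
}

# Aggregate per-direction feature values into the six catalogue variants:
# the four angles, their mean (AllDirection) and population SD. Degenerate
# directions (NA) are excluded from the mean/SD.
direction_variants <- function(per_direction) {
  vals <- as.numeric(per_direction)
  ok <- is.finite(vals)
  all_dir <- if (any(ok)) mean(vals[ok]) else NA_real_
  all_sd <- if (any(ok)) pop_sd(vals[ok]) else NA_real_
  c(vals, all_dir, all_sd)
}

#' First-order histogram features
#'
#' 42 statistics of the masked intensity distribution: location, dispersion,
#' moment, energy and entropy statistics plus the percentiles 5-95 in steps
#' of 5. Percentiles use the linear-interpolation convention
#' (`quantile(type = 7)`); histogram entropy/uniformity use 32 equal-width
#' bins over the masked range.
#'
#' @param volume A `voxel_grid` (normally grey-normalised 0-255).
#' @param mask An aligned `roi_mask`.
#' @return Named numeric vector of 42 values.
#' @export
histogram_features <- function(volume, mask) {
  check_aligned(volume, mask)
  x <- volume$values[mask$values]
  if (length(x) == 0L) abort("mask is empty.")
  n <- length(x)
  mu <- mean(x)
  if (n == 1L) inform("single-voxel mask: dispersion statistics reported as 0.")
  sdev <- if (n > 1L) sd(x) else 0
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 1e-24) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-24) mean((x - mu)^4) / m2^2 - 3 else 0
  qs <- quantile(x, c(0.01, 0.25, 0.5, 0.75, 0.9, 0.99, seq(0.05, 0.95, by = 0.05)),
                 names = FALSE, type = 7)
  p1 <- qs[1]; q25 <- qs[2]; med <- qs[3]; q75 <- qs[4]; p90 <- qs[5]; p99 <- qs[6]
  pct <- qs[-(1:6)]
  rng <- range(x)
  # 32 equal-width bins over the masked range (constant region: one bin)
  if (rng[2] > rng[1]) {
    b <- pmin(floor((x - rng[1]) / ((rng[2] - rng[1]) / 32)), 31)
    p <- tabulate(b + 1L, 32L) / n
  } else {
    p <- 1
  }
  p <- p[p > 0]
  tb <- table(x)
  mode_val <- as.numeric(names(tb)[which.max(tb)])  # ties: smallest value wins
  vals <- c(
    rng[1], rng[2], diff(rng), mu, med, mode_val,
    sdev, if (n > 1L) var(x) else 0, mean(abs(x - mu)), median(abs(x - med)),
    skew, kurt, sum(x^2), sqrt(mean(x^2)), -sum(p * log2(p)), sum(p^2),
    if (abs(mu) > 1e-24) sdev / mu else 0, q75 - q25,
    if (abs(q75 + q25) > 1e-24) (q75 - q25) / (q75 + q25) else 0,
    p1, p99, p99 - p1, mean(x[x >= p90]),
    pct
  )
  setNames(vals, histogram_feature_names)
}

#' Shape features of a lesion mask
#'
#' Mesh-free voxel-based shape descriptors: volume (voxel count x voxel
#' volume), surface area (exposed voxel faces), surface-to-volume ratio,
#' sphericity `pi^(1/3) (6V)^(2/3) / A`, compactness 1 and 2, spherical
#' disproportion, maximum 3D diameter (largest pairwise distance between
#' boundary voxel centres) and elongation (square root of the ratio of the
#' second to the first principal spatial moment).
#'
#' @param mask An `roi_mask`.
#' @return Named numeric vector of 9 values (lengths in mm, volume in mm^3).
#' @export
shape_features <- function(mask) {
  m <- mask$values
  sp <- mask$spacing_mm
  nvox <- sum(m)
  if (nvox == 0L) abort("mask is empty.")
  if (!mask_is_connected(mask)) {
    warn("mask is disconnected: shape computed on the union of components.")
  }
  V <- nvox * prod(sp)

  pad <- array(FALSE, dim(m) + 2L)
  pad[2:(dim(m)[1] + 1), 2:(dim(m)[2] + 1), 2:(dim(m)[3] + 1)] <- m
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  A <- 0
  exposed <- array(FALSE, dim(pad))
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- shift_array(pad, a, s)
      open_faces <- pad & !nb
      A <- A + sum(open_faces) * face_area[a]
      exposed <- exposed | open_faces
    }
  }
  idx <- which(exposed, arr.ind = TRUE) - 1L  # padded -> original 1-based
  bcoords <- sweep(idx - 0.5, 2, sp, `*`)
  max_diam <- if (nrow(bcoords) > 1L) max(stats::dist(bcoords)) else 0

  allidx <- which(m, arr.ind = TRUE)
  coords <- sweep(allidx - 0.5, 2, sp, `*`)
  elong <- if (nrow(coords) > 1L) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    if (ev[1] > 1e-12) sqrt(max(ev[2], 0) / ev[1]) else 0
  } else 0

  r_eq <- (3 * V / (4 * pi))^(1 / 3)
  c(
    Volume = V,
    SurfaceArea = A,
    SurfaceToVolumeRatio = A / V,
    Sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    Compactness1 = V / (sqrt(pi) * A^1.5),
    Compactness2 = 36 * pi * V^2 / A^3,
    SphericalDisproportion = A / (4 * pi * r_eq^2),
    Maximum3DDiameter = max_diam,
    Elongation = elong
  )
}

# shift a logical array by one voxel along an axis, padding with FALSE
shift_array <- function(a, axis, s) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (s > 0) {
    src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis]
  } else {
    src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the full 396-feature vector for one volume/mask pair
#'
#' Runs every feature family on a preprocessed (isotropic, grey-normalised)
#' volume: histogram and shape statistics on the continuous values and mask,
#' then GLCM, Haralick and run-length families on the `L`-level discretised
#' lesion. Family failures are recorded as `NA`, never dropped, so the output
#' always has the full catalogue length.
#'
#' @param volume Preprocessed `voxel_grid`.
#' @param mask Aligned `roi_mask` (the anatomical lesion mask).
#' @param levels Grey levels for the matrix families, default 32.
#' @param offsets Voxel offsets / scan steps, default `c(1, 4, 7)`.
#' @return Named numeric vector of 396 values in catalogue order.
#' @export
extract_all <- function(volume, mask, levels = 32L, offsets = c(1L, 4L, 7L)) {
  check_aligned(volume, mask)
  catalog <- feature_catalog(offsets)
  if (!any(mask$values)) abort("mask is empty.")

  bb <- mask_bbox(mask, margin = 1L)
  vol_c <- crop_to_bbox(volume, bb)
  mask_c <- crop_to_bbox(mask, bb)

  hist_f <- histogram_features(vol_c, mask_c)
  shape_f <- shape_features(mask)
  grey <- discretize(vol_c, mask_c, L = levels)

  glcm_vals <- numeric(0)
  haralick_vals <- numeric(0)
  for (o in offsets) {
    mats <- lapply(glcm_directions, function(d) glcm(grey, d, o))
    per_dir <- vapply(mats, glcm_feature_set, numeric(7L))
    block <- t(apply(per_dir, 1, direction_variants))
    glcm_vals <- c(glcm_vals, as.vector(t(block)))
    ok <- vapply(mats, function(m) !is.null(m$g), TRUE)
    gbar <- if (any(ok)) Reduce(`+`, lapply(mats[ok], `[[`, "g")) / sum(ok) else NULL
    haralick_vals <- c(haralick_vals, haralick_feature_set(gbar))
  }
  # Haralick block precedes GLCM in the catalogue: reorder offsets together
  haralick_vals <- as.numeric(haralick_vals)

  rlm_vals <- numeric(0)
  for (s in offsets) {
    per_dir <- vapply(glcm_directions, function(d) {
      tryCatch(rlm_feature_set(rlm(grey, d, s)),
               error = function(e) setNames(rep(NA_real_, 11L), rlm_base_names))
    }, numeric(11L))
    block <- t(apply(per_dir, 1, direction_variants))
    rlm_vals <- c(rlm_vals, as.vector(t(block)))
  }

  out <- c(hist_f, shape_f, haralick_vals, glcm_vals, rlm_vals)
  names(out) <- catalog$name
  out
}

mask_is_connected <- function(mask) {
  bb <- mask_bbox(mask)
  m <- crop_to_bbox(mask, bb)$values
  seed <- which(m)[1L]
  comp <- flood_fill26(m, seed)
  sum(comp) == sum(m)
}

# 26-connected component of `arr` containing linear index `seed`,
# grown by iterated one-voxel dilation.
flood_fill26 <- function(arr, seed) {
  comp <- array(FALSE, dim(arr))
  comp[seed] <- TRUE
  repeat {
    grown <- comp
    for (a in 1:3) {
      grown <- grown | shift_array(grown, a, 1L) | shift_array(grown, a, -1L)
    }
    grown <- grown & arr
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

#' Extract per-modality feature tables for a cohort
#'
#' Preprocesses every subject's volume (isotropic resampling when needed, then
#' 0-255 grey normalisation) and extracts the 396-feature vector per subject
#' and modality.
#'
#' @param cohort A `radstage_cohort` from [generate_cohort()].
#' @param modality `"pet"` or `"mr"`.
#' @inheritParams extract_all
#' @return A tibble: `subject_id` plus one column per catalogue feature.
#' @export
extract_cohort_features <- function(cohort, modality = c("pet", "mr"),
                                    levels = 32L, offsets = c(1L, 4L, 7L)) {
  modality <- match.arg(modality)
  rows <- purrr::map(cohort$subjects, function(s) {
    vol <- if (modality == "pet") s$pet_volume else s$mr_volume
    mask <- s$lesion_mask
    if (max(abs(vol$spacing_mm - 1)) > 1e-9) {
      vol <- resample_isotropic(vol, 1, "linear")
      mask <- resample_isotropic(mask, 1, "nearest")
    }
    vol <- suppressWarnings(normalize_grey(vol))
    fv <- extract_all(vol, mask, levels = levels, offsets = offsets)
    tibble::as_tibble_row(c(list(subject_id = s$subject_id), as.list(fv)))
  })
  dplyr::bind_rows(rows)
}
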