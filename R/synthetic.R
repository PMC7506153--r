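#' Phantom cohort specification
#'
#' Defines the study conditions emulated by the phantom generator: two stage
#' classes (early = TNM I-II, advanced = III-IV) whose lesion size, peak uptake
#' and texture heterogeneity differ by configurable effect sizes. Defaults
#' reproduce the cohort structure of the staging study this pipeline targets:
#' 100 subjects, a 70/30 train/test split, 27% early vs 73% advanced, and an
#' overall SUVmax scale near 10.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param train_fraction Training fraction for the stratified split (0-1).
#' @param class_prevalence Proportion of advanced (stage III-IV) cases.
#' @param grid_shape Voxels per axis.
#' @param voxel_spacing_mm Voxel size per axis (mm).
#' @param lesion_radius_mm Per-class mean/sd of the lesion radius (mm), a list
#'   with elements `early` and `advanced`, each `c(mean, sd)`.
#' @param lesion_suv_peak Per-class mean/sd of the lesion SUVmax.
#' @param heterogeneity_corr_len_mm Per-class correlation length (mm) of the
#'   lesion texture field; shorter = finer, more heterogeneous texture.
#' @param heterogeneity_sd Per-class relative amplitude of the texture field.
#' @param couple_heterogeneity If `TRUE` the per-subject texture amplitude
#'   scales with relative lesion volume, planting the positive texture-vs-TLG
#'   correlations the association stage is designed to recover.
#' @param background_suv Background SUV level.
#' @param noise_sd Gaussian noise sd added outside the lesion.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_subjects = 100,
                         train_fraction = 0.7,
                         class_prevalence = 0.73,
                         grid_shape = c(64, 64, 64),
                         voxel_spacing_mm = c(1, 1, 1),
                         lesion_radius_mm = list(early = c(10, 1.5), advanced = c(14, 2)),
                         lesion_suv_peak = list(early = c(9, 3), advanced = c(12, 4)),
                         heterogeneity_corr_len_mm = c(early = 6, advanced = 3),
                         heterogeneity_sd = c(early = 0.15, advanced = 0.30),
                         couple_heterogeneity = TRUE,
                         background_suv = 1,
                         noise_sd = 0.1,
                         seed = 1L) {
  if (n_subjects < 4) abort("need at least 4 subjects (two per class).")
  if (!(train_fraction > 0 && train_fraction < 1)) abort("train_fraction must be in (0, 1).")
  if (!(class_prevalence > 0 && class_prevalence < 1)) abort("class_prevalence must be in (0, 1).")
  if (any(unlist(heterogeneity_sd) < 0) || noise_sd < 0) abort("sds must be >= 0.")
  spec <- list(
    n_subjects = as.integer(n_subjects), train_fraction = train_fraction,
    class_prevalence = class_prevalence, grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.double(voxel_spacing_mm),
    lesion_radius_mm = lesion_radius_mm, lesion_suv_peak = lesion_suv_peak,
    heterogeneity_corr_len_mm = heterogeneity_corr_len_mm,
    heterogeneity_sd = heterogeneity_sd,
    couple_heterogeneity = isTRUE(couple_heterogeneity),
    background_suv = background_suv, noise_sd = noise_sd, seed = as.integer(seed)
  )
  # worst-case lesion (mean + 3 sd, +20% axis jitter) must fit inside the grid
  max_r <- max(vapply(lesion_radius_mm, function(p) p[1] + 3 * p[2], 0)) * 1.2
  half_extent <- min(spec$grid_shape * spec$voxel_spacing_mm) / 2
  if (max_r + 4 >= half_extent) {
    abort("lesion does not fit inside the grid: enlarge grid_shape or shrink radii.")
  }
  structure(spec, class = "phantom_spec")
}

#' Sample cosmetic clinical covariates
#'
#' Age ~ Normal(52, 12.5) truncated to [18, 90]; gender ~ Bernoulli(0.78 male).
#' These mimic the demographic scale of a head-and-neck cohort and carry no
#' class signal; they exist so the cohort-comparison statistics have realistic
#' inputs.
#'
#' @param n Number of subjects to draw.
#' @return A tibble with columns `age`, `gender`.
#' @export
sample_covariates <- function(n) {
  lo <- pnorm(18, 52, 12.5)
  hi <- pnorm(90, 52, 12.5)
  age <- qnorm(runif(n, lo, hi), 52, 12.5)
  gender <- ifelse(rbinom(n, 1, 0.78) == 1, "male", "female")
  tibble(age = age, gender = gender)
}

# Correlated Gaussian random field: white noise smoothed by a (periodic)
# Gaussian kernel of width = correlation length, then renormalised to unit sd.
gaussian_field <- function(dims, corr_len_vox) {
  white <- array(rnorm(prod(dims)), dims)
  if (all(corr_len_vox <= 1e-9)) return(white)
  kern1 <- lapply(seq_len(3), function(a) {
    n <- dims[a]
    d <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance
    k <- exp(-0.5 * (d / max(corr_len_vox[a], 1e-9))^2)
    k / sum(k)
  })
  kern <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  dim(kern) <- dims
  sm <- Re(fft(fft(white) * fft(kern), inverse = TRUE)) / prod(dims)
  s <- sd(as.vector(sm))
  if (s < 1e-12) return(array(0, dims))
  (sm - mean(sm)) / s
}

# Unit-variance correlated field winsorised at +-2 (bounded heterogeneity).
bounded_field <- function(dims, corr_len_vox) {
  pmin(pmax(gaussian_field(dims, corr_len_vox), -2), 2)
}

# One subject's paired PET/MR volumes and anatomical mask.
simulate_subject <- function(spec, stage_label, subject_id, mean_volume_by_class) {
  class <- if (stage_label == 1L) "advanced" else "early"
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing_mm

  rp <- spec$lesion_radius_mm[[class]]
  base_r <- max(rnorm(1, rp[1], rp[2]), 3)
  radii <- base_r * runif(3, 0.8, 1.2)  # axis-aligned ellipsoid, +-20% jitter
  centre_mm <- dims * sp / 2 + runif(3, -3, 3)

  cx <- lapply(1:3, function(a) ((seq_len(dims[a]) - 0.5) * sp[a] - centre_mm[a]) / radii[a])
  d2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, `+`), cx[[3]]^2, `+`)
  mask <- d2 <= 1

  # volume-heterogeneity coupling: bigger lesions get a stronger and finer
  # texture field (amplitude up, correlation length down), planting the
  # positive texture-vs-TLG association the correlation stage must recover
  vol_mm3 <- sum(mask) * prod(sp)
  rel_vol <- vol_mm3 / mean_volume_by_class[[class]]
  het_scale <- if (spec$couple_heterogeneity) rel_vol else 1
  len_scale <- if (spec$couple_heterogeneity) rel_vol^(-3 / 4) else 1
  het_sd <- spec$heterogeneity_sd[[class]] * het_scale
  corr_vox <- pmax(spec$heterogeneity_corr_len_mm[[class]] * len_scale, 1) / sp

  peak <- max(rnorm(1, spec$lesion_suv_peak[[class]][1], spec$lesion_suv_peak[[class]][2]),
              spec$background_suv + 1)

  # lesion texture = smooth radial profile x (1 + correlated field), >= 0,
  # rescaled so the lesion maximum equals the drawn SUV peak. The unit field
  # is winsorised at +-2 so uptake heterogeneity is bounded: a single extreme
  # voxel must not stretch the grey-level range and mask the planted texture.
  profile <- pmax(1 - 0.2 * d2, 0)
  field_pet <- if (het_sd > 0) bounded_field(dims, corr_vox) * het_sd else array(0, dims)
  lesion <- pmax(profile * (1 + field_pet), 0)
  mx <- max(lesion[mask])
  pet <- array(pmax(spec$background_suv + rnorm(prod(dims), 0, spec$noise_sd), 0), dims)
  pet[mask] <- lesion[mask] / mx * peak

  # MR: independent texture field on an arbitrary 0-1000 scale
  field_mr <- if (het_sd > 0) bounded_field(dims, corr_vox) * het_sd else array(0, dims)
  mr <- array(pmax(300 + rnorm(prod(dims), 0, 60 * max(spec$noise_sd, 0.05) / 0.1), 0), dims)
  mr_lesion <- pmax((1 - 0.2 * d2) * (1 + field_mr), 0) * 600
  mr[mask] <- pmin(mr_lesion[mask], 1000)

  list(
    subject_id = subject_id,
    stage_label = stage_label,
    pet_volume = voxel_grid(pet, spacing_mm = sp),
    mr_volume = voxel_grid(mr, spacing_mm = sp),
    lesion_mask = roi_mask(mask, spacing_mm = sp)
  )
}

#' Generate a paired PET/MR phantom cohort
#'
#' Draws `n_subjects` phantom subjects with class-dependent lesion radius,
#' SUV peak and texture heterogeneity (advanced lesions are larger, hotter and
#' more heterogeneous under the defaults), assigns cosmetic covariates and a
#' stratified train/test split. Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Optional directory: per-subject NIfTI volumes
#'   (`<id>_pet.nii.gz`, `<id>_mr.nii.gz`, `<id>_mask.nii.gz`) and `cohort.csv`
#'   are written there.
#' @return A `radstage_cohort`: list with `subjects` (list of subject records)
#'   and `cohort` (tibble `subject_id`, `stage_label`, `age`, `gender`,
#'   `split`).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_subjects
  n_adv <- round(n * spec$class_prevalence)
  n_adv <- min(max(n_adv, 2L), n - 2L)  # at least two per class
  labels <- c(rep(0L, n - n_adv), rep(1L, n_adv))

  # expected lesion volume per class, used to normalise the volume coupling
  mean_vol <- lapply(spec$lesion_radius_mm, function(p) 4 / 3 * pi * p[1]^3)

  subjects <- with_seed(derive_seed(spec$seed, "simulate"), {
    ids <- sprintf("S%03d", seq_len(n))
    lapply(seq_len(n), function(i) {
      simulate_subject(spec, labels[i], ids[i], mean_vol)
    })
  })
  cov <- with_seed(derive_seed(spec$seed, "covariates"), sample_covariates(n))

  cohort <- tibble(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    stage_label = labels,
    age = cov$age,
    gender = cov$gender
  )
  cohort <- split_cohort(cohort, train_fraction = spec$train_fraction,
                         seed = derive_seed(spec$seed, "split"))
  for (i in seq_len(n)) {
    subjects[[i]]$age <- cohort$age[i]
    subjects[[i]]$gender <- cohort$gender[i]
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      write_volume(s$pet_volume, file.path(out_dir, paste0(s$subject_id, "_pet.nii.gz")))
      write_volume(s$mr_volume, file.path(out_dir, paste0(s$subject_id, "_mr.nii.gz")))
      write_volume(s$lesion_mask, file.path(out_dir, paste0(s$subject_id, "_mask.nii.gz")))
    }
    write_table(cohort, file.path(out_dir, "cohort.csv"))
  }

  structure(list(subjects = subjects, cohort = cohort, spec = spec),
            class = "radstage_cohort")
}

#' @export
print.radstage_cohort <- function(x, ...) {
  cat(sprintf(
    "<radstage_cohort> %d subjects (%d early / %d advanced), %d train / %d test\n",
    nrow(x$cohort), sum(x$cohort$stage_label == 0), sum(x$cohort$stage_label == 1),
    sum(x$cohort$split == "train"), sum(x$cohort$split == "test")
  ))
  invisible(x)
}
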