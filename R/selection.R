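#' Stratified train/test split
#'
#' Assigns each subject to the training or testing cohort, stratified by stage
#' label so the class balance survives the split; per-stratum sizes round to
#' the nearest subject. Deterministic given `seed`.
#'
#' @param cohort A data frame with columns `subject_id`, `stage_label`.
#' @param train_fraction Training fraction, default 0.7.
#' @param seed Integer seed.
#' @return The cohort tibble with a `split` column (`"train"` / `"test"`).
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(cohort))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be in (0, 1).")
  }
  classes <- unique(cohort$stage_label)
  if (length(classes) < 2L) abort("both stage classes must be present to split.")
  if (any(table(cohort$stage_label) < 2L)) abort("need at least 2 subjects per class.")
  # largest-remainder apportionment: per-stratum counts round to the nearest
  # subject while the overall training size stays round(n * train_fraction)
  classes <- sort(classes)
  sizes <- vapply(classes, function(cl) sum(cohort$stage_label == cl), 0L)
  target <- round(nrow(cohort) * train_fraction)
  quota <- sizes * train_fraction
  n_train <- floor(quota)
  rem <- order(quota - n_train, decreasing = TRUE)
  short <- target - sum(n_train)
  if (short > 0) n_train[rem[seq_len(short)]] <- n_train[rem[seq_len(short)]] + 1L
  n_train <- pmin(pmax(n_train, 1L), sizes - 1L)
  split <- character(nrow(cohort))
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(cohort$stage_label == classes[i])
      tr <- sample(idx, n_train[i])
      split[idx] <- "test"
      split[tr] <- "train"
    }
  })
  out <- tibble::as_tibble(cohort)
  out$split <- split
  out
}

#' Clean and standardise a feature table
#'
#' Per feature, training values more than `outlier_z` training standard
#' deviations from the training mean are replaced by the mean of the
#' non-outlying training values; columns are then z-scored with the
#' (post-replacement) training mean and sd. Test rows are transformed with the
#' training statistics only, so no test information leaks upstream.
#' Zero-variance features are dropped with a warning.
#'
#' @param features Tibble: `subject_id` + numeric feature columns.
#' @param train_ids Character vector of training subject ids.
#' @param outlier_z Outlier threshold in training z units, default 3.
#' @return A `radstage_cleaned` list: `features` (standardised tibble),
#'   `center`/`scale` (training statistics), `dropped` (zero-variance names),
#'   `n_outliers_replaced`.
#' @export
clean_features <- function(features, train_ids, outlier_z = 3) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  feat_names <- setdiff(names(features), "subject_id")
  tr <- features$subject_id %in% train_ids
  if (!any(tr)) abort("no training rows found in the feature table.")
  X <- as.matrix(features[, feat_names, drop = FALSE])
  center <- numeric(0)
  scale <- numeric(0)
  dropped <- character(0)
  n_repl <- 0L
  for (f in feat_names) {
    x <- X[tr, f]
    mu <- mean(x)
    s <- sd(x)
    if (is.finite(s) && s > 0) {
      z <- abs(x - mu) / s
      out <- z > outlier_z
      if (any(out)) {
        x[out] <- mean(x[!out])
        n_repl <- n_repl + sum(out)
        X[tr, f] <- x
        mu <- mean(x)
        s <- sd(x)
      }
    }
    if (!is.finite(s) || s < 1e-12) {
      dropped <- c(dropped, f)
      next
    }
    center[f] <- mu
    scale[f] <- s
    X[, f] <- (X[, f] - mu) / s
  }
  if (length(dropped) > 0L) {
    warn(sprintf("dropped %d zero-variance feature(s): %s", length(dropped),
                 paste(head(dropped, 5), collapse = ", ")))
  }
  keep <- setdiff(feat_names, dropped)
  out <- dplyr::bind_cols(tibble(subject_id = features$subject_id),
                          tibble::as_tibble(X[, keep, drop = FALSE]))
  structure(list(features = out, center = center, scale = scale,
                 dropped = dropped, n_outliers_replaced = n_repl,
                 train_ids = train_ids),
            class = "radstage_cleaned")
}

# Mutual information (nats) between two discrete codes in 1..ka / 1..kb.
mi_discrete <- function(a, b, ka, kb) {
  n <- length(a)
  joint <- tabulate((b - 1L) * ka + a, nbins = ka * kb) / n  # a fastest
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  ep <- as.vector(outer(pa, pb, `*`))  # also a fastest, b slowest
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / ep[pos]))
}

# Equal-frequency discretisation into (up to) `bins` codes 1..k.
ef_bins <- function(x, bins = 10L) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), type = 7))
  if (length(qs) < 2L) return(list(code = rep(1L, length(x)), k = 1L))
  code <- findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
  list(code = as.integer(code), k = length(qs) - 1L)
}

#' Rank features by minimum redundancy, maximum relevance
#'
#' Greedy mRMR with the MID (mutual-information difference) criterion: the
#' first feature maximises MI with the stage label; each subsequent feature
#' maximises `MI(f; label) - mean(MI(f; already selected))`. MI is estimated
#' by plug-in after equal-frequency 10-bin discretisation of each feature.
#' Ties break in favour of catalogue (column) order.
#'
#' @param train Training feature tibble (`subject_id` + standardised columns),
#'   e.g. the training rows of [clean_features()].
#' @param labels Binary stage labels aligned with `train` rows.
#' @param keep Number of features to keep, default 20.
#' @param bins Discretisation bins for MI estimation, default 10.
#' @return A tibble `name`, `rank`, `relevance`, `redundancy`, `score` in
#'   selection order.
#' @export
mrmr_rank <- function(train, labels, keep = 20L, bins = 10L) {
  feat_names <- setdiff(names(train), "subject_id")
  if (keep > length(feat_names)) abort("`keep` exceeds the number of features.")
  y <- as.integer(factor(labels))
  ky <- length(unique(y))
  X <- as.matrix(train[, feat_names, drop = FALSE])
  n_feat <- length(feat_names)
  disc <- lapply(seq_len(n_feat), function(j) ef_bins(X[, j], bins))
  rel <- vapply(disc, function(d) mi_discrete(d$code, y, d$k, ky), 0)

  selected <- integer(0)
  red_sum <- numeric(n_feat)  # sum of MI(f, s) over selected s
  red_mean <- numeric(n_feat)
  out <- vector("list", keep)
  remaining <- seq_len(n_feat)
  for (step in seq_len(keep)) {
    score <- if (step == 1L) rel[remaining] else rel[remaining] - red_mean[remaining]
    pick <- remaining[which.max(score)]  # which.max: first max = catalogue order
    out[[step]] <- tibble(
      name = feat_names[pick], rank = step, relevance = rel[pick],
      redundancy = if (step == 1L) 0 else red_mean[pick],
      score = if (step == 1L) rel[pick] else rel[pick] - red_mean[pick]
    )
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0L) break
    dp <- disc[[pick]]
    upd <- vapply(remaining, function(j) {
      mi_discrete(disc[[j]]$code, dp$code, disc[[j]]$k, dp$k)
    }, 0)
    red_sum[remaining] <- red_sum[remaining] + upd
    red_mean[remaining] <- red_sum[remaining] / length(selected)
  }
  dplyr::bind_rows(out)
}

#' L1-penalised logistic selection with cross-validation
#'
#' Fits the lasso-logistic path over a log-spaced lambda grid on the
#' mRMR-kept features, picks `lambda*` by stratified k-fold cross-validated
#' misclassification error (probability cutoff 0.5, minimum rule), and
#' returns the features with nonzero coefficients at `lambda*`.
#'
#' @param train Training feature tibble restricted to the mRMR-kept columns
#'   (`subject_id` + features).
#' @param labels Binary stage labels aligned with `train` rows.
#' @param folds Number of CV folds, default 10 (stratified).
#' @param nlambda Lambda grid size, default 50.
#' @param seed Seed for fold assignment.
#' @return A `radstage_selection` list: `selected` (names), `lambda_star`,
#'   `lambda` (grid), `cv_error`, `nonzero` (per-lambda counts), `coefs`
#'   (coefficients at `lambda_star`), `ranking_names`.
#' @export
lasso_select <- function(train, labels, folds = 10L, nlambda = 50L, seed = 1L) {
  feat_names <- setdiff(names(train), "subject_id")
  X <- as.matrix(train[, feat_names, drop = FALSE])
  y <- as.integer(labels)
  if (folds > nrow(X)) abort("more folds than training subjects.")
  foldid <- integer(nrow(X))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, nlambda = nlambda)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          lambda = fit$lambda, foldid = foldid,
                          type.measure = "class")
  lambda_star <- cv$lambda.min
  cf <- as.matrix(coef(fit, s = lambda_star))
  nz <- rownames(cf)[cf[, 1] != 0]
  selected <- setdiff(nz, "(Intercept)")
  if (length(selected) == 0L) {
    warn("lasso selected no feature at lambda*; callers should fail loudly.")
  }
  structure(list(
    selected = selected,
    lambda_star = lambda_star,
    lambda = cv$lambda,
    cv_error = cv$cvm,
    nonzero = setNames(fit$df, paste0("s", seq_along(fit$lambda) - 1L)),
    coefs = setNames(cf[, 1], rownames(cf)),
    ranking_names = feat_names
  ), class = "radstage_selection")
}

#' @export
print.radstage_selection <- function(x, ...) {
  cat(sprintf("<radstage_selection> %d feature(s) at lambda* = %.4g\n",
              length(x$selected), x$lambda_star))
  if (length(x$selected)) cat(paste0("  ", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' Run the full selection stage for one modality
#'
#' Cleaning/standardisation on the training split, mRMR ranking (keep 20),
#' then lasso-logistic selection with 10-fold CV, mirroring the two-step
#' dimension reduction of the staging study.
#'
#' @param features Feature tibble (`subject_id` + 396 columns).
#' @param cohort Cohort tibble with `subject_id`, `stage_label`, `split`.
#' @param keep mRMR keep count, default 20.
#' @param folds CV folds, default 10.
#' @param seed Seed for fold assignment.
#' @return List with `cleaned`, `ranking`, `selection`.
#' @export
select_features <- function(features, cohort, keep = 20L, folds = 10L, seed = 1L) {
  train_ids <- cohort$subject_id[cohort$split == "train"]
  cleaned <- clean_features(features, train_ids)
  tr_tbl <- dplyr::semi_join(cleaned$features,
                             tibble(subject_id = train_ids), by = "subject_id")
  lab <- cohort$stage_label[match(tr_tbl$subject_id, cohort$subject_id)]
  ranking <- mrmr_rank(tr_tbl, lab, keep = keep)
  kept <- tr_tbl[, c("subject_id", ranking$name)]
  selection <- lasso_select(kept, lab, folds = folds, seed = seed)
  list(cleaned = cleaned, ranking = ranking, selection = selection)
}
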