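#' Pearson correlation of features against metabolic parameters
#'
#' Product-moment correlation of each selected radiomic feature against
#' SUVmax, MTV and TLG across the full cohort, with two-sided p-values from
#' the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#' Significance stars follow the usual convention (* p < 0.05, ** p < 0.01,
#' no multiplicity correction). A zero-variance vector yields `NA`.
#'
#' @param features Feature tibble (`subject_id` + columns), typically
#'   restricted to the selected feature names.
#' @param metabolics Tibble from [cohort_metabolics()].
#' @param feature_names Features to correlate; default = all non-id columns.
#' @param parameters Metabolic columns, default `c("suv_max", "mtv_ml", "tlg")`.
#' @return A tibble: `feature`, `parameter`, `r`, `p`, `sig`.
#' @export
pearson_matrix <- function(features, metabolics,
                           feature_names = NULL,
                           parameters = c("suv_max", "mtv_ml", "tlg")) {
  feature_names <- feature_names %||% setdiff(names(features), "subject_id")
  joined <- dplyr::inner_join(features[, c("subject_id", feature_names)],
                              metabolics, by = "subject_id")
  n <- nrow(joined)
  if (n < 3L) abort("need at least 3 paired observations.")
  grid <- tidyr::expand_grid(feature = feature_names, parameter = parameters)
  res <- purrr::pmap(grid, function(feature, parameter) {
    x <- joined[[feature]]
    y <- joined[[parameter]]
    if (sd(x) < 1e-15 || sd(y) < 1e-15) {
      return(tibble(feature = feature, parameter = parameter,
                    r = NA_real_, p = NA_real_, sig = NA_character_))
    }
    r <- cor(x, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    tibble(feature = feature, parameter = parameter, r = r, p = p,
           sig = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  })
  dplyr::bind_rows(res)
}

#' Pooled-variance two-sample t-test
#'
#' Classical two-sample t with pooled variance on `n1 + n2 - 2` degrees of
#' freedom, available both from summary statistics and from raw vectors
#' (`two_sample_t_raw()`). The statistic is `(mean2 - mean1) / se` with group
#' 1 = the first (training) group, matching the reporting convention of
#' train-vs-test cohort tables.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A tibble: `statistic`, `df`, `p`.
#' @examples
#' two_sample_t(52.23, 12.33, 70, 50.40, 13.68, 30)  # t = -0.658, p = 0.512
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("both groups need at least 2 observations.")
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0) {
    abort("standard deviations must be positive.")
  }
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  tibble(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

#' @param x,y Raw observation vectors for groups 1 and 2.
#' @rdname two_sample_t
#' @export
two_sample_t_raw <- function(x, y) {
  two_sample_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction on a table of counts,
#' `df = (rows - 1)(cols - 1)`.
#'
#' @param tab Matrix of nonnegative counts with positive margins.
#' @return A tibble: `statistic`, `df`, `p`.
#' @examples
#' chi_square_test(matrix(c(56, 22, 14, 8), 2))  # 0.544, p = 0.461
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("counts must be nonnegative.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has a zero margin.")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p = unname(res$p.value))
}

#' Train-vs-test cohort comparison table
#'
#' The clinical-table replica: continuous variables (age, SUVmax, MTV, TLG)
#' via the pooled two-sample t-test, categorical variables (gender, stage
#' distribution) via Pearson chi-square, each comparing the training and
#' testing cohorts.
#'
#' @param cohort Cohort tibble with `subject_id`, `stage_label`, `age`,
#'   `gender`, `split`.
#' @param metabolics Tibble from [cohort_metabolics()].
#' @return A tibble: `variable`, `test`, `statistic`, `p`.
#' @export
compare_cohorts <- function(cohort, metabolics) {
  if (length(unique(cohort$split)) < 2L) abort("both train and test splits required.")
  d <- dplyr::inner_join(cohort, metabolics, by = "subject_id")
  tr <- d[d$split == "train", ]
  te <- d[d$split == "test", ]
  cont <- c(age = "age", suv_max = "suv_max", mtv_ml = "mtv_ml", tlg = "tlg")
  rows <- purrr::imap(cont, function(col, nm) {
    res <- two_sample_t_raw(tr[[col]], te[[col]])
    tibble(variable = nm, test = "t", statistic = res$statistic, p = res$p)
  })
  cat_tests <- list(
    gender = table(factor(d$split, c("train", "test")), d$gender),
    stage = table(factor(d$split, c("train", "test")), d$stage_label)
  )
  rows2 <- purrr::imap(cat_tests, function(tab, nm) {
    res <- chi_square_test(tab)
    tibble(variable = nm, test = "chi-square", statistic = res$statistic, p = res$p)
  })
  dplyr::bind_rows(c(rows, rows2))
}
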