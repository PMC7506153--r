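test_that("logistic fitting recovers known coefficients", {
  set.seed(71)
  n <- 2000
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  eta <- 0.2 + 1 * x1 - 0.5 * x2
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  tbl <- tibble::tibble(subject_id = as.character(1:n), x1 = x1, x2 = x2)
  m <- fit_stage_model(tbl, y)
  expect_lt(abs(m$coefficients[["x1"]] - 1), 0.15)
  expect_lt(abs(m$coefficients[["x2"]] + 0.5), 0.15)
})

test_that("the null model gives intercept ~0 and probabilities ~0.5", {
  n <- 400
  tbl <- tibble::tibble(subject_id = as.character(1:n), x = rep(0, n))
  y <- rep_len(0:1, n)
  m <- suppressWarnings(fit_stage_model(tbl, y))
  expect_lt(abs(m$intercept), 1e-6)
  probs <- 1 / (1 + exp(-radscore(m, tbl)))
  expect_true(all(abs(probs - 0.5) < 1e-6))
})

test_that("perfect separation falls back to a stabilised fit", {
  n <- 60
  y <- rep_len(0:1, n)
  tbl <- tibble::tibble(subject_id = as.character(1:n), x = y * 2 - 1 + rnorm(n, 0, 1e-4))
  expect_warning(m <- fit_stage_model(tbl, y), "separation")
  probs <- 1 / (1 + exp(-radscore(m, tbl)))
  expect_true(all(probs[y == 1] > 0.99))
  expect_true(all(probs[y == 0] < 0.01))
})

test_that("radscore is the affine linear predictor", {
  m <- structure(list(intercept = 0.1, coefficients = c(f = 0.5),
                      features = "f", modality = "pet", cutoff = 0),
                 class = "stage_model")
  expect_equal(radscore(m, tibble::tibble(f = 2)), 1.1)
  expect_equal(radscore(m, tibble::tibble(f = 0)), 0.1)
  # affinity: score(x + y) - score(y) = score(x) - intercept
  x <- 1.3; y <- -0.4
  expect_equal(radscore(m, tibble::tibble(f = x + y)) - radscore(m, tibble::tibble(f = y)),
               radscore(m, tibble::tibble(f = x)) - m$intercept)
  expect_error(radscore(m, tibble::tibble(g = 1)), "missing")
})

test_that("ROC analysis reproduces enumerated AUCs and tie conventions", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # positives {2, 4} vs negatives {1, 3}: 3 of 4 pairs concordant
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_analysis(c(2, 2, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
  pts <- roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$roc_points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC equals the pair-counting oracle and pROC on random score sets", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(6), n, replace = TRUE) + round(rnorm(n), 1)
    expect_equal(roc_analysis(s, y)$auc, auc_oracle(s, y))
  }
  y <- c(0, 0, 1, 1, 0, 1, 1, 0, 1)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.2, 0.5, 0.5, 0.5, 0.9)
  expect_equal(roc_analysis(s, y)$auc,
               as.numeric(suppressMessages(pROC::auc(y, s))))
})

test_that("the Youden cutoff matches exhaustive threshold enumeration", {
  # positives {2, 4}, negatives {1, 3}: J = 0.5 at cutoffs 2 (sens 1,
  # spec .5) and 4 (sens .5, spec 1) -- the tie resolves to the lower cutoff
  res <- choose_cutoff(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(res$cutoff, 2)
  expect_equal(res$accuracy, 0.75)
  expect_equal(res$youden, 0.5)

  sep <- choose_cutoff(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(sep$youden, 1)
  expect_equal(sep$accuracy, 1)

  expect_message(choose_cutoff(c(4, 3, 2, 1), c(0, 0, 1, 1)), "inversely")
})

test_that("calibration curves are honest for calibrated inputs", {
  set.seed(90)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  cal <- calibration_curve(p, y)
  expect_equal(nrow(cal$bins), 10)
  expect_lt(abs(cal$slope - 1), 0.1)

  cal2 <- calibration_curve(rep(0.5, 100), rep_len(0:1, 100))
  expect_equal(nrow(cal2$bins), 1)
  expect_true(is.na(cal2$slope))
  expect_equal(cal2$bins$observed_fraction, 0.5)

  y3 <- rep_len(0:1, 40)
  cal3 <- calibration_curve(as.numeric(y3), y3)
  expect_equal(cal3$slope, 1)
  expect_equal(cal3$intercept, 0)
  expect_error(calibration_curve(c(-0.1, 0.5), c(0, 1)), "0, 1")
})

test_that("reports evaluate a frozen model with train and cohort cutoffs", {
  set.seed(14)
  n <- 120
  y <- rep_len(0:1, n)
  tbl <- tibble::tibble(subject_id = as.character(1:n), x = y + rnorm(n, 0, 0.8))
  m <- fit_stage_model(tbl, y, modality = "pet")
  rep_tr <- evaluate_model(m, tbl, y, cohort_name = "train")
  expect_equal(rep_tr$cutoff, m$cutoff)
  expect_true(rep_tr$auc >= 0.5 && rep_tr$auc <= 1)
  td <- tidy(rep_tr)
  expect_identical(td$cohort, "train")
  expect_identical(names(td), c("cohort", "modality", "auc", "accuracy",
                                "sensitivity", "specificity", "cutoff",
                                "cohort_cutoff"))
  # metrics at the stored cutoff agree with direct recomputation
  sc <- radscore(m, tbl)
  expect_equal(rep_tr$accuracy, mean(as.integer(sc >= m$cutoff) == y))
})

test_that("tidy/glance/autoplot methods expose the fitted model", {
  n <- 80
  y <- rep_len(0:1, n)
  tbl <- tibble::tibble(subject_id = as.character(1:n), a = y + rnorm(n), b = rnorm(n))
  m <- fit_stage_model(tbl, y, modality = "mr")
  td <- tidy(m)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 3)
  gl <- glance(m)
  expect_equal(gl$n_features, 2)
  expect_identical(gl$modality, "mr")
  rep <- evaluate_model(m, tbl, y)
  expect_s3_class(autoplot(rep$roc), "ggplot")
  expect_s3_class(autoplot(rep$calibration), "ggplot")
})
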