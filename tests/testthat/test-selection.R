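make_cohort_tbl <- function(n, prev = 0.5) {
  n1 <- round(n * prev)
  tibble::tibble(
    subject_id = sprintf("P%03d", seq_len(n)),
    stage_label = rep(c(0L, 1L), c(n - n1, n1))
  )
}

test_that("the stratified split rounds to the nearest subject per class", {
  coh <- make_cohort_tbl(100, 0.73)
  sp <- split_cohort(coh, 0.7, seed = 3)
  expect_equal(sum(sp$split == "train"), 70)
  expect_equal(sum(sp$split == "test"), 30)
  tab <- table(sp$split, sp$stage_label)
  expect_equal(unname(tab["train", "1"]), 51)  # round(73 * 0.7)
  expect_equal(unname(tab["train", "0"]), 19)

  sp10 <- split_cohort(make_cohort_tbl(10, 0.5), 0.7, seed = 1)
  expect_equal(sum(sp10$split == "train"), 7)
  expect_equal(sum(sp10$split == "test"), 3)

  expect_identical(split_cohort(coh, 0.7, seed = 9)$split,
                   split_cohort(coh, 0.7, seed = 9)$split)
  expect_error(split_cohort(dplyr::filter(coh, stage_label == 1), 0.7, 1), "classes")
})

test_that("cleaning replaces gross outliers and standardises on training stats", {
  n <- 50
  x <- c(rep(0, n - 1), 100)
  tbl <- tibble::tibble(subject_id = sprintf("P%03d", 1:n), f1 = x, f2 = rnorm(n),
                        f3 = 1)
  expect_warning(cl <- clean_features(tbl, train_ids = tbl$subject_id[1:40]),
                 "zero-variance")
  expect_false("f3" %in% names(cl$features))
  # the 100 lands outside the training split, transformed with training stats:
  # training f1 is all zeros after replacement... it is constant -> dropped too
  expect_true("f1" %in% cl$dropped || all(abs(cl$features$f1[1:40]) < 1e-9))

  # standardisation contract on a well-behaved table
  tbl2 <- tibble::tibble(subject_id = sprintf("P%03d", 1:n),
                         a = rnorm(n, 5, 2), b = runif(n))
  tr_ids <- tbl2$subject_id[1:35]
  cl2 <- clean_features(tbl2, tr_ids)
  tr_rows <- cl2$features$subject_id %in% tr_ids
  expect_equal(mean(cl2$features$a[tr_rows]), 0, tolerance = 1e-9)
  expect_equal(sd(cl2$features$a[tr_rows]), 1, tolerance = 1e-9)
  expect_equal(sd(cl2$features$b[tr_rows]), 1, tolerance = 1e-9)
})

test_that("an outlier inside the training split is pulled to the clean mean", {
  n <- 50
  set.seed(2)
  x <- rnorm(n)
  x[10] <- 100
  tbl <- tibble::tibble(subject_id = sprintf("P%03d", 1:n), f = x)
  cl <- clean_features(tbl, train_ids = tbl$subject_id)
  expect_equal(cl$n_outliers_replaced, 1)
  # after replacement and z-scoring no value is extreme any more
  expect_lt(max(abs(cl$features$f)), 5)
})

test_that("test rows never influence cleaning or ranking (no leakage)", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("f", 1:20)
  tbl <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("P%03d", 1:n)),
                          tibble::as_tibble(X))
  tr_ids <- tbl$subject_id[1:42]
  y_tr <- rep_len(0:1, 42)
  base <- clean_features(tbl, tr_ids)
  # corrupt every test row; training statistics and the ranking must not move
  tbl2 <- tbl
  tbl2[43:60, -1] <- tbl2[43:60, -1] * 1000 + 77
  alt <- clean_features(tbl2, tr_ids)
  expect_identical(base$center, alt$center)
  expect_identical(base$scale, alt$scale)
  tr_tbl <- base$features[base$features$subject_id %in% tr_ids, ]
  tr_tbl2 <- alt$features[alt$features$subject_id %in% tr_ids, ]
  expect_identical(mrmr_rank(tr_tbl, y_tr, keep = 5),
                   mrmr_rank(tr_tbl2, y_tr, keep = 5))
})

test_that("mRMR ranks a label-copy first and returns exactly `keep` names", {
  set.seed(8)
  n <- 80
  y <- rep_len(0:1, n)
  tbl <- tibble::tibble(
    subject_id = sprintf("P%03d", 1:n),
    oracle = y + rnorm(n, 0, 1e-6),  # essentially the label itself
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)
  )
  rk <- mrmr_rank(tbl, y, keep = 3)
  expect_equal(nrow(rk), 3)
  expect_equal(rk$name[1], "oracle")
  expect_error(mrmr_rank(tbl, y, keep = 10), "exceeds")
})

test_that("the redundancy penalty demotes a duplicated informative feature", {
  # f_dup duplicates f_info; a weaker but independent feature must outrank
  # the duplicate once the redundancy penalty bites (MID hand computation)
  set.seed(19)
  n <- 200
  y <- rep_len(0:1, n)
  f_info <- y + rnorm(n, 0, 0.5)
  f_dup <- f_info + rnorm(n, 0, 1e-3)
  f_weak <- y + rnorm(n, 0, 2.5)
  tbl <- tibble::tibble(subject_id = sprintf("P%03d", 1:n),
                        f_info = f_info, f_dup = f_dup, f_weak = f_weak)
  rk <- mrmr_rank(tbl, y, keep = 3)
  expect_equal(rk$name[1], "f_info")
  expect_equal(rk$name[2], "f_weak")
  expect_equal(rk$name[3], "f_dup")
})

test_that("lasso selection honours its grid-endpoint and arg-min contracts", {
  set.seed(5)
  n <- 140
  y <- rep_len(0:1, n)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 1] <- y * 4 - 2 + rnorm(n, 0, 0.05)  # essentially separating
  colnames(X) <- paste0("f", 1:6)
  tbl <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("P%03d", 1:n)),
                          tibble::as_tibble(X))
  sel <- lasso_select(tbl, y, folds = 10, seed = 11)
  expect_true("f1" %in% sel$selected)
  # largest lambda: nothing enters the model
  expect_equal(unname(sel$nonzero[1]), 0L)
  # lambda* attains the minimum CV error on the grid
  expect_equal(min(sel$cv_error), sel$cv_error[which(sel$lambda == sel$lambda_star)])
  # smallest lambda is at least as dense as lambda*
  expect_gte(unname(tail(sel$nonzero, 1)),
             sum(names(sel$coefs) != "(Intercept)" & sel$coefs != 0))
})

test_that("planted informative features are recovered by mRMR", {
  set.seed(99)
  hits <- replicate(50, {
    n <- 140
    p <- 396
    X <- matrix(rnorm(n * p), n, p)
    y <- rep_len(0:1, n)
    X[, 1:5] <- X[, 1:5] + y  # standardised effect d = 1
    colnames(X) <- paste0("f", seq_len(p))
    tbl <- dplyr::bind_cols(tibble::tibble(subject_id = as.character(1:n)),
                            tibble::as_tibble(X))
    rk <- mrmr_rank(tbl, y, keep = 20)
    expect_equal(nrow(rk), 20)
    sum(paste0("f", 1:5) %in% rk$name)
  })
  expect_gte(mean(hits >= 4), 0.9)
})
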