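#' Fit the logistic staging model
#'
#' Unpenalised maximum-likelihood logistic regression of the binary stage
#' label on the selected standardised features. Under perfect separation the
#' fit falls back to a ridge-stabilised solution (L2 penalty 1e-6) with a
#' warning. The training radscore cutoff (Youden index) is stored with the
#' model.
#'
#' @param train Training feature tibble (`subject_id` + selected columns).
#' @param labels Binary stage labels aligned with `train` rows.
#' @param features Character vector of selected feature names; defaults to all
#'   non-id columns.
#' @param modality Optional label carried in reports (`"pet"`, `"mr"`, ...).
#' @return A `stage_model`: coefficients, feature names, training cutoff.
#' @export
fit_stage_model <- function(train, labels, features = NULL, modality = NA_character_) {
  features <- features %||% setdiff(names(train), "subject_id")
  if (length(features) == 0L) abort("no features to fit: selection was empty.")
  X <- as.matrix(train[, features, drop = FALSE])
  if (anyNA(X)) abort("missing feature values: clean the table first.")
  y <- as.integer(labels)
  df <- data.frame(y = y, X, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 200)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  cf[is.na(cf)] <- 0  # rank-deficient columns carry no information
  if (separated || any(abs(cf) > 50)) {
    warn("quasi-separation detected: refitting with a ridge-stabilised model.")
    cf <- ridge_logistic(X, y, lambda = 1e-6)
  }
  names(cf)[1] <- "(Intercept)"
  model <- structure(list(
    intercept = unname(cf[1]),
    coefficients = setNames(cf[-1], features),
    features = features,
    modality = modality,
    cutoff = NA_real_
  ), class = "stage_model")
  scores <- radscore(model, train)
  model$cutoff <- choose_cutoff(scores, y)$cutoff
  model
}

# Newton-iterated L2-penalised logistic fit (intercept unpenalised); the
# stabiliser used under quasi-separation, where the tiny penalty bounds the
# coefficients without materially moving the decision boundary.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 200, tol = 1e-8) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(as.vector(Xd %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Xd, y - mu) - pen %*% beta
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    beta <- beta + as.vector(step)
    if (max(abs(grad)) < tol) break
  }
  setNames(as.vector(beta), colnames(Xd))
}

#' Radscore: the model's linear predictor
#'
#' `radscore = intercept + sum(beta_i * x_i)` on the selected standardised
#' features; the per-subject staging score the cutoff is applied to.
#'
#' @param model A `stage_model`.
#' @param newdata Feature data frame containing the model's features.
#' @return Numeric vector of radscores.
#' @export
radscore <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing) > 0L) {
    abort(sprintf("missing model feature(s): %s", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[, model$features, drop = FALSE])
  as.vector(model$intercept + X %*% model$coefficients)
}

#' Empirical ROC curve and AUC
#'
#' ROC over all observed score thresholds (predicted positive = score >=
#' threshold), with AUC by the trapezoidal rule — equivalent to the
#' Mann-Whitney statistic with 1/2 credit for ties.
#'
#' @param scores Numeric scores (higher = more advanced).
#' @param labels Binary labels (1 = advanced).
#' @return A `radstage_roc` list: `auc` and `roc_points` tibble
#'   (`threshold`, `fpr`, `tpr`).
#' @export
roc_analysis <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) abort("both classes must be present.")
  np <- sum(y == 1)
  nn <- sum(y == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nn, 0)
  pts <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(auc = auc, roc_points = pts), class = "radstage_roc")
}

#' Optimal radscore cutoff by the Youden index
#'
#' Maximises `J = sensitivity + specificity - 1` over the observed scores
#' (predicted positive = score >= cutoff); ties resolve to the lower cutoff.
#' An orientation problem (AUC < 0.5) is reported with a message.
#'
#' @inheritParams roc_analysis
#' @return List: `cutoff`, `accuracy`, `sensitivity`, `specificity`, `youden`.
#' @export
choose_cutoff <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) abort("both classes must be present.")
  auc <- roc_analysis(scores, y)$auc
  if (auc < 0.5) inform("AUC < 0.5: scores appear inversely oriented to the label.")
  cand <- sort(unique(scores))
  stats <- vapply(cand, function(ct) {
    pred <- as.integer(scores >= ct)
    sens <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    c(sens + spec - 1, sens, spec, mean(pred == y))
  }, numeric(4))
  best <- which.max(stats[1, ])  # first max = lowest cutoff on ties
  list(cutoff = cand[best], accuracy = stats[4, best],
       sensitivity = stats[2, best], specificity = stats[3, best],
       youden = stats[1, best])
}

#' Calibration curve of predicted probabilities
#'
#' Ten equal-width probability bins; each nonempty bin contributes its mean
#' predicted probability and observed event fraction, and a least-squares
#' line is fitted through the bin points (undefined, with bins still
#' reported, when fewer than two bins are nonempty).
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Binary outcomes.
#' @param bins Number of equal-width bins, default 10.
#' @return A `radstage_calibration` list: `bins` tibble (`bin`,
#'   `mean_predicted`, `observed_fraction`, `n`), `slope`, `intercept`.
#' @export
calibration_curve <- function(probs, labels, bins = 10L) {
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  y <- as.integer(labels)
  b <- pmin(floor(probs * bins), bins - 1L) + 1L
  tab <- tibble(bin = b, p = probs, y = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_predicted = mean(.data$p),
                     observed_fraction = mean(.data$y),
                     n = dplyr::n(), .groups = "drop")
  if (nrow(tab) >= 2L) {
    fit <- lm(observed_fraction ~ mean_predicted, data = tab)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  } else {
    slope <- NA_real_
    intercept <- NA_real_
  }
  structure(list(bins = tab, slope = slope, intercept = intercept),
            class = "radstage_calibration")
}

#' Diagnostic report for a frozen staging model
#'
#' Evaluates one fitted model on a cohort: AUC, accuracy/sensitivity/
#' specificity at the supplied radscore cutoff (defaults to the model's
#' training cutoff), the per-cohort Youden-optimal cutoff reported alongside,
#' ROC points and the calibration curve. The model is never refitted here.
#'
#' @param model A `stage_model`.
#' @param data Feature tibble for the cohort.
#' @param labels Binary stage labels aligned with `data` rows.
#' @param cutoff Radscore cutoff; default = the model's training cutoff.
#' @param cohort_name `"train"` or `"test"` (carried in the report).
#' @return A `stage_report` list: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `cutoff`, `cohort_cutoff` (per-cohort optimum), `roc`,
#'   `calibration`, `cohort`, `modality`.
#' @export
evaluate_model <- function(model, data, labels, cutoff = NULL,
                           cohort_name = "train") {
  scores <- radscore(model, data)
  y <- as.integer(labels)
  cutoff <- cutoff %||% model$cutoff
  roc <- roc_analysis(scores, y)
  own <- choose_cutoff(scores, y)
  pred <- as.integer(scores >= cutoff)
  probs <- 1 / (1 + exp(-scores))
  structure(list(
    auc = roc$auc,
    accuracy = mean(pred == y),
    sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
    specificity = sum(pred == 0 & y == 0) / sum(y == 0),
    cutoff = cutoff,
    cohort_cutoff = own$cutoff,
    roc = roc,
    calibration = calibration_curve(probs, y),
    cohort = cohort_name,
    modality = model$modality
  ), class = "stage_report")
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("<stage_model%s> %d feature(s), training cutoff %.3f\n",
              if (is.na(x$modality)) "" else paste0(" ", x$modality),
              length(x$features), x$cutoff))
  print(tidy(x))
  invisible(x)
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf(
    "<stage_report %s%s> AUC %.3f | acc %.3f | sens %.3f | spec %.3f @ cutoff %.3f\n",
    if (is.na(x$modality)) "" else paste0(x$modality, " "), x$cohort,
    x$auc, x$accuracy, x$sensitivity, x$specificity, x$cutoff
  ))
  invisible(x)
}

#' Tidy a staging model's coefficients
#'
#' @param x A `stage_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @export
tidy.stage_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.stage_model
#' @export
glance.stage_model <- function(x, ...) {
  tibble(n_features = length(x$features), cutoff = x$cutoff,
         modality = x$modality)
}

#' @param x A `stage_report`.
#' @param ... Unused.
#' @rdname evaluate_model
#' @export
tidy.stage_report <- function(x, ...) {
  tibble(
    cohort = x$cohort, modality = x$modality, auc = x$auc,
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, cutoff = x$cutoff,
    cohort_cutoff = x$cohort_cutoff
  )
}

#' Plot an ROC curve
#'
#' @param object A `radstage_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radstage_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' @param object A `radstage_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radstage_calibration <- function(object, ...) {
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(x = .data$mean_predicted,
                                    y = .data$observed_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point()
  if (is.finite(object$slope)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept, colour = "red")
  }
  p + ggplot2::labs(x = "Mean predicted probability", y = "Observed fraction") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
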