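#' Area under the ROC curve
#'
#' The probability that a randomly chosen event outranks a randomly chosen
#' non-event, ties counted half, computed from midranks. The confidence
#' interval uses the DeLong placement variance.
#'
#' @param pred Numeric prediction vector (any monotone score).
#' @param outcome Binary outcome vector.
#' @param level Confidence level. Default 0.95.
#' @return One-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
auroc <- function(pred, outcome, level = 0.95) {
  stopifnot(length(pred) == length(outcome))
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pred[keep]
  outcome <- as.numeric(outcome[keep])
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC requires both outcome classes", call. = FALSE)
  }
  r <- rank(pred, ties.method = "average")
  a <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  rx <- rank(pred[outcome == 1], ties.method = "average")
  ry <- rank(pred[outcome == 0], ties.method = "average")
  v10 <- (r[outcome == 1] - rx) / n0       # placement of each event
  v01 <- 1 - (r[outcome == 0] - ry) / n1   # placement of each non-event
  var_a <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(var_a)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(estimate = a, std.error = se,
                 conf.low = max(0, a - z * se),
                 conf.high = min(1, a + z * se))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary
#' outcome; zero is perfect.
#'
#' @param pred Probabilities in `[0, 1]`.
#' @param outcome Binary outcome vector.
#' @return A single number.
#' @export
brier_score <- function(pred, outcome) {
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pred[keep]
  outcome <- as.numeric(outcome[keep])
  if (any(pred < 0 | pred > 1)) {
    stop("predictions must lie in [0, 1]", call. = FALSE)
  }
  mean((pred - outcome)^2)
}

#' Calibration slope and intercept
#'
#' The slope comes from the free logistic recalibration of the outcome on
#' the logit of the prediction; the intercept is calibration-in-the-large,
#' i.e. the same regression with the slope fixed at 1 (offset model). Ideal
#' calibration gives slope 1 and intercept 0.
#'
#' @param pred Probabilities; values outside `(0, 1)` are clamped to
#'   `[1e-12, 1 - 1e-12]` with a warning.
#' @param outcome Binary outcome vector.
#' @param level Confidence level. Default 0.95.
#' @return Tibble with rows `slope` and `intercept`: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
calibration_fit <- function(pred, outcome, level = 0.95) {
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pred[keep]
  outcome <- as.numeric(outcome[keep])
  if (any(pred <= 0 | pred >= 1)) {
    warning("predictions at or beyond 0/1 clamped to [1e-12, 1 - 1e-12]",
            call. = FALSE)
    pred <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
  }
  lp <- stats::qlogis(pred)
  z <- stats::qnorm(1 - (1 - level) / 2)
  slope_fit <- stats::glm.fit(cbind(1, lp), outcome,
                              family = stats::binomial())
  if (!slope_fit$converged) {
    stop("calibration regression did not converge (separation?)",
         call. = FALSE)
  }
  w <- slope_fit$weights
  xw <- cbind(1, lp)
  slope_vcov <- solve(crossprod(xw, xw * w))
  slope <- slope_fit$coefficients[2]
  slope_se <- sqrt(slope_vcov[2, 2])
  int_fit <- stats::glm.fit(matrix(1, length(lp)), outcome,
                            family = stats::binomial(), offset = lp)
  int <- int_fit$coefficients[1]
  int_se <- sqrt(1 / sum(int_fit$weights))
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(unname(slope), unname(int)),
    std.error = c(slope_se, int_se),
    conf.low = c(slope - z * slope_se, int - z * int_se),
    conf.high = c(slope + z * slope_se, int + z * int_se)
  )
}

#' Hosmer--Lemeshow goodness-of-fit test
#'
#' Groups records into deciles of predicted risk and compares observed vs
#' expected events and non-events with a chi-square statistic on
#' `groups - 2` degrees of freedom. Groups whose expected event count is
#' zero are merged with their neighbour, with a warning.
#'
#' @param pred Probabilities.
#' @param outcome Binary outcome vector.
#' @param groups Number of risk groups. Default 10.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `groups`.
#' @export
hosmer_lemeshow <- function(pred, outcome, groups = 10) {
  stopifnot(groups >= 2)
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pred[keep]
  outcome <- as.numeric(outcome[keep])
  br <- unique(stats::quantile(pred, seq(0, 1, length.out = groups + 1)))
  g <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(g = g, p = pred, y = outcome), g),
    n = dplyr::n(), obs = sum(.data$y), exp = sum(.data$p),
    .groups = "drop"
  )
  while (any(tab$exp == 0 | tab$n - tab$exp == 0) && nrow(tab) > 2) {
    warning("merging a risk group with zero expected count", call. = FALSE)
    i <- which(tab$exp == 0 | tab$n - tab$exp == 0)[1]
    j <- if (i == 1) 2 else i - 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$obs[j] <- tab$obs[j] + tab$obs[i]
    tab$exp[j] <- tab$exp[j] + tab$exp[i]
    tab <- tab[-i, ]
  }
  stat <- sum((tab$obs - tab$exp)^2 / tab$exp +
                ((tab$n - tab$obs) - (tab$n - tab$exp))^2 /
                  (tab$n - tab$exp))
  df <- nrow(tab) - 2
  tibble::tibble(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 groups = nrow(tab))
}

#' Risk decile table
#'
#' @param pred Probabilities.
#' @param outcome Binary outcome vector.
#' @param groups Number of groups. Default 10.
#' @return Tibble with `decile`, `n`, `mean_predicted`, `observed_rate`.
#' @export
decile_table <- function(pred, outcome, groups = 10) {
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pred[keep]
  outcome <- as.numeric(outcome[keep])
  br <- unique(stats::quantile(pred, seq(0, 1, length.out = groups + 1)))
  g <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(g = g, p = pred, y = outcome),
                    decile = g),
    n = dplyr::n(), mean_predicted = mean(.data$p),
    observed_rate = mean(.data$y), .groups = "drop"
  )
}

#' Smoothed calibration curve
#'
#' Fits a penalized spline logistic smoother (a generalised additive model)
#' of the outcome on the logit of the prediction and evaluates it on a grid
#' of predicted probabilities, with pointwise 95% bands. Under perfect
#' calibration the curve approaches the diagonal.
#'
#' @param pred Probabilities.
#' @param outcome Binary outcome vector.
#' @param n_grid Grid size. Default 100.
#' @return Tibble with `predicted`, `observed`, `conf.low`, `conf.high`.
#' @export
calibration_curve <- function(pred, outcome, n_grid = 100) {
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pmin(pmax(pred[keep], 1e-12), 1 - 1e-12)
  outcome <- as.numeric(outcome[keep])
  lp <- stats::qlogis(pred)
  dat <- data.frame(y = outcome, lp = lp)
  fit <- mgcv::gam(y ~ s(lp), family = stats::binomial(), data = dat)
  grid_p <- seq(stats::quantile(pred, 0.005),
                stats::quantile(pred, 0.995), length.out = n_grid)
  nd <- data.frame(lp = stats::qlogis(grid_p))
  pr <- mgcv::predict.gam(fit, newdata = nd, type = "link", se.fit = TRUE)
  tibble::tibble(
    predicted = grid_p,
    observed = stats::plogis(pr$fit),
    conf.low = stats::plogis(pr$fit - 1.96 * pr$se.fit),
    conf.high = stats::plogis(pr$fit + 1.96 * pr$se.fit)
  )
}

#' Full performance report
#'
#' Discrimination (AUROC with DeLong CI), overall accuracy (Brier),
#' calibration (slope, intercept, Hosmer--Lemeshow, smoothed curve) and the
#' risk decile table for one prediction vector.
#'
#' @param pred Probabilities.
#' @param outcome Binary outcome vector; records with missing outcome or
#'   missing prediction are excluded.
#' @param curve Also fit the GAM calibration curve. Default `TRUE`.
#' @return An object of class `champ_performance`. [glance()] returns the
#'   headline metrics as one row; [autoplot()] draws the calibration curve.
#' @export
performance_report <- function(pred, outcome, curve = TRUE) {
  keep <- !is.na(pred) & !is.na(outcome)
  pred <- pred[keep]
  outcome <- as.numeric(outcome[keep])
  structure(
    list(
      n = length(pred),
      prevalence = mean(outcome),
      auroc = auroc(pred, outcome),
      brier = brier_score(pred, outcome),
      calibration = calibration_fit(pred, outcome),
      hosmer_lemeshow = hosmer_lemeshow(pred, outcome),
      deciles = decile_table(pred, outcome),
      curve = if (curve) calibration_curve(pred, outcome)
    ),
    class = "champ_performance"
  )
}

#' @export
print.champ_performance <- function(x, ...) {
  cat("Performance report (n = ", x$n, ", event rate ",
      sprintf("%.1f%%", 100 * x$prevalence), ")\n", sep = "")
  cat(sprintf("  AUROC     %.3f (%.3f to %.3f)\n", x$auroc$estimate,
              x$auroc$conf.low, x$auroc$conf.high))
  cat(sprintf("  Brier     %.3f\n", x$brier))
  sl <- x$calibration[x$calibration$term == "slope", ]
  ic <- x$calibration[x$calibration$term == "intercept", ]
  cat(sprintf("  Slope     %.3f (%.3f to %.3f)\n", sl$estimate,
              sl$conf.low, sl$conf.high))
  cat(sprintf("  Intercept %.3f (%.3f to %.3f)\n", ic$estimate,
              ic$conf.low, ic$conf.high))
  cat(sprintf("  Hosmer-Lemeshow chi2 = %.1f on %d df (p = %.3g)\n",
              x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
              x$hosmer_lemeshow$p.value))
  invisible(x)
}

#' @rdname performance_report
#' @param x A `champ_performance`.
#' @param ... Unused.
#' @method glance champ_performance
#' @export
glance.champ_performance <- function(x, ...) {
  sl <- x$calibration[x$calibration$term == "slope", ]
  ic <- x$calibration[x$calibration$term == "intercept", ]
  tibble::tibble(
    n = x$n, prevalence = x$prevalence,
    auroc = x$auroc$estimate, auroc.conf.low = x$auroc$conf.low,
    auroc.conf.high = x$auroc$conf.high,
    brier = x$brier,
    slope = sl$estimate, slope.conf.low = sl$conf.low,
    slope.conf.high = sl$conf.high,
    intercept = ic$estimate, intercept.conf.low = ic$conf.low,
    intercept.conf.high = ic$conf.high,
    hl_statistic = x$hosmer_lemeshow$statistic,
    hl_df = x$hosmer_lemeshow$df, hl_p = x$hosmer_lemeshow$p.value
  )
}

#' @rdname performance_report
#' @param object A `champ_performance`.
#' @method autoplot champ_performance
#' @export
autoplot.champ_performance <- function(object, ...) {
  if (is.null(object$curve)) {
    stop("report was built with curve = FALSE", call. = FALSE)
  }
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$predicted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(data = object$deciles,
                        ggplot2::aes(x = .data$mean_predicted,
                                     y = .data$observed_rate)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted 30-day mortality",
                  y = "Observed 30-day mortality",
                  title = "Calibration") +
    ggplot2::theme_minimal()
}

#' Predictor effect curve
#'
#' Predicted probability of death along a grid of one continuous predictor,
#' with the remaining covariates held at reference values (medians for
#' continuous variables, modes for categories), exposing the fitted spline
#' nonlinearity. The pointwise CI uses the delta method on the linear
#' predictor.
#'
#' @param fit A `champ_fit` carrying its transform (e.g. from
#'   [fit_pooled()] or an ensemble model).
#' @param data Model-variable tibble supplying the reference values.
#' @param variable Continuous predictor to vary.
#' @param n_grid Grid size. Default 100.
#' @return Tibble with `value`, `p`, `conf.low`, `conf.high`.
#' @export
predictor_effect_curve <- function(fit, data, variable, n_grid = 100) {
  stopifnot(inherits(fit, "champ_fit"), !is.null(fit$transform))
  subset <- if (is.null(fit$subset)) fit$transform$retained else fit$subset
  if (!variable %in% subset || !variable %in% names(fit$transform$knots)) {
    stop("'", variable, "' is not a continuous predictor of this model",
         call. = FALSE)
  }
  ref <- lapply(subset, function(v) {
    x <- stats::na.omit(data[[v]])
    if (is.character(x)) {
      names(sort(table(x), decreasing = TRUE))[1]
    } else {
      stats::median(x)
    }
  })
  names(ref) <- subset
  grid <- seq(min(data[[variable]], na.rm = TRUE),
              max(data[[variable]], na.rm = TRUE), length.out = n_grid)
  nd <- tibble::as_tibble(ref)[rep(1, n_grid), ]
  nd[[variable]] <- grid
  xx <- build_design(nd, fit$transform, subset)
  xx <- xx[, names(fit$coefficients), drop = FALSE]
  eta <- drop(xx %*% fit$coefficients)
  se <- sqrt(rowSums((xx %*% fit$vcov) * xx))
  tibble::tibble(
    value = grid, p = stats::plogis(eta),
    conf.low = stats::plogis(eta - 1.96 * se),
    conf.high = stats::plogis(eta + 1.96 * se)
  )
}
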