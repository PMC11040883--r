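test_that("AUROC matches pair counting and behaves at the extremes", {
  set.seed(11)
  y <- rbinom(40, 1, 0.4)
  y[1] <- 1; y[2] <- 0
  p <- round(runif(40), 1) # coarse grid forces ties
  a <- auroc(p, y)
  expect_equal(a$estimate, oracle_auroc(p, y), tolerance = 1e-12)
  # perfect separation and constant predictions
  expect_equal(auroc(y, y)$estimate, 1)
  expect_equal(auroc(rep(0.3, 40), y)$estimate, 0.5)
  expect_error(auroc(p, rep(1, 40)), "both outcome classes")
  # invariance under a strictly increasing transform
  expect_equal(auroc(qlogis(pmin(pmax(p, 0.01), 0.99)), y)$estimate,
               auroc(pmin(pmax(p, 0.01), 0.99), y)$estimate)
})

test_that("AUROC and DeLong interval agree with the reference package", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(300, 1, 0.3)
  p <- plogis(rnorm(300) + y)
  a <- auroc(p, y)
  ref <- pROC::roc(y, p, quiet = TRUE, direction = "<")
  expect_equal(a$estimate, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(a$conf.low, ci[1], tolerance = 1e-6)
  expect_equal(a$conf.high, ci[3], tolerance = 1e-6)
})

test_that("Brier score reduces to hand arithmetic", {
  expect_equal(brier_score(c(0.2, 0.8, 0.6, 0.1), c(0, 1, 1, 0)), 0.0625)
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.25)
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("calibration regression recovers known distortions", {
  set.seed(13)
  n <- 40000
  eta <- rnorm(n, -1, 1.3)
  y <- rbinom(n, 1, plogis(eta))
  # predictions formed by doubling the true log-odds: slope near 0.5
  half <- calibration_fit(plogis(2 * eta), y)
  expect_lt(abs(half$estimate[half$term == "slope"] - 0.5), 0.03)
  # shifting the log-odds by +0.5: calibration-in-the-large near -0.5
  shift <- calibration_fit(plogis(eta + 0.5), y)
  expect_lt(abs(shift$estimate[shift$term == "intercept"] + 0.5), 0.04)
  # well-calibrated predictions: slope 1, intercept 0
  ok <- calibration_fit(plogis(eta), y)
  expect_lt(abs(ok$estimate[ok$term == "slope"] - 1), 0.05)
  expect_lt(abs(ok$estimate[ok$term == "intercept"]), 0.05)
  w <- capture_warnings(calibration_fit(c(0, 0.5, 1), c(0, 1, 1)))
  expect_true(any(grepl("clamped", w)))
})

test_that("Hosmer-Lemeshow matches a hand-built decile table", {
  set.seed(14)
  n <- 200
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  hl <- hosmer_lemeshow(p, y, groups = 10)
  # independent decile-table chi-square
  br <- unique(quantile(p, seq(0, 1, 0.1)))
  g <- cut(p, br, include.lowest = TRUE, labels = FALSE)
  stat <- 0
  for (gg in unique(g)) {
    idx <- g == gg
    o1 <- sum(y[idx]); e1 <- sum(p[idx])
    o0 <- sum(idx) - o1; e0 <- sum(idx) - e1
    stat <- stat + (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
  }
  expect_equal(hl$statistic, stat, tolerance = 1e-10)
  expect_equal(hl$df, 8)
  expect_true(hl$p.value >= 0 && hl$p.value <= 1)
})

test_that("Hosmer-Lemeshow detects systematic overconfidence", {
  set.seed(15)
  n <- 30000
  eta <- rnorm(n, -0.8, 1)
  y <- rbinom(n, 1, plogis(eta))
  over <- plogis(2 * eta) # overconfident by construction
  expect_lt(hosmer_lemeshow(over, y)$p.value, 0.001)
  # near-calibrated predictions give a statistic near its df
  ok <- hosmer_lemeshow(plogis(eta), y)
  expect_lt(ok$statistic, 5 * ok$df)
})

test_that("the calibration curve bends the right way", {
  set.seed(16)
  n <- 30000
  eta <- rnorm(n, -0.8, 1)
  y <- rbinom(n, 1, plogis(eta))
  cc <- calibration_curve(plogis(eta), y)
  expect_true(all(cc$observed >= 0 & cc$observed <= 1))
  expect_lt(max(abs(cc$observed - cc$predicted)), 0.08)
  # under halved true log-odds (slope-0.5 construction) the curve sits
  # above the diagonal for low predictions, below for high
  cc2 <- calibration_curve(plogis(2 * eta), y)
  lo <- cc2$predicted < 0.15
  hi <- cc2$predicted > 0.85
  expect_true(mean(cc2$observed[lo] > cc2$predicted[lo]) > 0.9)
  if (any(hi)) {
    expect_true(mean(cc2$observed[hi] < cc2$predicted[hi]) > 0.9)
  }
})

test_that("predictor effect curves expose the fitted nonlinearity", {
  # simulate a true U-shaped systolic blood pressure effect
  set.seed(17)
  n <- 12000
  co <- make_toy_cohort(n)
  eta <- -1.5 + 0.0005 * (co$sbp - 135)^2
  co$outcome <- rbinom(n, 1, plogis(eta))
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr <- fit_transform(rows, scr)
  fit <- fit_pooled(list(rows), tr, subset = c("sbp", "sex"))
  curve <- predictor_effect_curve(fit, rows, "sbp")
  i_min <- which.min(curve$p)
  expect_gt(curve$value[i_min], quantile(co$sbp, 0.1))
  expect_lt(curve$value[i_min], quantile(co$sbp, 0.9))
  # outside the winsorization limits the curve is flat (clamped input)
  wide <- rows[rep(1, 50), ]
  wide$sbp <- seq(250, 400, length.out = 50) # all beyond the upper limit
  pw <- champr:::predict_fit(fit, wide)
  expect_lt(diff(range(pw)), 1e-12)
  expect_error(predictor_effect_curve(fit, rows, "gcs"), "not a continuous")
})

test_that("performance report glances into one tidy row", {
  set.seed(18)
  n <- 3000
  eta <- rnorm(n, -0.8, 1)
  y <- rbinom(n, 1, plogis(eta))
  rep_ <- performance_report(plogis(eta), y)
  g <- glance(rep_)
  expect_equal(nrow(g), 1)
  expect_true(all(c("auroc", "brier", "slope", "intercept", "hl_p")
                  %in% names(g)))
  expect_equal(sum(rep_$deciles$n), n)
  plt <- ggplot2::autoplot(rep_)
  expect_s3_class(plt, "ggplot")
})
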