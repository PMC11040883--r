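test_that("intercept-only fit at 50% prevalence recovers logit(0.5) = 0", {
  x <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(x, y)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-10)
  # fitted probabilities average to the prevalence (score equation)
  expect_equal(mean(fit$fitted), 0.5, tolerance = 1e-10)
})

test_that("single binary predictor matches the 2x2 closed form", {
  a <- 37; b <- 21; c <- 43; d <- 59
  dat <- expand_2x2(a, b, c, d)
  x <- cbind(`(Intercept)` = 1, exposed = dat$exposed)
  fit <- fit_logistic(x, dat$outcome)
  expect_equal(unname(coef(fit)["exposed"]), log((a * d) / (b * c)),
               tolerance = 1e-8)
  # Woolf variance oracle for the CI
  se_oracle <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  or <- odds_ratios(fit, "exposed")
  expect_equal(or$conf.low,
               exp(log((a * d) / (b * c)) - qnorm(0.975) * se_oracle),
               tolerance = 1e-6)
  expect_equal(or$conf.high,
               exp(log((a * d) / (b * c)) + qnorm(0.975) * se_oracle),
               tolerance = 1e-6)
})

test_that("coefficients agree with the reference IRLS implementation", {
  set.seed(8)
  n <- 500
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(x) <- c("(Intercept)", "z", "b")
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, 2] - 0.4 * x[, 3]))
  fit <- fit_logistic(x, y)
  ref <- suppressWarnings(glm.fit(x, y, family = binomial()))
  expect_equal(unname(coef(fit)), unname(ref$coefficients),
               tolerance = 1e-7)
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  expect_true(fit$converged)
})

test_that("separation and rank deficiency raise distinct errors", {
  x <- cbind(`(Intercept)` = 1, z = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(x, y), "separation")
  x2 <- cbind(`(Intercept)` = 1, a = rnorm(30), a2 = 0)
  x2 <- cbind(x2, dup = x2[, "a"])
  expect_error(fit_logistic(x2, rbinom(30, 1, 0.5)), "collinear")
  expect_error(fit_logistic(cbind(1, rnorm(30)), rep(1, 30)), "both classes")
})

test_that("Wald blocks reduce to (b/se)^2 and match a dense oracle", {
  set.seed(9)
  n <- 800
  x <- cbind(1, matrix(rnorm(n * 4), n, 4))
  colnames(x) <- c("(Intercept)", paste0("v", 1:4))
  y <- rbinom(n, 1, plogis(0.3 * x[, 2] - 0.2 * x[, 4]))
  fit <- fit_logistic(x, y)
  w1 <- wald_test(fit, "v1")
  se <- sqrt(diag(vcov(fit))["v1"])
  expect_equal(w1$statistic, unname((coef(fit)["v1"] / se)^2),
               tolerance = 1e-10)
  expect_equal(w1$df, 1)
  blk <- c("v1", "v2", "v3")
  wb <- wald_test(fit, blk)
  bvec <- coef(fit)[blk]
  vinv <- solve(vcov(fit)[blk, blk])
  expect_equal(wb$statistic, drop(t(bvec) %*% vinv %*% bvec),
               tolerance = 1e-10)
  expect_equal(wb$df, 3)
  expect_error(wald_test(fit, "nope"), "not in model")
})

test_that("spline variables carry k-1 Wald degrees of freedom", {
  co <- make_toy_cohort(800)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr <- fit_transform(rows, scr)
  fit <- fit_pooled(list(rows), tr)
  wt <- wald_table(fit, tr)
  expect_equal(wt$df[wt$variable == "age"], 3)
  expect_equal(wt$df[wt$variable == "gcs"], 2)
  expect_equal(wt$df[wt$variable == "rhythm_binary"], 1)
  expect_equal(sum(wt$df), 29)
})

test_that("Rubin pooling matches hand arithmetic", {
  # degenerate stack: no between-imputation variance
  p0 <- pool_rubin(rep(0.7, 5), rep(0.01, 5))
  expect_equal(p0$estimate, 0.7)
  expect_equal(p0$between, 0)
  expect_equal(p0$variance, 0.01)
  # hand evaluation: W = 0.5, B = 1, total = 0.5 + (1 + 1/3) * 1
  p1 <- pool_rubin(c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_equal(p1$estimate, 2)
  expect_equal(p1$variance, 0.5 + (1 + 1 / 3) * 1, tolerance = 1e-12)
  # total variance grows monotonically with between-imputation spread
  spread <- sapply(c(0.1, 0.5, 1, 2), function(s) {
    pool_rubin(c(2 - s, 2, 2 + s), c(0.5, 0.5, 0.5))$variance
  })
  expect_true(all(diff(spread) > 0))
  expect_error(pool_rubin(1:3, 1:2), "length")
  expect_error(pool_rubin(1:3, c(1, -1, 1)), "negative")
  expect_warning(pool_rubin(1, 0.2), "single imputation")
})

test_that("pooling identical datasets equals the single fit", {
  co <- make_toy_cohort(500)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr <- fit_transform(rows, scr)
  single <- fit_pooled(list(rows), tr)
  pooled <- fit_pooled(list(rows, rows, rows), tr)
  expect_equal(coef(pooled), coef(single), tolerance = 1e-10)
  expect_equal(unname(vcov(pooled)), unname(vcov(single)),
               tolerance = 1e-10)
  expect_equal(pooled$m, 3)
})

test_that("null effects give odds ratios at one", {
  fit <- structure(
    list(coefficients = c(`(Intercept)` = 0.2, z = 0),
         vcov = diag(c(0.01, 0.04)), n = 10, m = 1L,
         converged = TRUE, subset = NULL, transform = NULL),
    class = "champ_fit"
  )
  dimnames(fit$vcov) <- list(names(fit$coefficients),
                             names(fit$coefficients))
  or <- odds_ratios(fit, "z")
  expect_equal(or$estimate, 1)
  expect_true(or$conf.low < 1 && or$conf.high > 1)
  fit$coefficients["z"] <- log(2)
  fit$vcov["z", "z"] <- 0
  or2 <- odds_ratios(fit, "z")
  expect_equal(or2$estimate, 2)
  expect_equal(or2$conf.low, 2)
  expect_equal(or2$conf.high, 2)
})
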