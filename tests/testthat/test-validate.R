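test_that("the sensitivity filter removes exactly one category", {
  co <- make_toy_cohort(1000)
  co$category <- sample(c(rep("cardiac_arrest", 3), rep("trauma", 7)),
                        1000, replace = TRUE)
  filt <- sensitivity_filter(co, "cardiac_arrest")
  expect_equal(nrow(filt), sum(co$category != "cardiac_arrest"))
  expect_false(any(filt$category == "cardiac_arrest"))
  expect_equal(attr(filt, "sensitivity"), "cardiac_arrest")
  expect_warning(out <- sensitivity_filter(co, "not_a_code"),
                 "not present")
  expect_equal(nrow(out), nrow(co))
  expect_error(sensitivity_filter(co[, "age"]), "category")
})

test_that("optimism correction is plain subtraction on the metric scale", {
  expect_equal(correct_optimism(0.932, 0.011), 0.921)
  expect_equal(correct_optimism(0.091, -0.006), 0.097)
  expect_equal(correct_optimism(0.5, 0), 0.5)
})

test_that("noise predictors produce positive AUROC optimism", {
  set.seed(20)
  n <- 400
  k <- 10
  noise <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(noise) <- paste0("x", 1:k)
  dat <- tibble::as_tibble(noise)
  dat$outcome <- rbinom(n, 1, 0.35)
  builder <- function(d) {
    fit_logistic(cbind(`(Intercept)` = 1, as.matrix(d[, paste0("x", 1:k)])),
                 d$outcome)
  }
  scorer <- function(fit, d) {
    plogis(drop(cbind(1, as.matrix(d[, paste0("x", 1:k)])) %*%
                  fit$coefficients))
  }
  rep_ <- estimate_optimism(dat, builder, scorer, n_sets = 1, n_boot = 30,
                            seed = 3, metrics = "auroc")
  expect_gt(rep_$optimism[1], 0)
  expect_lte(rep_$corrected[1], rep_$apparent[1])
  # corrected = apparent - optimism for every metric reported
  expect_equal(rep_$corrected, rep_$apparent - rep_$optimism)
})

test_that("an intercept-only pipeline has nothing to overfit", {
  set.seed(21)
  dat <- tibble::tibble(outcome = rbinom(300, 1, 0.3))
  builder <- function(d) mean(d$outcome)
  scorer <- function(m, d) {
    # constant prediction plus a fixed tie-breaking jitter so AUROC is
    # defined; the jitter is independent of the outcome
    rep(m, nrow(d)) + seq_len(nrow(d)) * 1e-9
  }
  rep_ <- estimate_optimism(dat, builder, scorer, n_sets = 1, n_boot = 25,
                            seed = 4, metrics = "brier")
  expect_lt(abs(rep_$optimism[1]), 0.01)
})

test_that("validation runs are reproducible under a fixed seed", {
  set.seed(22)
  n <- 200
  dat <- tibble::tibble(x = rnorm(n))
  dat$outcome <- rbinom(n, 1, plogis(dat$x))
  builder <- function(d) {
    fit_logistic(cbind(1, x = d$x), d$outcome)
  }
  scorer <- function(fit, d) plogis(drop(cbind(1, d$x) %*% fit$coefficients))
  r1 <- estimate_optimism(dat, builder, scorer, n_sets = 1, n_boot = 20,
                          seed = 9, metrics = c("auroc", "brier"))
  r2 <- estimate_optimism(dat, builder, scorer, n_sets = 1, n_boot = 20,
                          seed = 9, metrics = c("auroc", "brier"))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("incomplete cohorts are imputed into the requested sets", {
  sim <- generate_cohort(default_fhdb_config(n = 500, seed = 41))
  co <- derive_model_variables(sim$observed, default_screening())
  co <- co[, c("age", "sbp", "outcome")]
  co <- co[!is.na(co$outcome), ]
  builder <- function(d) fit_logistic(cbind(1, d$age, d$sbp), d$outcome)
  scorer <- function(fit, d) {
    plogis(drop(cbind(1, d$age, d$sbp) %*% fit$coefficients))
  }
  rep_ <- estimate_optimism(co, builder, scorer, n_sets = 2, n_boot = 5,
                            seed = 10, metrics = "brier",
                            impute_args = list(maxit = 2))
  expect_s3_class(rep_, "champ_optimism")
  expect_equal(attr(rep_, "n_sets"), 2)
})
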