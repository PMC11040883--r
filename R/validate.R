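#' Exclude one patient category (sensitivity analysis)
#'
#' Returns the sub-cohort without the excluded dispatch category (cardiac
#' arrest by default), leaving everything else untouched so the downstream
#' pipeline can be re-run unchanged on the filtered cohort.
#'
#' @param data Cohort tibble with a `category` column.
#' @param excluded_category Level to remove. Default `"cardiac_arrest"`.
#' @return Filtered tibble with attribute `"sensitivity"` naming the
#'   excluded category.
#' @export
sensitivity_filter <- function(data, excluded_category = "cardiac_arrest") {
  if (!"category" %in% names(data)) {
    stop("cohort has no 'category' column", call. = FALSE)
  }
  if (!excluded_category %in% data$category) {
    warning("category '", excluded_category,
            "' not present; returning the cohort unchanged", call. = FALSE)
    out <- data
  } else {
    out <- data[is.na(data$category) | data$category != excluded_category, ]
  }
  attr(out, "sensitivity") <- excluded_category
  out
}

#' Optimism-correct a performance estimate
#'
#' `corrected = apparent - optimism`, the standard bootstrap correction.
#'
#' @param apparent Apparent (resubstitution) value of a metric.
#' @param optimism Estimated optimism of the same metric on the same scale.
#' @return Corrected value.
#' @export
correct_optimism <- function(apparent, optimism) {
  apparent - optimism
}

metric_value <- function(metric, pred, outcome) {
  switch(metric,
    auroc = auroc(pred, outcome)$estimate,
    brier = brier_score(pred, outcome),
    slope = calibration_fit(pred, outcome)$estimate[1],
    intercept = calibration_fit(pred, outcome)$estimate[2],
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Bootstrap optimism on multiply imputed data
#'
#' Internal validation in the impute-then-bootstrap style: the cohort is
#' completed into `n_sets` imputed datasets; within each, `n_boot`
#' bootstrap resamples are drawn, the whole model-building procedure
#' (`builder`) is repeated on every resample, and the optimism contribution
#' is the resample (training) performance minus the performance of the
#' resample-trained model on the source dataset. Per-set means are pooled
#' across sets; `corrected = apparent - pooled optimism`. Everything the
#' builder estimates from data (knots, winsorization limits, coefficients)
#' is refit inside every resample.
#'
#' @param data Cohort tibble (may contain missing cells).
#' @param builder Function `function(data)` returning a fitted object.
#'   Default: a full submodel-ensemble build via [champ_builder()].
#' @param scorer Function `function(object, data)` returning a probability
#'   per row. Default matches the default builder.
#' @param n_sets Number of imputed sets. Default 4.
#' @param n_boot Bootstrap resamples per set. Default 250.
#' @param seed Integer seed. Default 1.
#' @param metrics Metrics to validate, a subset of
#'   `c("auroc", "brier", "slope", "intercept")`.
#' @param impute_args List of arguments passed to [impute_cohort()]
#'   (besides `data`, `m` and `seed`).
#' @param max_skip_fraction Abort if more than this fraction of inner
#'   refits fail. Default 0.05.
#' @return An object of class `champ_optimism`: a tibble with one row per
#'   metric (`apparent`, `optimism`, `optimism.conf.low/high`,
#'   `corrected`, `corrected.conf.low/high`) plus provenance attributes.
#' @export
estimate_optimism <- function(data, builder = NULL, scorer = NULL,
                              n_sets = 4, n_boot = 250, seed = 1,
                              metrics = c("auroc", "brier", "slope",
                                          "intercept"),
                              impute_args = list(),
                              max_skip_fraction = 0.05) {
  stopifnot(n_sets >= 1, n_boot >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(builder)) {
    bs <- champ_builder()
    builder <- bs$builder
    scorer <- bs$scorer
  }
  if (is.null(scorer)) stop("scorer must accompany builder", call. = FALSE)

  if (anyNA(data[, setdiff(names(data), "outcome"), drop = FALSE]) ||
      anyNA(data$outcome)) {
    imp <- do.call(impute_cohort,
                   c(list(data = data, m = n_sets, seed = seed),
                     impute_args))
    sets <- complete_datasets(imp)
  } else {
    sets <- replicate(n_sets, data, simplify = FALSE)
  }

  n_fail <- 0
  n_total <- 0
  apparent <- matrix(NA_real_, n_sets, length(metrics),
                     dimnames = list(NULL, metrics))
  opt_mean <- matrix(NA_real_, n_sets, length(metrics),
                     dimnames = list(NULL, metrics))
  opt_var <- matrix(NA_real_, n_sets, length(metrics),
                    dimnames = list(NULL, metrics))

  for (s in seq_len(n_sets)) {
    d <- sets[[s]]
    model0 <- builder(d)
    p0 <- scorer(model0, d)
    for (mt in metrics) apparent[s, mt] <- metric_value(mt, p0, d$outcome)
    opt <- matrix(NA_real_, n_boot, length(metrics),
                  dimnames = list(NULL, metrics))
    for (b in seq_len(n_boot)) {
      n_total <- n_total + 1
      res <- with_substream(seed, paste0("boot", s, "_", b), {
        idx <- sample.int(nrow(d), replace = TRUE)
        db <- d[idx, , drop = FALSE]
        tryCatch({
          mb <- builder(db)
          list(train = scorer(mb, db), test = scorer(mb, d), data = db)
        }, error = function(e) NULL)
      })
      if (is.null(res)) {
        n_fail <- n_fail + 1
        next
      }
      for (mt in metrics) {
        tr <- tryCatch(metric_value(mt, res$train, res$data$outcome),
                       error = function(e) NA_real_)
        te <- tryCatch(metric_value(mt, res$test, d$outcome),
                       error = function(e) NA_real_)
        opt[b, mt] <- tr - te
      }
    }
    if (n_fail / n_total > max_skip_fraction) {
      stop("more than ", 100 * max_skip_fraction,
           "% of bootstrap refits failed", call. = FALSE)
    }
    for (mt in metrics) {
      v <- stats::na.omit(opt[, mt])
      opt_mean[s, mt] <- mean(v)
      opt_var[s, mt] <- stats::var(v) / length(v)
    }
  }

  rows <- lapply(metrics, function(mt) {
    pooled <- if (n_sets == 1) {
      tibble::tibble(estimate = opt_mean[1, mt],
                     variance = opt_var[1, mt])
    } else {
      suppressWarnings(pool_rubin(opt_mean[, mt], opt_var[, mt]))
    }
    ap <- mean(apparent[, mt])
    se <- sqrt(pooled$variance)
    tibble::tibble(
      metric = mt,
      apparent = ap,
      optimism = pooled$estimate,
      optimism.conf.low = pooled$estimate - 1.96 * se,
      optimism.conf.high = pooled$estimate + 1.96 * se,
      corrected = correct_optimism(ap, pooled$estimate),
      corrected.conf.low = correct_optimism(ap, pooled$estimate) -
        1.96 * se,
      corrected.conf.high = correct_optimism(ap, pooled$estimate) +
        1.96 * se
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("champ_optimism", class(out)),
            n_sets = n_sets, n_boot = n_boot, seed = seed,
            n_failed = n_fail)
}

#' @export
print.champ_optimism <- function(x, ...) {
  cat("Internal validation (", attr(x, "n_sets"), " imputed set(s) x ",
      attr(x, "n_boot"), " bootstrap(s))\n", sep = "")
  cat(sprintf("  %-10s %9s %9s %9s\n", "metric", "apparent", "optimism",
              "corrected"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s %9.3f %9.3f %9.3f\n", x$metric[i], x$apparent[i],
                x$optimism[i], x$corrected[i]))
  }
  invisible(x)
}

#' Default ensemble builder/scorer pair for internal validation
#'
#' Wraps the full development procedure — screening structure, frozen
#' transform estimation and the pattern-submodel ensemble — as a
#' `builder(data)` / `scorer(object, data)` pair for
#' [estimate_optimism()]. The builder refits everything (knots, limits,
#' coefficients) on whatever data it receives.
#'
#' @param screening A `champ_screening`; default [default_screening()].
#' @param droppable Droppable set; default [champ_droppable()].
#' @param config A `champ_transform_config`.
#' @return List with elements `builder` and `scorer`.
#' @export
champ_builder <- function(screening = default_screening(),
                          droppable = champ_droppable(),
                          config = transform_config()) {
  list(
    builder = function(data) {
      rows <- if (!all(screening$retained %in% names(data))) {
        derive_model_variables(data, screening)
      } else {
        data
      }
      build_ensemble(list(rows), screening, config, droppable)
    },
    scorer = function(object, data) {
      rows <- if (!all(screening$retained %in% names(data))) {
        derive_model_variables(data, screening)
      } else {
        data
      }
      predict(object, rows, on_unscorable = "na")$p
    }
  )
}
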