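#' End-to-end model development
#'
#' Runs the full development pipeline on a raw cohort: predictor screening,
#' chained-equations imputation (skipped with a message when the cohort is
#' complete), ensemble building over the droppable-variable subsets, and
#' apparent performance of the availability-selecting algorithm on the
#' original non-imputed cohort (records missing the outcome or a
#' non-droppable predictor are excluded from the metrics and reported as
#' rejects).
#'
#' @param data Raw cohort tibble (see [read_cohort()]).
#' @param m Number of completed datasets. Default 30.
#' @param maxit Imputation sweeps per dataset. Default 10.
#' @param seed Integer seed. Default 1.
#' @param screening_args List of arguments for [screen_variables()].
#' @param transform Config from [transform_config()].
#' @param droppable Droppable predictor set. Default [champ_droppable()].
#' @param impute_args Extra arguments for [impute_cohort()].
#' @param curve Fit the GAM calibration curve in the report. Default
#'   `TRUE`.
#' @return An object of class `champ_development`: `screening`, `imputed`,
#'   `ensemble`, `performance` (a `champ_performance`), `scores` (per-record
#'   tibble with masks and probabilities) and `rejects`.
#' @export
champ_develop <- function(data, m = 30, maxit = 10, seed = 1,
                          screening_args = list(),
                          transform = transform_config(),
                          droppable = champ_droppable(),
                          impute_args = list(), curve = TRUE) {
  screening <- do.call(screen_variables, c(list(data = data),
                                           screening_args))
  rows <- derive_model_variables(data, screening)
  if (anyNA(rows)) {
    imputed <- do.call(impute_cohort,
                       c(list(data = rows, m = m, maxit = maxit,
                              seed = seed), impute_args))
  } else {
    message("cohort is complete: imputation skipped")
    imputed <- impute_cohort(rows, m = 1, maxit = 1, seed = seed)
  }
  ensemble <- build_ensemble(imputed, screening, transform, droppable)
  scores <- predict(ensemble, rows, on_unscorable = "na")
  scores$outcome <- rows$outcome
  usable <- !is.na(scores$p) & !is.na(scores$outcome)
  performance <- performance_report(scores$p[usable],
                                    scores$outcome[usable], curve = curve)
  structure(
    list(screening = screening, imputed = imputed, ensemble = ensemble,
         performance = performance, scores = scores,
         rejects = scores[!is.na(scores$reason), ],
         seed = seed),
    class = "champ_development"
  )
}

#' @export
print.champ_development <- function(x, ...) {
  print(x$screening)
  print(x$ensemble)
  print(x$performance)
  if (nrow(x$rejects) > 0) {
    cat("  rejects: ", nrow(x$rejects), " unscorable record(s)\n",
        sep = "")
  }
  invisible(x)
}

#' Score a cohort with a fitted ensemble
#'
#' Batch scoring: derives model variables, selects the submodel matching
#' each record's availability pattern and returns per-record probabilities.
#' Records missing a non-droppable predictor are returned with a missing
#' probability and a reject reason instead of an error.
#'
#' @param ensemble A `champ_ensemble` (fitted or imported from a registry).
#' @param data Raw cohort tibble.
#' @param screening Screening used to derive model variables; defaults to
#'   the ensemble's own.
#' @return Tibble with `.row`, `mask`, `p`, `reason`.
#' @export
champ_score <- function(ensemble, data, screening = NULL) {
  stopifnot(inherits(ensemble, "champ_ensemble"))
  if (is.null(screening)) screening <- ensemble$screening
  rows <- if (!all(screening$retained %in% names(data))) {
    derive_model_variables(data, screening)
  } else {
    tibble::as_tibble(data)
  }
  predict(ensemble, rows, on_unscorable = "na")
}
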