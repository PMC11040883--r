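#' Candidate predictor variables for HEMS mortality modelling
#'
#' Metadata for the 14 candidate predictors recorded per patient encounter,
#' plus the 30-day mortality outcome. Types drive cohort validation, the
#' screening rules, and the conditional models used during imputation.
#'
#' @return A tibble with one row per variable: `variable`, `type`
#'   (`"continuous"`, `"integer"`, `"binary"`, `"categorical"` or
#'   `"outcome"`), `lower`/`upper` hard bounds for numeric variables (NA when
#'   unbounded), and `levels` (list-column of legal levels for categorical
#'   variables).
#' @export
#' @examples
#' champ_variables()
champ_variables <- function() {
  tibble::tibble(
    variable = c(
      "age", "sex", "n_patients", "gcs", "vehicle", "rhythm_raw",
      "resp_rate", "sbp", "spo2", "heart_rate", "category",
      "time_to_hems", "time_to_ems", "facility", "outcome"
    ),
    type = c(
      "continuous", "categorical", "integer", "integer", "categorical",
      "categorical", "continuous", "continuous", "continuous", "continuous",
      "categorical", "continuous", "continuous", "binary", "outcome"
    ),
    lower = c(0, NA, 1, 3, NA, NA, 0, 0, 0, 0, NA, 0, 0, 0, 0),
    upper = c(NA, NA, NA, 15, NA, NA, NA, NA, 100, NA, NA, NA, NA, 1, 1),
    levels = list(
      NULL, champ_levels("sex"), NULL, NULL, champ_levels("vehicle"),
      champ_levels("rhythm_raw"), NULL, NULL, NULL, NULL,
      champ_levels("category"), NULL, NULL, NULL, NULL
    )
  )
}

#' Legal levels of a categorical cohort variable
#'
#' @param variable One of `"sex"`, `"vehicle"`, `"rhythm_raw"`, `"category"`.
#' @return Character vector of legal levels, in canonical order.
#' @export
champ_levels <- function(variable) {
  switch(variable,
    sex = c("female", "male"),
    vehicle = c("helicopter", "ground_unit"),
    rhythm_raw = c(
      "sinus", "sves_ves_mono", "aflut_afib_avblock_vespoly",
      "vf_vt_asystole_pea", "not_registered", "paced"
    ),
    category = c(
      "cardiac_arrest", "trauma", "respiratory_failure", "chest_pain",
      "stroke", "neurological_other", "psychiatric_intoxication",
      "gyn_obstetrics", "infection", "other"
    ),
    stop("unknown categorical variable: ", variable, call. = FALSE)
  )
}

# Five predictors with the most missing data: the ones the pattern-submodel
# ensemble is allowed to drop. Fixed order — registry masks are keyed by it.
#' Droppable predictors of the pattern-submodel ensemble
#'
#' The five predictors with the most missing data in pre-hospital records;
#' the ensemble contains one submodel for every subset of these. The order is
#' fixed and defines the bit order of ensemble mask keys.
#'
#' @return Character vector of length five.
#' @export
champ_droppable <- function() {
  c("sbp", "heart_rate", "spo2", "gcs", "rhythm_binary")
}

# Predictors required at scoring time regardless of the selected submodel.
champ_core_predictors <- function() {
  c("age", "sex", "vehicle", "facility", "time_to_hems", "category")
}

# Continuous model variables and their spline knot counts (GCS gets three
# knots and is exempt from winsorization; the rest get four).
champ_spline_spec <- function() {
  c(age = 4L, heart_rate = 4L, sbp = 4L, spo2 = 4L, time_to_hems = 4L,
    gcs = 3L)
}
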