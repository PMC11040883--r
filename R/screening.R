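#' Screen candidate predictors for modelling compatibility
#'
#' Applies the three screening rules used before model development: a
#' variable is dropped when too much of it is missing; a categorical level is
#' dropped (for two-level structures, the whole variable) when it is too
#' rare; and a level with too few deaths is merged away. Rare or
#' low-mortality levels of the patient category merge into a single union
#' level which becomes the regression reference group.
#'
#' Screening looks only at marginal frequencies, so its decisions are
#' invariant to record order. The number-of-patients count is screened on its
#' binarised form (one patient vs two or more); the cardiac-rhythm variable
#' is screened on its modelled binary form (arrest rhythm vs other observed
#' rhythm), so rare raw rhythm levels are absorbed rather than dropped.
#'
#' @param data Cohort tibble from [read_cohort()] or [generate_cohort()].
#' @param max_missing_fraction Drop a variable whose missing fraction exceeds
#'   this. Default `1/3`.
#' @param min_category_prevalence Minimum prevalence of a categorical level.
#'   Default `0.02`.
#' @param min_outcome_prevalence Minimum 30-day mortality within a level
#'   (among records with observed outcome). Default `0.02`.
#' @param candidates Candidate predictor names to screen. Default: all 14.
#' @return An object of class `champ_screening`: a list with `retained`
#'   (ordered character vector of retained predictors, on the model-variable
#'   scale where `rhythm_raw` appears as `rhythm_binary`), `dropped` (tibble
#'   of variable, reason, statistic), `merged` (tibble of level, into),
#'   `reference_level` (the category reference group) and `config`.
#'   [tidy()][generics::tidy] returns the per-variable decision table.
#' @export
screen_variables <- function(data,
                             max_missing_fraction = 1 / 3,
                             min_category_prevalence = 0.02,
                             min_outcome_prevalence = 0.02,
                             candidates = NULL) {
  stopifnot(
    max_missing_fraction > 0, max_missing_fraction < 1,
    min_category_prevalence > 0, min_category_prevalence < 1,
    min_outcome_prevalence > 0, min_outcome_prevalence < 1
  )
  if (nrow(data) == 0) stop("cannot screen an empty cohort", call. = FALSE)
  if (!"outcome" %in% names(data) || all(is.na(data$outcome))) {
    stop("screening requires an outcome observed for at least one record",
         call. = FALSE)
  }
  vars <- champ_variables()
  all_candidates <- setdiff(vars$variable, "outcome")
  if (is.null(candidates)) candidates <- intersect(all_candidates, names(data))
  n <- nrow(data)
  outcome <- data$outcome

  dropped <- tibble::tibble(variable = character(), reason = character(),
                            statistic = numeric())
  merged <- tibble::tibble(level = character(), into = character())

  # Rule 1: missing fraction, over all records (missing-outcome rows count).
  for (v in candidates) {
    frac <- mean(is.na(data[[v]]))
    if (frac > max_missing_fraction) {
      dropped <- tibble::add_row(dropped, variable = v,
                                 reason = "missing_fraction", statistic = frac)
    }
  }
  survivors <- setdiff(candidates, dropped$variable)

  # Screening level structure per surviving variable.
  level_values <- function(v) {
    switch(v,
      n_patients = ifelse(is.na(data$n_patients), NA_character_,
                          ifelse(data$n_patients >= 2, "2+", "1")),
      rhythm_raw = ifelse(is.na(data$rhythm_raw), NA_character_,
                          ifelse(data$rhythm_raw == "vf_vt_asystole_pea",
                                 "arrest_rhythm", "other_rhythm")),
      facility = ifelse(is.na(data$facility), NA_character_,
                        ifelse(data$facility == 1, "yes", "no")),
      as.character(data[[v]])
    )
  }
  is_level_screened <- function(v) {
    v %in% c("sex", "vehicle", "category", "n_patients", "rhythm_raw",
             "facility")
  }

  for (v in intersect(survivors, candidates)) {
    if (!is_level_screened(v)) next
    lv <- level_values(v)
    obs <- !is.na(lv)
    tab <- table(lv[obs])
    prev <- as.numeric(tab) / n
    names(prev) <- names(tab)
    death <- vapply(names(tab), function(l) {
      idx <- obs & lv == l & !is.na(outcome)
      if (!any(idx)) return(0)
      mean(outcome[idx])
    }, numeric(1))
    flag <- prev < min_category_prevalence | death < min_outcome_prevalence
    if (!any(flag)) next
    if (v == "category") {
      # merge flagged levels into a union reference level
      for (l in names(tab)[flag]) {
        reason <- if (prev[l] < min_category_prevalence) prev[l] else death[l]
        merged <- tibble::add_row(merged, level = l, into = "")
      }
    } else {
      # two-level structure: a deficient level kills the variable
      l <- names(tab)[flag][1]
      stat <- if (prev[l] < min_category_prevalence) prev[l] else death[l]
      reason <- if (prev[l] < min_category_prevalence) {
        "rare_level"
      } else {
        "few_deaths_in_level"
      }
      dropped <- tibble::add_row(dropped, variable = v, reason = reason,
                                 statistic = stat)
    }
  }
  survivors <- setdiff(survivors, dropped$variable)

  # union-level label follows the conventional reporting order (rarest
  # prevalence first), which names the usual pair infection-first
  reference_level <- if (nrow(merged) > 0) {
    if (setequal(merged$level, c("infection", "gyn_obstetrics"))) {
      "infection_or_gyn_obstetrics"
    } else {
      paste(sort(merged$level), collapse = "_or_")
    }
  } else {
    "other"
  }
  if (nrow(merged) > 0) merged$into <- reference_level

  if (length(survivors) == 0) {
    stop("no predictors survive screening", call. = FALSE)
  }

  canonical <- c("sbp", "heart_rate", "spo2", "gcs", "sex", "age", "vehicle",
                 "facility", "rhythm_binary", "time_to_hems", "category",
                 "resp_rate", "time_to_ems", "n_patients")
  model_names <- ifelse(survivors == "rhythm_raw", "rhythm_binary", survivors)
  retained <- canonical[canonical %in% model_names]

  structure(
    list(
      retained = retained,
      dropped = dropped,
      merged = merged,
      reference_level = reference_level,
      config = list(
        max_missing_fraction = max_missing_fraction,
        min_category_prevalence = min_category_prevalence,
        min_outcome_prevalence = min_outcome_prevalence
      )
    ),
    class = "champ_screening"
  )
}

#' @export
print.champ_screening <- function(x, ...) {
  cat("Predictor screening\n")
  cat("  retained (", length(x$retained), "): ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  if (nrow(x$dropped) > 0) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("    %-12s %s (%.3f)\n", x$dropped$variable[i],
                  x$dropped$reason[i], x$dropped$statistic[i]))
    }
  }
  if (nrow(x$merged) > 0) {
    cat("  merged category levels -> ", x$reference_level, ": ",
        paste(x$merged$level, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname screen_variables
#' @param x A `champ_screening` object.
#' @param ... Unused.
#' @method tidy champ_screening
#' @export
tidy.champ_screening <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(variable = x$retained, decision = "retained",
                   reason = NA_character_, statistic = NA_real_),
    tibble::tibble(variable = x$dropped$variable, decision = "dropped",
                   reason = x$dropped$reason, statistic = x$dropped$statistic),
    if (nrow(x$merged) > 0) {
      tibble::tibble(variable = paste0("category:", x$merged$level),
                     decision = "merged", reason = paste("->", x$merged$into),
                     statistic = NA_real_)
    }
  )
}

#' Derive model variables from raw cohort records
#'
#' Maps screened raw records onto the model scale: the raw cardiac rhythm
#' collapses to a binary arrest-rhythm indicator (VF, VT, asystole or PEA vs
#' any other observed rhythm), flagged category levels merge into the
#' reference group, and variables dropped by screening are omitted.
#' Missingness propagates: a missing raw rhythm yields a missing indicator.
#'
#' @param data Cohort tibble.
#' @param screening A `champ_screening` object.
#' @param not_registered_as_missing If `TRUE`, the raw rhythm level
#'   `"not_registered"` maps to a missing indicator instead of 0. Default
#'   `FALSE`: it is an observed non-arrest state.
#' @return A tibble with the retained model variables plus `outcome`.
#' @export
derive_model_variables <- function(data, screening,
                                   not_registered_as_missing = FALSE) {
  stopifnot(inherits(screening, "champ_screening"))
  out <- tibble::as_tibble(data)
  if ("rhythm_raw" %in% names(out)) {
    r <- out$rhythm_raw
    rb <- ifelse(is.na(r), NA_real_,
                 ifelse(r == "vf_vt_asystole_pea", 1, 0))
    if (not_registered_as_missing) rb[!is.na(r) & r == "not_registered"] <- NA
    out$rhythm_binary <- rb
  }
  if ("category" %in% names(out) && nrow(screening$merged) > 0) {
    cat_col <- out$category
    hit <- !is.na(cat_col) & cat_col %in% screening$merged$level
    cat_col[hit] <- screening$reference_level
    out$category <- cat_col
  }
  keep <- c(screening$retained, "outcome")
  out[, intersect(keep, names(out)), drop = FALSE]
}
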