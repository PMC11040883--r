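# Deterministic per-variable substreams: each draw family gets its own seed
# derived from the cohort seed and the stream name, so adding or removing a
# variable never perturbs the others.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, name))
  expr
}

# Piecewise-linear quantile sampler through (min, q25, q50, q75, max)
# anchors: reproduces the target median and IQR exactly in distribution.
sample_quantile_anchors <- function(n, anchors) {
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  stats::approx(c(0, 0.25, 0.5, 0.75, 1), anchors, xout = u,
                rule = 2)$y
}

anchor_row <- function(q50, q25, q75, floor, cap) {
  iqr <- q75 - q25
  c(max(floor, q25 - 1.5 * iqr), q25, q50, q75, min(cap, q75 + 1.5 * iqr))
}

#' Default cohort generator configuration
#'
#' A generator configuration calibrated to the published characteristics of
#' a national physician-staffed HEMS registry cohort (n = 30 186): per
#' outcome stratum (alive at 30 days, dead within 30 days, outcome missing)
#' it encodes continuous medians and IQRs as piecewise-quantile targets,
#' integer GCS distributions, categorical level frequencies, and per-variable
#' missingness rates with their strong outcome dependence (vital signs are
#' missing far more often among non-survivors). Under the default
#' `fixed_prevalence` mechanism the 30-day mortality among outcome-observed
#' records is 30.4% and the outcome is missing in 6.0% of records.
#'
#' @param n Cohort size. Default 30186.
#' @param seed Integer seed. Default 1.
#' @param outcome_mechanism `"fixed_prevalence"` (outcome drawn first,
#'   covariates drawn per stratum; emulates the registry's summary table) or
#'   `"from_true_model"` (covariates drawn from the stratum mixture, outcome
#'   drawn from a logistic model on the transformed design; for
#'   parameter-recovery studies).
#' @param true_model A list with elements `beta` (named coefficient vector
#'   on the design scale) and `transform` (a `champ_transform`); required
#'   when `outcome_mechanism = "from_true_model"`. Default
#'   [default_true_model()].
#' @param missingness Optional named list overriding per-variable missing
#'   probabilities; each element is a length-3 vector (alive, dead,
#'   outcome-missing strata) or a single number used for all strata. Use
#'   `0` to switch a variable's missingness off.
#' @return An object of class `champ_sim_config`.
#' @seealso [generate_cohort()]
#' @export
default_fhdb_config <- function(n = 30186, seed = 1,
                                outcome_mechanism = c("fixed_prevalence",
                                                      "from_true_model"),
                                true_model = NULL,
                                missingness = NULL) {
  outcome_mechanism <- match.arg(outcome_mechanism)
  strata <- c("alive", "dead", "mout")
  cont <- list(
    age = rbind(anchor_row(53.0, 33.4, 68.4, 16, 105),
                anchor_row(70.2, 60.0, 79.8, 16, 105),
                anchor_row(50.0, 30.0, 67.7, 16, 105)),
    heart_rate = rbind(anchor_row(90, 77, 108, 0, 250),
                       anchor_row(90, 70, 110, 0, 250),
                       anchor_row(90, 77, 105, 0, 250)),
    sbp = rbind(anchor_row(131, 113, 151, 0, 300),
                anchor_row(134, 103, 168, 0, 300),
                anchor_row(130, 112, 148, 0, 300)),
    resp_rate = rbind(anchor_row(16, 14, 20, 0, 80),
                      anchor_row(16, 12, 22, 0, 80),
                      anchor_row(16, 14, 20, 0, 80)),
    spo2 = rbind(anchor_row(97, 94, 99, 40, 100),
                 anchor_row(95, 89, 98, 40, 100),
                 anchor_row(97, 95, 99, 40, 100)),
    time_to_hems = rbind(anchor_row(19, 14, 29, 0, 240),
                         anchor_row(19, 14, 28, 0, 240),
                         anchor_row(19, 13, 28, 0, 240)),
    time_to_ems = rbind(anchor_row(11, 8, 16, 0, 240),
                        anchor_row(10, 7, 15, 0, 240),
                        anchor_row(11, 8, 18, 0, 240))
  )
  cont <- lapply(cont, function(m) {
    rownames(m) <- strata
    m
  })
  # Integer GCS pmfs over 3..15 per stratum, constructed to match the
  # published median [IQR]: 14 [7, 15] among survivors, 3 [3, 3] among
  # deaths.
  gcs_alive <- c(0.15, 0.02, 0.03, 0.04, 0.05, 0.03, 0.03, 0.03, 0.03,
                 0.03, 0.05, 0.21, 0.30)
  gcs_dead <- c(0.78, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01,
                0.01, 0.02, 0.04, 0.06)
  gcs <- rbind(alive = gcs_alive, dead = gcs_dead, mout = gcs_alive)
  colnames(gcs) <- as.character(3:15)

  cat_probs <- function(...) {
    m <- rbind(...)
    sweep(m, 1, rowSums(m), "/")
  }
  categorical <- list(
    sex = cat_probs(alive = c(female = 0.367, male = 0.633),
                    dead = c(female = 0.324, male = 0.668),
                    mout = c(female = 0.292, male = 0.551)),
    vehicle = cat_probs(alive = c(helicopter = 0.499, ground_unit = 0.501),
                        dead = c(helicopter = 0.517, ground_unit = 0.483),
                        mout = c(helicopter = 0.489, ground_unit = 0.511)),
    facility = cat_probs(alive = c(no = 0.948, yes = 0.052),
                         dead = c(no = 0.914, yes = 0.086),
                         mout = c(no = 0.967, yes = 0.033)),
    n_patients = cat_probs(alive = c(`1` = 0.978, `2` = 0.022),
                           dead = c(`1` = 0.996, `2` = 0.004),
                           mout = c(`1` = 0.971, `2` = 0.029)),
    rhythm_raw = cat_probs(
      alive = c(sinus = 0.718, sves_ves_mono = 0.004,
                aflut_afib_avblock_vespoly = 0.070,
                vf_vt_asystole_pea = 0.042, not_registered = 0.082,
                paced = 0.005),
      dead = c(sinus = 0.266, sves_ves_mono = 0.003,
               aflut_afib_avblock_vespoly = 0.090,
               vf_vt_asystole_pea = 0.544, not_registered = 0.015,
               paced = 0.009),
      mout = c(sinus = 0.662, sves_ves_mono = 0.003,
               aflut_afib_avblock_vespoly = 0.054,
               vf_vt_asystole_pea = 0.043, not_registered = 0.109,
               paced = 0.003)
    ),
    category = cat_probs(
      alive = c(cardiac_arrest = 0.071, trauma = 0.328,
                respiratory_failure = 0.055, chest_pain = 0.041,
                stroke = 0.057, neurological_other = 0.141,
                psychiatric_intoxication = 0.149, gyn_obstetrics = 0.032,
                infection = 0.010, other = 0.116),
      dead = c(cardiac_arrest = 0.634, trauma = 0.106,
               respiratory_failure = 0.034, chest_pain = 0.009,
               stroke = 0.095, neurological_other = 0.059,
               psychiatric_intoxication = 0.0073, gyn_obstetrics = 0.00012,
               infection = 0.0072, other = 0.047),
      mout = c(cardiac_arrest = 0.074, trauma = 0.354,
               respiratory_failure = 0.041, chest_pain = 0.026,
               stroke = 0.045, neurological_other = 0.125,
               psychiatric_intoxication = 0.170, gyn_obstetrics = 0.030,
               infection = 0.008, other = 0.126)
    )
  )
  miss <- rbind(
    heart_rate = c(0.128, 0.589, 0.237),
    sbp = c(0.144, 0.612, 0.269),
    resp_rate = c(0.343, 0.683, 0.478),
    spo2 = c(0.156, 0.639, 0.265),
    time_to_ems = c(0.680, 0.567, 0.732),
    gcs = c(0.065, 0.089, 0.083),
    rhythm_raw = c(0.079, 0.072, 0.125),
    sex = c(0.000, 0.008, 0.156)
  )
  colnames(miss) <- strata
  if (!is.null(missingness)) {
    for (v in names(missingness)) {
      p <- missingness[[v]]
      if (length(p) == 1) p <- rep(p, 3)
      if (v %in% rownames(miss)) {
        miss[v, ] <- p
      } else {
        miss <- rbind(miss, p)
        rownames(miss)[nrow(miss)] <- v
      }
    }
  }
  if (outcome_mechanism == "from_true_model" && is.null(true_model)) {
    true_model <- default_true_model()
  }
  cfg <- structure(
    list(n = n, seed = seed,
         prevalence = 8611 / 28369,
         p_outcome_missing = 1817 / 30186,
         continuous = cont, gcs = gcs, categorical = categorical,
         missingness = miss, outcome_mechanism = outcome_mechanism,
         true_model = true_model),
    class = "champ_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "champ_sim_config"))
  if (config$n < 0) stop("cohort size must be non-negative", call. = FALSE)
  probs <- c(config$prevalence, config$p_outcome_missing,
             as.numeric(config$missingness), as.numeric(config$gcs),
             unlist(lapply(config$categorical, as.numeric)))
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (v in names(config$categorical)) {
    s <- rowSums(config$categorical[[v]])
    if (any(abs(s - 1) > 1e-8)) {
      stop("config error: level probabilities for '", v,
           "' must sum to 1", call. = FALSE)
    }
  }
  if (any(abs(rowSums(config$gcs) - 1) > 1e-8)) {
    stop("config error: GCS probabilities must sum to 1", call. = FALSE)
  }
  invisible(config)
}

#' Canonical screening structure of the published model
#'
#' The screening outcome the registry cohort produces: respiratory rate and
#' time to first-EMS arrival dropped for missingness above one third, the
#' patient count dropped because the two-or-more level is too rare, and the
#' infection and gynaecology/obstetrics categories merged into the reference
#' group. Useful for constructing true models and toy registries without
#' running [screen_variables()] on data.
#'
#' @return A `champ_screening` object with the 11 retained predictors.
#' @export
default_screening <- function() {
  structure(
    list(
      retained = c("sbp", "heart_rate", "spo2", "gcs", "sex", "age",
                   "vehicle", "facility", "rhythm_binary", "time_to_hems",
                   "category"),
      dropped = tibble::tibble(
        variable = c("resp_rate", "time_to_ems", "n_patients"),
        reason = c("missing_fraction", "missing_fraction", "rare_level"),
        statistic = c(0.448, 0.651, 0.017)
      ),
      merged = tibble::tibble(
        level = c("infection", "gyn_obstetrics"),
        into = "infection_or_gyn_obstetrics"
      ),
      reference_level = "infection_or_gyn_obstetrics",
      config = list(max_missing_fraction = 1 / 3,
                    min_category_prevalence = 0.02,
                    min_outcome_prevalence = 0.02)
    ),
    class = "champ_screening"
  )
}

#' A fixed ground-truth logistic model on the design scale
#'
#' A plausible data-generating model for simulation studies: fixed
#' winsorization limits and spline knots (so the truth does not depend on
#' any sample) and a named coefficient vector over the full 30-column design
#' (intercept + 29 predictor columns). Mortality rises with age, falls with
#' GCS and oxygen saturation, is U-shaped in systolic blood pressure, and is
#' dominated by arrest rhythm and the cardiac-arrest category.
#'
#' @return A list with `beta`, `transform` and `screening`.
#' @export
default_true_model <- function() {
  screening <- default_screening()
  tr <- structure(
    list(
      limits = list(sbp = c(60, 220), heart_rate = c(40, 180),
                    spo2 = c(70, 100), gcs = c(3, 15), age = c(18, 95),
                    time_to_hems = c(5, 90)),
      knots = list(sbp = c(85, 115, 140, 190),
                   heart_rate = c(55, 80, 100, 140),
                   spo2 = c(75, 90, 97, 100), gcs = c(3, 12, 15),
                   age = c(25, 45, 65, 85), time_to_hems = c(8, 15, 25, 50)),
      category_levels = c("infection_or_gyn_obstetrics", "cardiac_arrest",
                          "trauma", "respiratory_failure", "chest_pain",
                          "stroke", "neurological_other",
                          "psychiatric_intoxication", "other"),
      reference_level = "infection_or_gyn_obstetrics",
      retained = screening$retained,
      config = transform_config(), columns = NULL),
    class = "champ_transform"
  )
  empty <- tibble::tibble(
    sbp = numeric(0), heart_rate = numeric(0), spo2 = numeric(0),
    gcs = numeric(0), sex = character(0), age = numeric(0),
    vehicle = character(0), facility = numeric(0),
    rhythm_binary = numeric(0), time_to_hems = numeric(0),
    category = character(0)
  )
  tr$columns <- colnames(build_design(empty, tr))
  # intercept calibrated once so that, with covariates drawn from the
  # default stratum mixture, the implied 30-day mortality is close to 30%
  beta <- c(
    `(Intercept)` = 1.7,
    sbp = -0.012, sbp_rcs1 = 0.05, sbp_rcs2 = -0.08,
    heart_rate = -0.008, heart_rate_rcs1 = 0.012, heart_rate_rcs2 = -0.02,
    spo2 = -0.045, spo2_rcs1 = 0.06, spo2_rcs2 = -0.12,
    gcs = -0.18, gcs_rcs1 = 0.15,
    sex_male = 0.10, age = 0.030, age_rcs1 = 0.02, age_rcs2 = -0.04,
    vehicle_ground = 0.05, facility_yes = 0.20, rhythm_binary = 1.50,
    time_to_hems = 0.005, time_to_hems_rcs1 = 0.010,
    time_to_hems_rcs2 = -0.020,
    category_cardiac_arrest = 1.20, category_trauma = 0.20,
    category_respiratory_failure = 0.30, category_chest_pain = 0.00,
    category_stroke = 0.80, category_neurological_other = -0.30,
    category_psychiatric_intoxication = -1.50, category_other = 0.10
  )
  stopifnot(setequal(names(beta), tr$columns))
  list(beta = beta[tr$columns], transform = tr, screening = screening)
}

#' Generate a synthetic HEMS cohort
#'
#' Draws a cohort from a [default_fhdb_config()]-style configuration,
#' returning both the observed cohort (missingness applied) and the latent
#' complete version, plus ground truth for parameter-recovery studies.
#' Reproducible: the same seed yields byte-identical cohorts, and each
#' variable uses its own counter-derived random substream.
#'
#' @param config A `champ_sim_config`.
#' @return An object of class `champ_sim`: list with `observed` (cohort
#'   tibble with missing cells), `complete` (pre-missingness tibble) and
#'   `truth` (stratum labels; for model-based outcomes also `beta`,
#'   `transform` and the latent probabilities `p`).
#' @export
generate_cohort <- function(config = default_fhdb_config()) {
  validate_sim_config(config)
  n <- config$n
  seed <- config$seed
  strata <- c("alive", "dead", "mout")
  p_str <- c(
    (1 - config$p_outcome_missing) * (1 - config$prevalence),
    (1 - config$p_outcome_missing) * config$prevalence,
    config$p_outcome_missing
  )
  stratum <- with_substream(seed, "stratum", {
    strata[sample.int(3, n, replace = TRUE, prob = p_str)]
  })

  draw_cont <- function(v) {
    x <- numeric(n)
    anchors <- config$continuous[[v]]
    u <- with_substream(seed, v, stats::runif(n))
    for (s in strata) {
      idx <- stratum == s
      x[idx] <- stats::approx(c(0, 0.25, 0.5, 0.75, 1), anchors[s, ],
                              xout = u[idx], rule = 2)$y
    }
    x
  }
  draw_cat <- function(v) {
    probs <- config$categorical[[v]]
    lev <- colnames(probs)
    x <- character(n)
    u <- with_substream(seed, v, stats::runif(n))
    for (s in strata) {
      idx <- stratum == s
      x[idx] <- lev[findInterval(u[idx], cumsum(probs[s, ]),
                                 rightmost.closed = TRUE) + 1]
    }
    x
  }
  draw_gcs <- function() {
    x <- numeric(n)
    u <- with_substream(seed, "gcs", stats::runif(n))
    vals <- as.numeric(colnames(config$gcs))
    for (s in strata) {
      idx <- stratum == s
      x[idx] <- vals[findInterval(u[idx], cumsum(config$gcs[s, ]),
                                  rightmost.closed = TRUE) + 1]
    }
    x
  }

  complete <- tibble::tibble(
    age = round(draw_cont("age"), 1),
    sex = draw_cat("sex"),
    n_patients = as.numeric(draw_cat("n_patients")),
    gcs = draw_gcs(),
    vehicle = draw_cat("vehicle"),
    rhythm_raw = draw_cat("rhythm_raw"),
    resp_rate = round(draw_cont("resp_rate")),
    sbp = round(draw_cont("sbp")),
    spo2 = pmin(100, round(draw_cont("spo2"))),
    heart_rate = round(draw_cont("heart_rate")),
    category = draw_cat("category"),
    time_to_hems = round(draw_cont("time_to_hems")),
    time_to_ems = round(draw_cont("time_to_ems")),
    facility = as.numeric(draw_cat("facility") == "yes")
  )

  truth <- list(stratum = stratum, config = config)
  if (config$outcome_mechanism == "from_true_model") {
    tm <- config$true_model
    rows <- derive_model_variables(complete, tm$screening)
    eta <- drop(build_design(rows, tm$transform) %*% tm$beta)
    p <- stats::plogis(eta)
    y <- with_substream(seed, "outcome_model", {
      as.numeric(stats::runif(n) < p)
    })
    complete$outcome <- y
    stratum_miss <- ifelse(y == 1, "dead", "alive")
    truth$beta <- tm$beta
    truth$transform <- tm$transform
    truth$screening <- tm$screening
    truth$p <- p
  } else {
    complete$outcome <- ifelse(stratum == "dead", 1, 0)
    stratum_miss <- stratum
  }

  observed <- complete
  for (v in rownames(config$missingness)) {
    if (!v %in% names(observed)) next
    u <- with_substream(seed, paste0("miss_", v), stats::runif(n))
    rate <- config$missingness[v, ][stratum_miss]
    observed[[v]][u < rate] <- NA
  }
  if (config$outcome_mechanism == "fixed_prevalence") {
    observed$outcome[stratum == "mout"] <- NA
    # the latent outcome of an outcome-missing record follows the overall
    # prevalence; keep the complete version fully defined
    u <- with_substream(seed, "mout_latent", stats::runif(n))
    idx <- stratum == "mout"
    complete$outcome[idx] <- as.numeric(u[idx] < config$prevalence)
  } else if (config$p_outcome_missing > 0) {
    u <- with_substream(seed, "miss_outcome", stats::runif(n))
    observed$outcome[u < config$p_outcome_missing] <- NA
  }

  structure(list(observed = observed, complete = complete, truth = truth),
            class = "champ_sim")
}

#' @export
print.champ_sim <- function(x, ...) {
  cat("Synthetic HEMS cohort: ", nrow(x$observed), " records (",
      x$truth$config$outcome_mechanism, ")\n", sep = "")
  invisible(x)
}
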