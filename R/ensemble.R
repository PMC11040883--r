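#' Enumerate droppable-variable inclusion masks
#'
#' All `2^k` subsets of the droppable predictors, encoded as bit strings in
#' the fixed droppable order (`"1"` = variable included). Deterministic
#' order: descending number of included variables, then lexicographic.
#'
#' @param droppable Character vector of droppable predictors (no
#'   duplicates). Default [champ_droppable()].
#' @return Character vector of `2^k` masks; the first is the all-ones mask.
#' @export
enumerate_subsets <- function(droppable = champ_droppable()) {
  if (anyDuplicated(droppable)) {
    stop("duplicate droppable variable", call. = FALSE)
  }
  k <- length(droppable)
  if (k == 0) return("")
  grid <- expand.grid(rep(list(c(1L, 0L)), k))[, k:1, drop = FALSE]
  masks <- apply(grid, 1, paste, collapse = "")
  masks[order(-nchar(gsub("0", "", masks)), masks)]
}

mask_to_subset <- function(mask, droppable, core, retained) {
  inc <- droppable[strsplit(mask, "")[[1]] == "1"]
  intersect(retained, c(core, inc))
}

availability_mask <- function(data, droppable) {
  bits <- vapply(droppable, function(v) {
    if (!v %in% names(data)) rep(FALSE, nrow(data)) else !is.na(data[[v]])
  }, logical(nrow(data)))
  if (nrow(data) == 1) bits <- matrix(bits, nrow = 1)
  apply(bits, 1, function(b) paste(as.integer(b), collapse = ""))
}

#' Build the missingness-adaptive submodel ensemble
#'
#' Fits one pooled winsorized-spline logistic submodel per subset of the
#' five droppable predictors (`2^5 = 32` models under the default set),
#' every submodel built in the same manner as the full model and restricted
#' to its own variables. The transform (winsorization limits, spline knots,
#' category levels) is frozen from the first completed dataset and shared by
#' all submodels, so the exported registry is self-contained.
#'
#' @param datasets A `champ_mice` object or a list of completed
#'   model-variable tibbles (each complete on the retained predictors and
#'   outcome). Raw-cohort columns are mapped to model variables
#'   automatically via `screening`.
#' @param screening A `champ_screening`.
#' @param config A `champ_transform_config`.
#' @param droppable Droppable predictor set. Default [champ_droppable()].
#' @return An object of class `champ_ensemble`: `models` (named by mask),
#'   `droppable`, `transform`, `screening`, `meta`.
#' @export
build_ensemble <- function(datasets, screening,
                           config = transform_config(),
                           droppable = champ_droppable()) {
  stopifnot(inherits(screening, "champ_screening"))
  if (inherits(datasets, "champ_mice")) {
    datasets <- complete_datasets(datasets)
  }
  if (!is.list(datasets) || length(datasets) == 0) {
    stop("datasets must be a non-empty list of completed tibbles",
         call. = FALSE)
  }
  droppable <- intersect(droppable, c(screening$retained))
  rows <- lapply(datasets, function(d) {
    if (!all(screening$retained %in% names(d))) {
      derive_model_variables(d, screening)
    } else {
      d
    }
  })
  transform <- fit_transform(rows[[1]], screening, config)
  core <- setdiff(screening$retained, droppable)
  masks <- enumerate_subsets(droppable)
  models <- vector("list", length(masks))
  names(models) <- masks
  for (msk in masks) {
    subset <- mask_to_subset(msk, droppable, core, screening$retained)
    models[[msk]] <- tryCatch(
      fit_pooled(rows, transform, subset),
      error = function(e) {
        stop("ensemble submodel '", msk, "' failed: ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  structure(
    list(models = models, droppable = droppable, transform = transform,
         screening = screening,
         meta = list(version = "1.0", m = length(rows),
                     n = nrow(rows[[1]]), created = "champr")),
    class = "champ_ensemble"
  )
}

#' @export
print.champ_ensemble <- function(x, ...) {
  cat("Pattern-submodel ensemble: ", length(x$models), " models over ",
      length(x$droppable), " droppable predictor(s)\n", sep = "")
  cat("  droppable (mask order): ", paste(x$droppable, collapse = ", "),
      "\n", sep = "")
  cat("  pooled over m = ", x$meta$m, " imputation(s), n = ", x$meta$n,
      "\n", sep = "")
  invisible(x)
}

#' Select the submodel with the most available variables
#'
#' For each record the selected mask is exactly the availability pattern of
#' the droppable predictors: the chosen submodel uses every observed
#' droppable variable and no missing one. Records missing a non-droppable
#' predictor are unscorable.
#'
#' @param ensemble A `champ_ensemble`.
#' @param data Model-variable tibble (see [derive_model_variables()]).
#' @param on_unscorable `"error"` (default) or `"na"` — how to treat records
#'   missing a non-droppable predictor.
#' @return Tibble with `.row`, `mask` and `reason` (`NA` when scorable).
#' @export
select_model <- function(ensemble, data,
                         on_unscorable = c("error", "na")) {
  on_unscorable <- match.arg(on_unscorable)
  stopifnot(inherits(ensemble, "champ_ensemble"))
  core <- setdiff(ensemble$screening$retained, ensemble$droppable)
  core_missing <- vapply(seq_len(nrow(data)), function(i) {
    mv <- core[vapply(core, function(v) is.na(data[[v]][i]), logical(1))]
    if (length(mv) == 0) NA_character_ else paste(mv, collapse = ", ")
  }, character(1))
  if (on_unscorable == "error" && any(!is.na(core_missing))) {
    bad <- which(!is.na(core_missing))[1]
    stop("unscorable record ", bad, ": missing non-droppable predictor(s): ",
         core_missing[bad], call. = FALSE)
  }
  mask <- availability_mask(data, ensemble$droppable)
  mask[!is.na(core_missing)] <- NA_character_
  tibble::tibble(.row = seq_len(nrow(data)), mask = mask,
                 reason = ifelse(is.na(core_missing), NA_character_,
                                 paste0("missing non-droppable: ",
                                        core_missing)))
}

#' Predict 30-day mortality with the ensemble
#'
#' Selects the submodel matching each record's availability pattern and
#' returns the inverse-logit of its linear predictor on the transformed
#' record. Continuous inputs are winsorized with the stored training limits
#' before basis evaluation, so extreme values cannot blow up the cubic
#' tails.
#'
#' @param object A `champ_ensemble`.
#' @param newdata Model-variable tibble.
#' @param on_unscorable `"error"` (default) or `"na"`.
#' @param ... Unused.
#' @return Tibble with `.row`, `mask`, `p` (probability of death within 30
#'   days) and `reason` for unscorable records.
#' @export
predict.champ_ensemble <- function(object, newdata,
                                   on_unscorable = c("error", "na"), ...) {
  on_unscorable <- match.arg(on_unscorable)
  sel <- select_model(object, newdata, on_unscorable)
  p <- rep(NA_real_, nrow(newdata))
  for (msk in unique(stats::na.omit(sel$mask))) {
    idx <- which(!is.na(sel$mask) & sel$mask == msk)
    fit <- object$models[[msk]]
    if (is.null(fit)) {
      stop("registry has no model for mask ", msk, call. = FALSE)
    }
    p[idx] <- predict_fit(fit, newdata[idx, , drop = FALSE])
  }
  tibble::tibble(.row = sel$.row, mask = sel$mask, p = p,
                 reason = sel$reason)
}

#' Export an ensemble registry to JSON
#'
#' Serialises the complete scoring state — droppable order, frozen
#' transform (winsorization limits, knots, category levels, column order)
#' and every submodel's coefficients (covariances optional) — into a
#' versioned JSON registry that [import_registry()] restores with
#' predictions preserved to near machine precision.
#'
#' @param ensemble A `champ_ensemble`.
#' @param path Output file path.
#' @param include_vcov Store covariance matrices too. Default `TRUE`.
#' @return `path`, invisibly.
#' @export
export_registry <- function(ensemble, path, include_vcov = TRUE) {
  stopifnot(inherits(ensemble, "champ_ensemble"))
  tr <- ensemble$transform
  obj <- list(
    schema = "champ-registry",
    schema_version = "1.0",
    droppable = ensemble$droppable,
    retained = ensemble$screening$retained,
    reference_level = ensemble$screening$reference_level,
    merged_levels = as.list(ensemble$screening$merged$level),
    transform = list(
      limits = tr$limits, knots = tr$knots,
      category_levels = tr$category_levels,
      winsor_exempt = tr$config$winsor_exempt,
      columns = tr$columns
    ),
    models = lapply(ensemble$models, function(f) {
      out <- list(
        subset = if (is.null(f$subset)) ensemble$screening$retained
                 else f$subset,
        columns = names(f$coefficients),
        coefficients = unname(f$coefficients),
        n = f$n, m = f$m
      )
      if (include_vcov) out$vcov <- unname(f$vcov)
      out
    }),
    meta = ensemble$meta
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Import an ensemble registry from JSON
#'
#' @param path Path to a registry written by [export_registry()].
#' @return A `champ_ensemble`.
#' @export
import_registry <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "champ-registry") {
    stop("not a champ registry file", call. = FALSE)
  }
  if (!identical(obj$schema_version, "1.0")) {
    stop("unsupported registry schema version: ", obj$schema_version,
         call. = FALSE)
  }
  droppable <- obj$droppable
  n_expected <- 2^length(droppable)
  if (length(obj$models) != n_expected) {
    stop("registry must contain 2^", length(droppable), " = ", n_expected,
         " models, found ", length(obj$models), call. = FALSE)
  }
  screening <- structure(
    list(retained = obj$retained,
         dropped = tibble::tibble(variable = character(),
                                  reason = character(),
                                  statistic = numeric()),
         merged = tibble::tibble(
           level = as.character(unlist(obj$merged_levels)),
           into = rep(obj$reference_level,
                      length(unlist(obj$merged_levels)))),
         reference_level = obj$reference_level,
         config = list()),
    class = "champ_screening"
  )
  transform <- structure(
    list(limits = lapply(obj$transform$limits, as.numeric),
         knots = lapply(obj$transform$knots, as.numeric),
         category_levels = obj$transform$category_levels,
         reference_level = obj$reference_level,
         retained = obj$retained,
         config = transform_config(
           winsor_exempt = obj$transform$winsor_exempt),
         columns = obj$transform$columns),
    class = "champ_transform"
  )
  models <- lapply(obj$models, function(mj) {
    beta <- as.numeric(mj$coefficients)
    names(beta) <- mj$columns
    vc <- if (!is.null(mj$vcov)) {
      v <- as.matrix(mj$vcov)
      dimnames(v) <- list(mj$columns, mj$columns)
      v
    } else {
      matrix(NA_real_, length(beta), length(beta),
             dimnames = list(mj$columns, mj$columns))
    }
    structure(
      list(coefficients = beta, vcov = vc, n = mj$n, converged = TRUE,
           iterations = NA_integer_, loglik = NULL, loglik_trace = NULL,
           fitted = NULL, m = mj$m, subset = mj$subset,
           transform = transform),
      class = "champ_fit"
    )
  })
  structure(
    list(models = models, droppable = droppable, transform = transform,
         screening = screening, meta = obj$meta),
    class = "champ_ensemble"
  )
}
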