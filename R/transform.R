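#' Empirical winsorization limits
#'
#' Learns the clipping limits used to curb the influence of extreme values:
#' the empirical lower and upper quantiles of the observed data (1% at both
#' ends by default). Values beyond the limits are later set to the limit
#' itself by [winsorize()].
#'
#' @param x Numeric vector; missing entries are ignored.
#' @param lower,upper Tail proportions to clip. Defaults `0.01` each.
#' @return Numeric vector `c(low, high)`.
#' @export
winsor_limits <- function(x, lower = 0.01, upper = 0.01) {
  stopifnot(lower >= 0, upper >= 0, lower < 0.5, upper < 0.5)
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    stop("need at least two finite values to estimate winsorization limits",
         call. = FALSE)
  }
  unname(stats::quantile(x, c(lower, 1 - upper), names = FALSE))
}

#' Apply winsorization limits
#'
#' @param x Numeric vector.
#' @param limits `c(low, high)` from [winsor_limits()].
#' @return `x` with values below/above the limits set to the limit itself;
#'   missing values pass through.
#' @export
winsorize <- function(x, limits) {
  stopifnot(length(limits) == 2, limits[1] <= limits[2])
  pmin(pmax(x, limits[1]), limits[2])
}

#' Place restricted-cubic-spline knots
#'
#' Knots sit at fixed quantiles of the observed data: `(0.10, 0.50, 0.90)`
#' for three knots and `(0.05, 0.35, 0.65, 0.95)` for four (the conventional
#' defaults when only the knot count is prescribed).
#'
#' @param x Numeric vector; missing entries are ignored.
#' @param k Number of knots (>= 3).
#' @param probs Optional explicit quantile probabilities of length `k`.
#' @return Strictly increasing numeric vector of `k` knot locations.
#' @export
place_knots <- function(x, k, probs = NULL) {
  stopifnot(k >= 3)
  if (is.null(probs)) {
    probs <- switch(as.character(k),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = k)
    )
  }
  stopifnot(length(probs) == k)
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) {
    stop("only ", length(unique(x)), " distinct value(s) for ", k,
         " knots; request fewer knots", call. = FALSE)
  }
  knots <- unname(stats::quantile(x, probs, names = FALSE))
  if (any(diff(knots) <= 0)) {
    stop("knot locations are not strictly increasing (too few distinct ",
         "values); request fewer knots", call. = FALSE)
  }
  knots
}

#' Restricted cubic spline basis
#'
#' Builds the (k-1)-column natural cubic spline basis for knots
#' `t_1 < ... < t_k`: the first column is `x` itself and column `j+1`
#' (`j = 1, ..., k-2`) is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' which is linear beyond the boundary knots. The `(t_k-t_1)^2`
#' normalisation keeps the nonlinear columns on the scale of `x`.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing knot locations, length >= 3.
#' @return Numeric matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("restricted cubic splines need at least 3 knots",
                  call. = FALSE)
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  cube <- function(u) pmax(u, 0)^3
  norm <- (knots[k] - knots[1])^2
  out <- matrix(NA_real_, nrow = length(x), ncol = k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (cube(x - knots[j]) -
      cube(x - knots[k - 1]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1]) +
      cube(x - knots[k]) * (knots[k - 1] - knots[j]) /
        (knots[k] - knots[k - 1])) / norm
  }
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2)))
  out
}

#' Transform configuration
#'
#' @param winsor_lower,winsor_upper Winsorization tail proportions
#'   (default 0.01 each).
#' @param knots_by_variable Named integer vector mapping continuous model
#'   variables to knot counts; default three knots for GCS, four for the
#'   rest.
#' @param winsor_exempt Variables never winsorized; default `"gcs"` (an
#'   already-bounded integer scale).
#' @return A list of class `champ_transform_config`.
#' @export
transform_config <- function(winsor_lower = 0.01, winsor_upper = 0.01,
                             knots_by_variable = champ_spline_spec(),
                             winsor_exempt = "gcs") {
  stopifnot(winsor_lower >= 0, winsor_upper >= 0,
            winsor_lower < 0.5, winsor_upper < 0.5,
            all(knots_by_variable >= 3))
  structure(
    list(winsor_lower = winsor_lower, winsor_upper = winsor_upper,
         knots_by_variable = knots_by_variable,
         winsor_exempt = winsor_exempt),
    class = "champ_transform_config"
  )
}

#' Fit the design transform on training data
#'
#' Learns, from a completed (no missing cells among its variables) set of
#' model rows, everything needed to build a design matrix deterministically
#' at scoring time: winsorization limits, spline knot locations, category
#' levels and the full design column order. Limits and knots are frozen here
#' and reused verbatim when scoring new records.
#'
#' @param data Model-variable tibble from [derive_model_variables()] with no
#'   missing cells among the retained predictors (use an imputed dataset).
#' @param screening A `champ_screening` object.
#' @param config A `champ_transform_config`.
#' @return An object of class `champ_transform`: per-variable `limits`,
#'   `knots`, `category_levels`, `reference_level` and `columns` (full
#'   design column order, including the intercept).
#' @export
fit_transform <- function(data, screening, config = transform_config()) {
  stopifnot(inherits(screening, "champ_screening"))
  cont <- names(config$knots_by_variable)
  cont <- cont[cont %in% screening$retained]
  limits <- list()
  knots <- list()
  for (v in cont) {
    x <- data[[v]]
    if (v %in% config$winsor_exempt) {
      limits[[v]] <- range(x, na.rm = TRUE)
    } else {
      limits[[v]] <- winsor_limits(x, config$winsor_lower,
                                   config$winsor_upper)
      x <- winsorize(x, limits[[v]])
    }
    knots[[v]] <- place_knots(x, config$knots_by_variable[[v]])
  }
  cat_levels <- NULL
  if ("category" %in% screening$retained) {
    obs <- sort(unique(stats::na.omit(data$category)))
    ref <- screening$reference_level
    cat_levels <- c(ref, setdiff(obs, ref))
  }
  tr <- structure(
    list(limits = limits, knots = knots, category_levels = cat_levels,
         reference_level = screening$reference_level,
         retained = screening$retained, config = config, columns = NULL),
    class = "champ_transform"
  )
  tr$columns <- colnames(build_design(data[0, , drop = FALSE], tr))
  tr
}

# design columns contributed by one model variable
design_block <- function(variable, transform) {
  if (variable %in% names(transform$knots)) {
    k <- length(transform$knots[[variable]])
    paste0(variable, c("", paste0("_rcs", seq_len(k - 2))))
  } else if (variable == "category") {
    paste0("category_", transform$category_levels[-1])
  } else {
    switch(variable,
      sex = "sex_male", vehicle = "vehicle_ground",
      facility = "facility_yes", rhythm_binary = "rhythm_binary",
      variable
    )
  }
}

#' Build a regression design matrix
#'
#' Assembles the design matrix for a subset of the retained predictors using
#' a frozen transform: intercept, restricted-cubic-spline bases for the
#' continuous members (winsorized with the stored training limits), binary
#' indicators (`sex_male`, `vehicle_ground`, `facility_yes`,
#' `rhythm_binary`), and category indicators against the merged reference
#' level. Column order is deterministic.
#'
#' @param data Model-variable tibble, complete on `subset`.
#' @param transform A `champ_transform` from [fit_transform()].
#' @param subset Character vector of model variables to include; default all
#'   retained predictors.
#' @return Numeric matrix with an `"(Intercept)"` first column.
#' @export
build_design <- function(data, transform, subset = NULL) {
  stopifnot(inherits(transform, "champ_transform"))
  if (is.null(subset)) subset <- transform$retained
  bad <- setdiff(subset, transform$retained)
  if (length(bad) > 0) {
    stop("variables not retained by screening: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  blocks <- list(`(Intercept)` = matrix(1, nrow = n, ncol = 1))
  for (v in intersect(transform$retained, subset)) {
    if (any(is.na(data[[v]]))) {
      stop("missing values in '", v, "' within the requested subset; ",
           "model selection should have routed this record elsewhere",
           call. = FALSE)
    }
    if (v %in% names(transform$knots)) {
      x <- data[[v]]
      if (!v %in% transform$config$winsor_exempt) {
        x <- winsorize(x, transform$limits[[v]])
      }
      b <- rcs_basis(x, transform$knots[[v]])
    } else if (v == "category") {
      lev <- transform$category_levels
      unknown <- setdiff(unique(data$category), lev)
      if (length(unknown) > 0) {
        stop("unknown category level(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      b <- vapply(lev[-1], function(l) as.numeric(data$category == l),
                  numeric(n))
      if (n == 0) b <- matrix(numeric(0), 0, length(lev) - 1)
      if (is.null(dim(b))) b <- matrix(b, nrow = n)
    } else {
      x <- switch(v,
        sex = as.numeric(data$sex == "male"),
        vehicle = as.numeric(data$vehicle == "ground_unit"),
        facility = as.numeric(data$facility == 1),
        data[[v]]
      )
      b <- matrix(x, ncol = 1)
    }
    colnames(b) <- design_block(v, transform)
    blocks[[v]] <- b
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(names(blocks), function(nm) {
    if (nm == "(Intercept)") "(Intercept)" else design_block(nm, transform)
  }))
  out
}
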