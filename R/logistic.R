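#' Maximum-likelihood logistic regression
#'
#' Fits a Bernoulli log-likelihood by iteratively reweighted least squares
#' (Newton) with step-halving, to a gradient tolerance of `1e-8` or 100
#' iterations. The covariance is the inverse observed information. Complete
#' separation (diverging coefficients) and rank-deficient designs raise
#' distinct errors rather than being silently regularised.
#'
#' @param x Design matrix including an intercept column (see
#'   [build_design()]).
#' @param y Binary outcome vector (0/1), same length as `nrow(x)`.
#' @param weights Optional non-negative case weights.
#' @param tol Convergence tolerance on the maximum absolute score. Default
#'   `1e-8`.
#' @param maxit Maximum Newton iterations. Default 100.
#' @return An object of class `champ_fit`: `coefficients`, `vcov`, `n`,
#'   `converged`, `iterations`, `loglik` (final), `loglik_trace`
#'   (per-iteration, non-decreasing), `fitted`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_logistic <- function(x, y, weights = NULL, tol = 1e-8, maxit = 100) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(all(weights >= 0))
  if (nrow(x) <= ncol(x)) {
    stop("more design columns than records", call. = FALSE)
  }
  if (min(sum(weights[y == 1]), sum(weights[y == 0])) == 0) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  loglik <- function(eta) {
    sum(weights * (y * eta - log1p(exp(eta))))
  }
  beta <- rep(0, ncol(x))
  eta <- drop(x %*% beta)
  ll <- loglik(eta)
  trace <- ll
  converged <- FALSE
  iter <- 0
  while (iter < maxit) {
    iter <- iter + 1
    mu <- stats::plogis(eta)
    w <- weights * mu * (1 - mu)
    score <- drop(crossprod(x, weights * (y - mu)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    info <- crossprod(x, x * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      stop("complete or quasi-complete separation detected: observed ",
           "information is numerically singular", call. = FALSE)
    }
    # step-halving to guarantee a non-decreasing log-likelihood
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      eta_new <- drop(x %*% beta_new)
      ll_new <- loglik(eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) {
        stop("step-halving failed to improve the log-likelihood",
             call. = FALSE)
      }
    }
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (max(abs(beta)) > 1e5) {
      stop("complete separation detected: coefficients diverge",
           call. = FALSE)
    }
  }
  if (max(abs(beta)) > 30) {
    # the score can vanish numerically while the likelihood is maximised
    # at infinity: coefficients this large are a separated fit
    stop("complete separation detected: coefficients diverge",
         call. = FALSE)
  }
  if (!converged) {
    warning("IRLS did not reach tolerance ", tol, " in ", maxit,
            " iterations", call. = FALSE)
  }
  mu <- stats::plogis(eta)
  info <- crossprod(x, x * (weights * mu * (1 - mu)))
  vcov <- solve(info)
  names(beta) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(
    list(coefficients = beta, vcov = vcov, n = nrow(x),
         converged = converged, iterations = iter, loglik = ll,
         loglik_trace = trace, fitted = mu, m = 1L,
         subset = NULL, transform = NULL),
    class = "champ_fit"
  )
}

#' @export
print.champ_fit <- function(x, ...) {
  cat("Logistic model fit (", x$n, " records",
      if (x$m > 1) paste0(", pooled over ", x$m, " imputations"), ")\n",
      sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.champ_fit <- function(object, ...) object$coefficients

#' @export
vcov.champ_fit <- function(object, ...) object$vcov

#' @rdname fit_logistic
#' @param object,x A `champ_fit`.
#' @param ... Unused.
#' @method tidy champ_fit
#' @export
tidy.champ_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @rdname fit_logistic
#' @method glance champ_fit
#' @export
glance.champ_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, n_terms = length(x$coefficients),
    converged = x$converged, iterations = x$iterations,
    logLik = if (is.null(x$loglik)) NA_real_ else x$loglik,
    n_imputations = x$m
  )
}

#' Odds ratios with confidence intervals
#'
#' `OR = exp(beta)` with a normal-theory interval
#' `exp(beta +/- z * SE)` using the model's (possibly pooled) covariance.
#'
#' @param fit A `champ_fit`.
#' @param terms Coefficient names to report; default all non-intercept terms.
#' @param level Confidence level. Default 0.95.
#' @return Tibble with `term`, `estimate` (OR), `conf.low`, `conf.high`.
#' @export
odds_ratios <- function(fit, terms = NULL, level = 0.95) {
  stopifnot(inherits(fit, "champ_fit"))
  if (is.null(terms)) {
    terms <- setdiff(names(fit$coefficients), "(Intercept)")
  }
  missing_terms <- setdiff(terms, names(fit$coefficients))
  if (length(missing_terms) > 0) {
    stop("term(s) not in model: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients[terms]
  se <- sqrt(diag(fit$vcov)[terms])
  tibble::tibble(
    term = terms,
    estimate = unname(exp(b)),
    conf.low = unname(exp(b - z * se)),
    conf.high = unname(exp(b + z * se))
  )
}

#' Wald test for a block of coefficients
#'
#' Computes `t(beta) V^-1 beta` over the columns of one predictor (a spline
#' variable contributes `k - 1` degrees of freedom, the patient category
#' `levels - 1`, a binary indicator 1) with a chi-square upper-tail p-value.
#'
#' @param fit A `champ_fit`.
#' @param terms Coefficient names forming the block.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
wald_test <- function(fit, terms) {
  stopifnot(inherits(fit, "champ_fit"), length(terms) >= 1)
  missing_terms <- setdiff(terms, names(fit$coefficients))
  if (length(missing_terms) > 0) {
    stop("term(s) not in model: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  b <- fit$coefficients[terms]
  v <- fit$vcov[terms, terms, drop = FALSE]
  vi <- tryCatch(solve(v), error = function(e) {
    stop("singular covariance block for Wald test", call. = FALSE)
  })
  stat <- drop(t(b) %*% vi %*% b)
  df <- length(terms)
  tibble::tibble(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Per-predictor Wald table
#'
#' Runs [wald_test()] on every predictor's coefficient block in a model
#' built by [build_design()] (each category level tested separately, as in
#' standard model-development reporting).
#'
#' @param fit A `champ_fit` whose coefficients follow the design column
#'   naming of [build_design()].
#' @param transform The `champ_transform` used to build the design.
#' @return Tibble with `variable`, `statistic`, `df`, `p.value`.
#' @export
wald_table <- function(fit, transform) {
  vars <- intersect(transform$retained,
                    if (is.null(fit$subset)) transform$retained
                    else fit$subset)
  rows <- lapply(vars, function(v) {
    cols <- design_block(v, transform)
    if (v == "category") {
      dplyr::bind_rows(lapply(cols, function(cl) {
        dplyr::mutate(wald_test(fit, cl),
                      variable = sub("^category_", "category:", cl),
                      .before = 1)
      }))
    } else {
      dplyr::mutate(wald_test(fit, cols), variable = v, .before = 1)
    }
  })
  dplyr::bind_rows(rows)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is the mean within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance. The small-sample
#' degrees of freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2` are returned for
#' interval construction.
#'
#' @param estimates Numeric vector of length `m` (one estimate per
#'   completed dataset).
#' @param variances Numeric vector of squared standard errors, length `m`.
#' @return One-row tibble: `estimate`, `within`, `between`, `variance`
#'   (total), `df`, `riv` (relative increase in variance).
#' @export
pool_rubin <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have the same length", call. = FALSE)
  }
  if (any(variances < 0)) stop("negative variance input", call. = FALSE)
  m <- length(estimates)
  if (m == 1) {
    warning("single imputation: no between-imputation variance available",
            call. = FALSE)
    return(tibble::tibble(estimate = estimates, within = variances,
                          between = 0, variance = variances, df = Inf,
                          riv = 0))
  }
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  riv <- (1 + 1 / m) * b / w
  df <- if (b == 0) Inf else (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  tibble::tibble(estimate = qbar, within = w, between = b,
                 variance = total, df = df, riv = riv)
}

#' Fit one submodel pooled over an imputed stack
#'
#' Fits the logistic model on every completed dataset and pools with Rubin's
#' rules: coefficients element-wise, covariance as the mean within-fit
#' covariance plus `(1 + 1/m)` times the between-imputation covariance of
#' the coefficient vectors (the full matrix, so Wald blocks keep their
#' off-diagonals). All fits share one frozen transform so the pooled
#' coefficients refer to a single, exportable basis.
#'
#' @param datasets List of completed model-variable tibbles (all sharing the
#'   observed cells; see [impute_cohort()] and [complete_datasets()]).
#' @param transform A `champ_transform` (frozen knots/limits).
#' @param subset Variables to include; default all retained.
#' @param outcome_var Name of the outcome column. Default `"outcome"`.
#' @return A pooled `champ_fit` with `m = length(datasets)`.
#' @export
fit_pooled <- function(datasets, transform, subset = NULL,
                       outcome_var = "outcome") {
  stopifnot(length(datasets) >= 1)
  fits <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    xx <- build_design(d, transform, subset)
    fit <- tryCatch(fit_logistic(xx, d[[outcome_var]]), error = function(e) {
      stop("submodel fit failed on imputed dataset ", i, ": ",
           conditionMessage(e), call. = FALSE)
    })
    fits[[i]] <- fit
  }
  m <- length(fits)
  if (m == 1) {
    out <- fits[[1]]
    out$subset <- subset
    out$transform <- transform
    return(out)
  }
  coefs <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  qbar <- colMeans(coefs)
  wbar <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / m
  centred <- sweep(coefs, 2, qbar)
  bmat <- crossprod(centred) / (m - 1)
  total <- wbar + (1 + 1 / m) * bmat
  structure(
    list(coefficients = qbar, vcov = total, n = fits[[1]]$n,
         converged = all(vapply(fits, function(f) f$converged, logical(1))),
         iterations = max(vapply(fits, function(f) f$iterations,
                                 numeric(1))),
         loglik = mean(vapply(fits, function(f) f$loglik, numeric(1))),
         loglik_trace = NULL, fitted = NULL, m = m,
         subset = subset, transform = transform),
    class = "champ_fit"
  )
}

# linear predictor / probability for model rows, using the fit's own
# transform and subset
predict_fit <- function(fit, data, type = c("response", "link")) {
  type <- match.arg(type)
  stopifnot(!is.null(fit$transform))
  xx <- build_design(data, fit$transform, fit$subset)
  xx <- xx[, names(fit$coefficients), drop = FALSE]
  eta <- drop(xx %*% fit$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}
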