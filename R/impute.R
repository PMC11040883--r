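# --- conditional draws used inside the chained-equations sweep ---------

# ridge-stabilised Bayesian linear draw + predictive mean matching
pmm_draw <- function(y_obs, x_obs, x_mis, k, ridge) {
  p <- ncol(x_obs)
  xtx <- crossprod(x_obs)
  a <- xtx + ridge * mean(diag(xtx)) * diag(p)
  betahat <- solve(a, crossprod(x_obs, y_obs))
  resid <- y_obs - drop(x_obs %*% betahat)
  df <- max(length(y_obs) - p, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  cv <- solve(a)
  cv <- (cv + t(cv)) / 2
  beta_star <- drop(betahat) +
    drop(t(chol(cv)) %*% stats::rnorm(p)) * sqrt(sigma2)
  yhat_obs <- drop(x_obs %*% betahat)
  yhat_mis <- drop(x_mis %*% beta_star)
  ord <- order(yhat_obs)
  ys <- y_obs[ord]
  yh <- yhat_obs[ord]
  n_obs <- length(yh)
  out <- numeric(length(yhat_mis))
  for (i in seq_along(yhat_mis)) {
    pos <- findInterval(yhat_mis[i], yh)
    lo <- max(1, pos - k)
    hi <- min(n_obs, pos + k)
    cand <- lo:hi
    d <- abs(yh[cand] - yhat_mis[i])
    donors <- cand[order(d)][seq_len(min(k, length(cand)))]
    out[i] <- ys[donors[sample.int(length(donors), 1)]]
  }
  out
}

# penalised IRLS logistic draw (ridge keeps separation finite)
logreg_draw <- function(y_obs, x_obs, x_mis, ridge = 1e-4) {
  p <- ncol(x_obs)
  beta <- rep(0, p)
  pen <- ridge * diag(p)
  for (it in 1:50) {
    eta <- drop(x_obs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(x_obs, y_obs - mu)) - ridge * beta
    info <- crossprod(x_obs, x_obs * w) + pen
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-6) break
  }
  info <- crossprod(x_obs, x_obs * pmax(stats::plogis(drop(x_obs %*% beta)) *
    (1 - stats::plogis(drop(x_obs %*% beta))), 1e-10)) + pen
  cv <- solve(info)
  cv <- (cv + t(cv)) / 2
  beta_star <- beta + drop(t(chol(cv)) %*% stats::rnorm(p))
  p_mis <- stats::plogis(drop(x_mis %*% beta_star))
  as.numeric(stats::runif(length(p_mis)) < p_mis)
}

# polytomous draw: multinomial logistic fitted on a bootstrap resample of
# the observed rows (parameter uncertainty via the bootstrap), classes drawn
# from the predicted probabilities
polyreg_draw <- function(y_obs, x_obs, x_mis) {
  boot <- sample.int(length(y_obs), replace = TRUE)
  yb <- factor(y_obs[boot])
  xb <- x_obs[boot, , drop = FALSE]
  df_fit <- data.frame(.y = yb, xb, check.names = FALSE)
  fit <- nnet::multinom(.y ~ . - 1, data = df_fit, trace = FALSE,
                        maxit = 200, MaxNWts = 5000)
  probs <- stats::predict(fit, newdata = data.frame(x_mis,
                                                    check.names = FALSE),
                          type = "probs")
  lev <- levels(yb)
  if (length(lev) == 2) probs <- cbind(1 - probs, probs)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  idx <- apply(probs, 1, function(pr) {
    sample.int(length(pr), 1, prob = pmax(pr, 0))
  })
  lev[idx]
}

# numeric predictor matrix (with intercept) from completed columns
impute_design <- function(data, predictors) {
  cols <- lapply(predictors, function(v) {
    x <- data[[v]]
    if (is.character(x) || is.factor(x)) {
      f <- factor(x)
      if (nlevels(f) < 2) return(NULL)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(v, "_", levels(f)[-1])
      m
    } else {
      matrix(x, ncol = 1, dimnames = list(NULL, v))
    }
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  cbind(`(Intercept)` = rep(1, nrow(data)), do.call(cbind, cols))
}

#' Multiple imputation by chained equations
#'
#' Fills the missing cells of a cohort with `m` independent completed
#' copies. Each sweep visits the incomplete variables in order of
#' increasing missingness and draws from a conditional model given all
#' other variables: predictive mean matching with `k` donors for continuous
#' variables (so imputed GCS values are always observed donor values, hence
#' integers in 3--15), a Bayesian logistic draw for binaries, and a
#' polytomous logistic draw for unordered categories. Observed cells are
#' never altered. Each completed dataset uses its own random substream, so
#' increasing `m` leaves earlier datasets unchanged.
#'
#' @param data Cohort tibble (candidate predictors, outcome, and any
#'   auxiliary columns).
#' @param m Number of completed datasets. Default 30.
#' @param maxit Chained-equation sweeps per dataset. Default 10.
#' @param seed Integer seed. Default 1.
#' @param k Donor count for predictive mean matching. Default 5.
#' @param include_outcome Keep the outcome in the imputation model, both as
#'   predictor and imputation target. Default `TRUE`.
#' @param methods Optional named character vector overriding the conditional
#'   model per variable (`"pmm"`, `"logreg"`, `"polyreg"`).
#' @param ridge Ridge stabilisation factor for near-collinear conditional
#'   fits. Default `1e-5`.
#' @return An object of class `champ_mice`: `imputations` (list of `m`
#'   completed tibbles), `trace` (per-iteration chain means/SDs of the
#'   imputed cells for convergence inspection), `visit_sequence`, `methods`
#'   and provenance (`m`, `maxit`, `seed`, `k`).
#' @export
impute_cohort <- function(data, m = 30, maxit = 10, seed = 1, k = 5,
                          include_outcome = TRUE, methods = NULL,
                          ridge = 1e-5) {
  stopifnot(m >= 1, maxit >= 1, k >= 1)
  data <- tibble::as_tibble(data)
  work_cols <- names(data)
  if (!include_outcome) work_cols <- setdiff(work_cols, "outcome")
  work <- data[, work_cols, drop = FALSE]

  n_miss <- vapply(work, function(x) sum(is.na(x)), integer(1))
  if (any(n_miss == nrow(work))) {
    stop("variable(s) 100% missing, no information to impute: ",
         paste(names(work)[n_miss == nrow(work)], collapse = ", "),
         call. = FALSE)
  }
  targets <- names(n_miss)[n_miss > 0]
  if (!any(n_miss == 0)) {
    stop("at least one fully observed variable is required", call. = FALSE)
  }
  visit <- targets[order(n_miss[targets])]

  default_method <- function(v) {
    x <- work[[v]]
    if (is.character(x) || is.factor(x)) {
      if (length(unique(stats::na.omit(x))) <= 2) "logreg" else "polyreg"
    } else if (all(stats::na.omit(x) %in% c(0, 1))) {
      "logreg"
    } else {
      "pmm"
    }
  }
  method <- vapply(visit, default_method, character(1))
  if (!is.null(methods)) {
    method[intersect(names(methods), visit)] <-
      methods[intersect(names(methods), visit)]
  }

  if (length(targets) == 0) {
    message("no missing cells: returning ", m, " identical copies")
    return(structure(
      list(data = data, imputations = replicate(m, data, simplify = FALSE),
           m = m, maxit = maxit, seed = seed, k = k,
           visit_sequence = character(0), methods = character(0),
           trace = tibble::tibble()),
      class = "champ_mice"
    ))
  }

  miss_idx <- lapply(visit, function(v) which(is.na(work[[v]])))
  names(miss_idx) <- visit
  trace <- list()
  imputations <- vector("list", m)

  for (d in seq_len(m)) {
    cur <- work
    with_substream(seed, paste0("imp", d), {
      # initial fill: random draws from the observed margin
      for (v in visit) {
        obs_vals <- stats::na.omit(work[[v]])
        cur[[v]][miss_idx[[v]]] <-
          obs_vals[sample.int(length(obs_vals), length(miss_idx[[v]]),
                              replace = TRUE)]
      }
      for (it in seq_len(maxit)) {
        for (v in visit) {
          idx <- miss_idx[[v]]
          preds <- setdiff(work_cols, v)
          x_all <- impute_design(cur, preds)
          x_obs <- x_all[-idx, , drop = FALSE]
          x_mis <- x_all[idx, , drop = FALSE]
          y_obs <- work[[v]][-idx]
          filled <- switch(method[[v]],
            pmm = pmm_draw(y_obs, x_obs, x_mis, k, ridge),
            logreg = {
              if (is.character(y_obs)) {
                lev <- sort(unique(y_obs))
                z <- logreg_draw(as.numeric(y_obs == lev[length(lev)]),
                                 x_obs, x_mis)
                lev[z + 1]
              } else {
                logreg_draw(y_obs, x_obs, x_mis)
              }
            },
            polyreg = polyreg_draw(y_obs, x_obs, x_mis),
            stop("unknown imputation method: ", method[[v]], call. = FALSE)
          )
          cur[[v]][idx] <- filled
          imp_vals <- cur[[v]][idx]
          trace[[length(trace) + 1]] <- tibble::tibble(
            .imp = d, iteration = it, variable = v,
            mean = if (is.numeric(imp_vals)) mean(imp_vals) else NA_real_,
            sd = if (is.numeric(imp_vals)) stats::sd(imp_vals) else NA_real_
          )
        }
      }
    })
    full <- data
    full[, work_cols] <- cur
    imputations[[d]] <- full
  }

  structure(
    list(data = data, imputations = imputations, m = m, maxit = maxit,
         seed = seed, k = k, visit_sequence = visit, methods = method,
         trace = dplyr::bind_rows(trace)),
    class = "champ_mice"
  )
}

#' @export
print.champ_mice <- function(x, ...) {
  cat("Chained-equations imputation: m = ", x$m, ", ", x$maxit,
      " iteration(s)\n", sep = "")
  if (length(x$visit_sequence) > 0) {
    cat("  imputed: ", paste(x$visit_sequence, collapse = ", "), "\n",
        sep = "")
  } else {
    cat("  (no missing cells)\n")
  }
  invisible(x)
}

#' Extract completed datasets from an imputation
#'
#' @param x A `champ_mice` object.
#' @param i Optional index of a single completed dataset.
#' @return A list of tibbles, or one tibble when `i` is given.
#' @export
complete_datasets <- function(x, i = NULL) {
  stopifnot(inherits(x, "champ_mice"))
  if (is.null(i)) x$imputations else x$imputations[[i]]
}
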