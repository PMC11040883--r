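# Shared fixtures and independent oracles for the test suite.

# A small complete cohort with every candidate variable, no missing cells.
make_toy_cohort <- function(n = 200, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    age = round(runif(n, 18, 90), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    n_patients = sample(c(1, 1, 1, 2), n, replace = TRUE),
    gcs = sample(3:15, n, replace = TRUE),
    vehicle = sample(c("helicopter", "ground_unit"), n, replace = TRUE),
    rhythm_raw = sample(champr::champ_levels("rhythm_raw"), n,
                        replace = TRUE),
    resp_rate = round(runif(n, 8, 40)),
    sbp = round(runif(n, 70, 200)),
    spo2 = round(runif(n, 80, 100)),
    heart_rate = round(runif(n, 40, 160)),
    category = sample(champr::champ_levels("category"), n, replace = TRUE),
    time_to_hems = round(runif(n, 5, 60)),
    time_to_ems = round(runif(n, 3, 30)),
    facility = sample(c(0, 1), n, replace = TRUE, prob = c(0.9, 0.1)),
    outcome = rbinom(n, 1, 0.35)
  )
}

# Sort-based empirical quantile oracle (type-7 interpolation written out
# directly, independent of stats::quantile).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Direct truncated-power evaluation of the restricted cubic spline,
# written from the closed formula without reusing package code.
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  tp <- function(u) ifelse(u > 0, u^3, 0)
  cols <- list(x)
  for (j in 1:(k - 2)) {
    num <- tp(x - knots[j]) -
      tp(x - knots[k - 1]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1]) +
      tp(x - knots[k]) * (knots[k - 1] - knots[j]) /
        (knots[k] - knots[k - 1])
    cols[[j + 1]] <- num / (knots[k] - knots[1])^2
  }
  do.call(cbind, cols)
}

# O(n^2) pair-counting AUROC oracle, ties counted half.
oracle_auroc <- function(pred, outcome) {
  pos <- pred[outcome == 1]
  neg <- pred[outcome == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Expand a 2x2 table (events/non-events by exposure) into records.
expand_2x2 <- function(a, b, c, d) {
  # a: exposed events, b: unexposed events, c: exposed non-events,
  # d: unexposed non-events
  tibble::tibble(
    exposed = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    outcome = c(rep(1, a + b), rep(0, c + d))
  )
}
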