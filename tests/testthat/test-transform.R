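test_that("winsorization limits match a sort-based quantile oracle", {
  x <- sample(1:1000)
  lim <- winsor_limits(x, 0.01, 0.01)
  expect_equal(lim[1], oracle_quantile(x, 0.01))
  expect_equal(lim[2], oracle_quantile(x, 0.99))
  w <- winsorize(x, lim)
  expect_equal(min(w), lim[1])
  expect_equal(max(w), lim[2])
  expect_true(all(w[x > lim[1] & x < lim[2]] == x[x > lim[1] & x < lim[2]]))
  # constant vector: limits coincide and clipping is the identity
  expect_equal(winsor_limits(c(5, 5, 5, 5)), c(5, 5))
  expect_equal(winsorize(c(5, 5), c(5, 5)), c(5, 5))
  expect_error(winsor_limits(c(NA_real_, NA_real_)), "finite")
})

test_that("knots sit at the conventional quantiles and stay ordered", {
  set.seed(1)
  x <- runif(200000)
  k3 <- place_knots(x, 3)
  expect_equal(k3, c(0.10, 0.50, 0.90), tolerance = 0.01)
  expect_equal(k3, sapply(c(0.1, 0.5, 0.9), function(p) {
    oracle_quantile(x, p)
  }), tolerance = 1e-12)
  k4 <- place_knots(x, 4)
  expect_length(k4, 4)
  expect_true(all(diff(k4) > 0))
  expect_error(place_knots(c(1, 1, 2, 2), 3), "fewer knots")
})

test_that("spline basis matches the truncated-power oracle and is
           tail-linear", {
  knots <- c(2, 5, 7, 11)
  probes <- c(-3, 2.5, 6, 9.9, 25)
  b <- rcs_basis(probes, knots)
  expect_equal(ncol(b), 3)
  expect_equal(unname(b), unname(oracle_rcs(probes, knots)),
               tolerance = 1e-12)
  # beyond the last knot the function is linear: second differences vanish
  far <- seq(15, 40, by = 0.5)
  bf <- rcs_basis(far, knots)
  for (j in seq_len(ncol(bf))) {
    expect_lt(max(abs(diff(diff(bf[, j])))), 1e-8)
  }
  # three knots give exactly two columns
  expect_equal(ncol(rcs_basis(probes, c(1, 4, 9))), 2)
  expect_error(rcs_basis(probes, c(5, 2, 7)), "increasing")
})

test_that("the full design has the documented block structure", {
  co <- make_toy_cohort(400)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr <- fit_transform(rows, scr)
  X <- build_design(rows, tr)
  expect_equal(ncol(X), 30) # intercept + 29 predictor columns
  expect_equal(colnames(X)[1], "(Intercept)")
  block_size <- function(v) length(grep(paste0("^", v), colnames(X)))
  expect_equal(block_size("age"), 3)
  expect_equal(block_size("sbp"), 3)
  expect_equal(block_size("gcs"), 2)
  expect_equal(block_size("category_"), 8)
  expect_equal(block_size("rhythm_binary"), 1)
  expect_equal(sum(grepl("^sex_male$|^vehicle_ground$|^facility_yes$",
                         colnames(X))), 3)
})

test_that("subsets exclude blocks without disturbing the rest", {
  co <- make_toy_cohort(300)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr <- fit_transform(rows, scr)
  full <- build_design(rows, tr)
  noh <- build_design(rows, tr, setdiff(scr$retained, "heart_rate"))
  expect_false(any(grepl("heart_rate", colnames(noh))))
  shared <- setdiff(colnames(noh), "(Intercept)")
  expect_equal(noh[, shared], full[, shared])
})

test_that("design construction is batch-invariant and frozen at scoring", {
  co <- make_toy_cohort(100)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr <- fit_transform(rows, scr)
  X <- build_design(rows, tr)
  X2 <- rbind(build_design(rows[1:40, ], tr),
              build_design(rows[41:100, ], tr))
  expect_equal(unname(X), unname(X2))
  # transforming the training data twice yields identical matrices
  expect_equal(build_design(rows, tr), X)
  # missing cell inside the subset is a routing error
  rows$sbp[5] <- NA
  expect_error(build_design(rows, tr), "routed")
})

test_that("winsorization commutes with record permutation", {
  co <- make_toy_cohort(250)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  tr1 <- fit_transform(rows, scr)
  perm <- sample.int(nrow(rows))
  tr2 <- fit_transform(rows[perm, ], scr)
  expect_equal(tr1$limits, tr2$limits)
  expect_equal(tr1$knots, tr2$knots)
  expect_equal(build_design(rows, tr1)[perm, ],
               build_design(rows[perm, ], tr2))
})
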