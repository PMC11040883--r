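test_that("subset enumeration covers the full power set in fixed order", {
  m5 <- enumerate_subsets(champ_droppable())
  expect_length(m5, 32)
  expect_equal(m5[1], "11111")
  expect_equal(m5[32], "00000")
  expect_false(anyDuplicated(m5) > 0)
  # descending popcount ordering
  pc <- nchar(gsub("0", "", m5))
  expect_true(all(diff(pc) <= 0))
  expect_length(enumerate_subsets(character(0)), 1)
  m3 <- enumerate_subsets(c("a", "b", "c"))
  expect_length(m3, 8)
  expect_false(anyDuplicated(m3) > 0)
  expect_error(enumerate_subsets(c("a", "a")), "duplicate")
})

test_that("the full-mask submodel equals a directly fitted model", {
  co <- make_toy_cohort(900)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  ens <- build_ensemble(list(rows), scr)
  expect_length(ens$models, 32)
  direct <- fit_pooled(list(rows), ens$transform)
  expect_equal(coef(ens$models[["11111"]]), coef(direct),
               tolerance = 1e-10)
  # every submodel's coefficient length matches its mask's design
  for (msk in names(ens$models)) {
    fit <- ens$models[[msk]]
    expect_equal(length(coef(fit)),
                 ncol(build_design(rows[1, ], ens$transform, fit$subset)))
  }
})

test_that("selection follows the availability pattern exactly", {
  co <- make_toy_cohort(6)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  ens <- build_ensemble(list(derive_model_variables(make_toy_cohort(800),
                                                    scr)), scr)
  sel <- select_model(ens, rows)
  expect_true(all(sel$mask == "11111"))
  rows$heart_rate[2] <- NA
  rows$gcs[3] <- NA
  rows$sbp[3] <- NA
  sel <- select_model(ens, rows)
  expect_equal(sel$mask[2], "10111") # order: sbp, hr, spo2, gcs, rhythm
  expect_equal(sel$mask[3], "01101")
  rows[4, champ_droppable()] <- NA
  expect_equal(select_model(ens, rows)$mask[4], "00000")
  # a missing non-droppable variable makes the record unscorable
  rows$age[5] <- NA
  expect_error(select_model(ens, rows), "age")
  sel <- select_model(ens, rows, on_unscorable = "na")
  expect_true(is.na(sel$mask[5]))
  expect_match(sel$reason[5], "missing non-droppable: age")
})

test_that("predictions match a hand-evaluated linear predictor", {
  # a tiny hand-written registry: one droppable variable, two models
  scr <- default_screening()
  co <- make_toy_cohort(700)
  rows <- derive_model_variables(co, scr)
  ens <- build_ensemble(list(rows), scr, droppable = "gcs")
  expect_length(ens$models, 2)
  rec <- rows[3, ]
  fit <- ens$models[["1"]]
  xx <- build_design(rec, ens$transform, fit$subset)
  eta <- sum(xx[1, ] * coef(fit)[colnames(xx)])
  expect_equal(predict(ens, rec)$p, exp(eta) / (1 + exp(eta)),
               tolerance = 1e-12)
  # batch scoring equals record-by-record scoring
  batch <- predict(ens, rows[1:10, ])
  single <- vapply(1:10, function(i) predict(ens, rows[i, ])$p, numeric(1))
  expect_equal(batch$p, single)
})

test_that("excluded variables cannot influence predictions", {
  co <- make_toy_cohort(800)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  ens <- build_ensemble(list(rows), scr)
  rec <- rows[5, ]
  rec$heart_rate <- NA
  p1 <- predict(ens, rec)$p
  rec2 <- rows[5, ]
  rec2$heart_rate <- NA
  p2 <- predict(ens, rec2)$p
  expect_equal(p1, p2)
  # complete cases route to the full model: identical to direct prediction
  full_p <- champr:::predict_fit(ens$models[["11111"]], rows[1:20, ])
  expect_equal(predict(ens, rows[1:20, ])$p, full_p)
})

test_that("the JSON registry round-trips predictions", {
  co <- make_toy_cohort(700)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  ens <- build_ensemble(list(rows), scr)
  probe <- rows[1:50, ]
  probe$gcs[1:10] <- NA
  probe$sbp[5:15] <- NA
  before <- predict(ens, probe, on_unscorable = "na")$p
  path <- withr::local_tempfile(fileext = ".json")
  export_registry(ens, path)
  ens2 <- import_registry(path)
  after <- predict(ens2, probe, on_unscorable = "na")$p
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("registry validation rejects incomplete or foreign files", {
  co <- make_toy_cohort(700)
  scr <- default_screening()
  rows <- derive_model_variables(co, scr)
  ens <- build_ensemble(list(rows), scr, droppable = c("gcs", "sbp"))
  path <- withr::local_tempfile(fileext = ".json")
  export_registry(ens, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obj$models[[4]] <- NULL
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  expect_error(import_registry(path), "2\\^2")
  obj$schema_version <- "9.9"
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  expect_error(import_registry(path), "schema version")
  writeLines('{"schema": "something-else"}', path)
  expect_error(import_registry(path), "not a champ registry")
})
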