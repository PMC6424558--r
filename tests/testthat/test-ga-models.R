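# Model hierarchy: design-matrix contracts, penalised fitting, prediction
# with pooled imputations, recalibration, serialisation round trip.

test_that("model specs enforce the hierarchy's term structure", {
  s1 <- model_spec(1)
  expect_identical(s1$clinical_terms, c("sex", "multiple_birth", "birthweight_g"))
  expect_length(s1$analyte_terms, 0)
  expect_identical(nrow(s1$interaction_pairs), 0L)
  s2 <- model_spec(2)
  expect_false("birthweight_g" %in% s2$clinical_terms)
  expect_true(all(c("sex", "multiple_birth") %in% s2$clinical_terms))
  s3 <- model_spec(3)
  expect_true("birthweight_g" %in% s3$clinical_terms)
  expect_identical(s3$analyte_terms, sort(analyte_panel()$name))
  # interaction pairs must reference declared analytes
  expect_error(model_spec(2, analyte_terms = c("ALA", "TSH"),
                          interaction_pairs = rbind(c("ALA", "TYR"))),
               "undeclared")
})

test_that("design matrices have the documented columns and order", {
  co <- tiny_cohort(n = 60, seed = 2, missing_rate = 0)
  rec <- co$records
  d1 <- build_design_matrix(rec, model_spec(1))
  expect_identical(colnames(d1$X), c("sex", "multiple_birth", "birthweight_g"))
  # p analytes with all pairs: 2 + p + p(p-1)/2 columns
  terms <- c("ALA", "C5", "TSH", "TYR")
  d2 <- build_design_matrix(rec, model_spec(2, analyte_terms = terms,
                                            interaction_pairs = "all"))
  expect_identical(ncol(d2$X), 2L + 4L + 6L)
  expect_identical(colnames(d2$X)[1:2], c("sex", "multiple_birth"))
  expect_identical(colnames(d2$X)[3:6], terms)   # alphabetical
  expect_identical(colnames(d2$X)[7], "ALA:C5")  # lexicographic pairs
  # standardized continuous columns: mean 0, sd 1 on the training set
  cont <- terms
  expect_true(all(abs(colMeans(d2$X[, cont])) < 1e-9))
  expect_true(all(abs(apply(d2$X[, cont], 2, sd) - 1) < 1e-9))
  # binary codes
  expect_setequal(unique(d1$X[, "sex"]), c(0, 1))
})

test_that("missing analytes in the design are a named error", {
  co <- tiny_cohort(n = 20, seed = 3, missing_rate = 0)
  co$records$ALA[4] <- NA_real_
  err <- expect_error(build_design_matrix(co$records, model_spec(3)))
  expect_match(conditionMessage(err), "ALA")
  expect_match(conditionMessage(err), co$records$sample_id[4], fixed = TRUE)
})

test_that("noiseless linear signal is recovered almost exactly", {
  co <- tiny_cohort(n = 500, seed = 61, missing_rate = 0,
                    paired_fraction = 0, unpaired_heel_fraction = 1)
  rec <- co$records
  active <- c("ALA", "C5", "HBF_HBA_RATIO", "TSH", "TYR")
  betas <- c(0.3, -0.4, -0.6, 0.25, 0.35)
  Z <- scale(as.matrix(rec[, active]))
  rec$ga_obs_weeks <- as.numeric(39 + Z %*% betas)
  spec <- model_spec(2, analyte_terms = active, interaction_pairs = "none")
  idx <- seq_len(400)
  d <- build_design_matrix(rec[idx, ], spec)
  fit <- fit_ga_model(d, rec$ga_obs_weeks[idx], spec, seed = 7)
  est <- predict_ga(fit, rec[-idx, ])
  expect_lt(rmse(est$pooled, est$observed), 0.05)
  expect_identical(sign(fit$coefficients[active]), sign(setNames(betas, active)))
})

test_that("null outcomes collapse to the training mean", {
  co <- tiny_cohort(n = 300, seed = 62, missing_rate = 0)
  rec <- co$records
  set.seed(1)
  rec$ga_obs_weeks <- rnorm(nrow(rec), 39, 1)  # independent of predictors
  spec <- model_spec(2, analyte_terms = strong_analytes(),
                     interaction_pairs = "none")
  d <- build_design_matrix(rec, spec)
  fit <- fit_ga_model(d, rec$ga_obs_weeks, spec, seed = 8)
  est <- predict_ga(fit, rec)
  expect_true(all(abs(est$pooled - mean(rec$ga_obs_weeks)) < 0.1))
})

test_that("fitting is deterministic given the seed", {
  co <- tiny_cohort(n = 200, seed = 63, missing_rate = 0)
  spec <- model_spec(3)
  d <- build_design_matrix(co$records, spec)
  f1 <- fit_ga_model(d, co$records$ga_obs_weeks, spec, seed = 123)
  f2 <- fit_ga_model(d, co$records$ga_obs_weeks, spec, seed = 123)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$intercept, f2$intercept)
})

test_that("degenerate fits fail loudly; zero-variance columns drop", {
  co <- tiny_cohort(n = 100, seed = 64, missing_rate = 0)
  spec <- model_spec(1)
  d <- build_design_matrix(co$records, spec)
  expect_error(fit_ga_model(d, rep(39, 100), spec), "constant")
  co$records$multiple_birth <- FALSE
  d2 <- build_design_matrix(co$records, spec)
  expect_warning(fit_ga_model(d2, co$records$ga_obs_weeks, spec, seed = 1),
                 "multiple_birth")
})

test_that("an intercept-only model predicts its intercept everywhere", {
  co <- tiny_cohort(n = 30, seed = 65, missing_rate = 0)
  est <- predict_ga(constant_model(39), co$records)
  expect_true(all(est$pooled == 39))
  expect_equal(est$residual, 39 - co$records$ga_obs_weeks)
})

test_that("pooled prediction over m identical copies equals single-copy", {
  co <- tiny_cohort(n = 50, seed = 66, missing_rate = 0)
  spec <- model_spec(3)
  d <- build_design_matrix(co$records, spec)
  # a 50-infant draw can have no multiples; the zero-variance drop is benign
  fit <- suppressWarnings(fit_ga_model(d, co$records$ga_obs_weeks, spec,
                                       seed = 2))
  single <- predict_ga(fit, co$records)
  imp <- impute_missing(co, m = 5, seed = 9)  # no missing: identical copies
  pooled <- predict_ga(fit, imp)
  expect_identical(pooled$pooled, single$pooled)
  expect_identical(ncol(pooled$per_imputation), 5L)
})

test_that("prediction clipping is off by default and clips when asked", {
  co <- tiny_cohort(n = 30, seed = 67, missing_rate = 0)
  m <- constant_model(55)
  expect_true(all(predict_ga(m, co$records)$pooled == 55))
  expect_true(all(predict_ga(m, co$records, clip = c(28, 43))$pooled == 43))
})

test_that("recalibration inverts shifts and shrinkage", {
  obs <- seq(34, 42, length.out = 60)
  # predictions equal observed: identity calibration
  ident <- recalibrate(make_estimates(obs, obs))
  expect_equal(ident$slope, 1, tolerance = 1e-10)
  expect_equal(ident$intercept, 0, tolerance = 1e-8)
  expect_equal(ident$adjusted$pooled, obs)
  # pure +1wk shift: adjusted equals observed exactly
  shift <- recalibrate(make_estimates(obs + 1, obs))
  expect_equal(shift$adjusted$pooled, obs, tolerance = 1e-10)
  # slope-0.8 shrinkage toward 39: recovered slope ~ 1/0.8, RMSE improves
  set.seed(4)
  noisy_obs <- rnorm(300, 39, 1.5)
  shrunk <- 39 + 0.8 * (noisy_obs - 39) + rnorm(300, 0, 0.2)
  rc <- recalibrate(make_estimates(shrunk, noisy_obs))
  expect_equal(rc$slope, 1 / 0.8, tolerance = 0.1)
  expect_lt(rmse(rc$adjusted$pooled, noisy_obs), rmse(shrunk, noisy_obs))
  # contracts
  expect_error(recalibrate(make_estimates(c(39, 39.5), c(39, 39.5))), "3 samples")
  expect_error(recalibrate(make_estimates(rep(39, 10), obs[1:10])),
               "zero-variance")
})

test_that("models survive a JSON round trip to 1e-12 weeks", {
  co <- tiny_cohort(n = 150, seed = 68, missing_rate = 0)
  spec <- model_spec(3)
  d <- build_design_matrix(co$records, spec)
  fit <- fit_ga_model(d, co$records$ga_obs_weeks, spec, seed = 3)
  f <- tempfile(fileext = ".json")
  write_ga_model(fit, f)
  back <- read_ga_model(f)
  p1 <- predict_ga(fit, co$records)$pooled
  p2 <- predict_ga(back, co$records)$pooled
  expect_lt(max(abs(p1 - p2)), 1e-12)
  unlink(f)
})
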