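# Validation metrics: RMSE, within-k accuracy, residual diagnostics, ROC/AUC
# against the pairwise oracle and pROC, stratified reporting, Table-1 summary.

test_that("rmse matches hand arithmetic and rejects bad input", {
  obs <- c(38, 39, 40, 41)
  expect_identical(rmse(obs, obs), 0)
  expect_equal(rmse(obs + c(1, -1, 1, -1), obs), 1.0)
  expect_equal(rmse(obs + c(2, 0, 0, 0), obs), 1.0)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "mismatch")
  expect_error(rmse(c(1, NA), c(1, 2)), "finite")
})

test_that("within_k uses a closed interval and one-decimal percents", {
  obs <- c(39, 39, 39)
  pred <- c(40, 38.5, 41.5)   # residuals +1, -0.5, +2.5
  w1 <- within_k(pred, obs, 1)
  expect_identical(w1$count, 2L)
  expect_equal(w1$percent, 66.7)
  w2 <- within_k(pred, obs, 2)
  expect_identical(w2$count, 2L)
  expect_error(within_k(pred, obs, 0), "k_weeks > 0")
  expect_error(within_k(numeric(0), numeric(0), 1), "empty")
})

test_that("within-k counts are monotone in k on random estimate sets", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    obs <- rnorm(n, 39, 1.5)
    pred <- obs + rnorm(n, 0, runif(1, 0.3, 2))
    c1 <- within_k(pred, obs, 1)$count
    c2 <- within_k(pred, obs, 2)$count
    expect_lte(c1, c2)
    expect_lte(rmse(pred, obs), Inf)
    # Jensen: RMSE dominates mean absolute residual
    expect_gte(rmse(pred, obs), mean(abs(pred - obs)) - 1e-12)
  }
})

test_that("residual tables categorise GA and average per category", {
  obs <- c(34, 36.9, 37, 42, 42.1, 43)
  pred <- obs + c(1, 1, 0, 0, -2, -2)
  est <- make_estimates(pred, obs)
  rt <- residual_table(est)
  expect_identical(rt$ga_category, c("<37", "<37", "37-42", "37-42", ">42", ">42"))
  cm <- attr(rt, "category_means")
  expect_equal(cm$mean_residual, c(1, 0, -2))
  expect_equal(cm$n, c(2L, 2L, 2L))
  # single sample: one row, category mean equals its residual
  one <- residual_table(make_estimates(40.5, 39.5))
  expect_identical(nrow(one), 1L)
  cm1 <- attr(one, "category_means")
  expect_equal(cm1$mean_residual[cm1$category == "37-42"], 1.0)
})

test_that("shrunken predictions show the regression-to-mean pattern", {
  set.seed(2)
  obs <- rnorm(400, 39, 2)
  shrunk <- 39 + 0.6 * (obs - 39) + rnorm(400, 0, 0.3)
  cm <- attr(residual_table(make_estimates(shrunk, obs)), "category_means")
  expect_gt(cm$mean_residual[cm$category == "<37"], 0)
  expect_lt(cm$mean_residual[cm$category == ">42"], 0)
})

test_that("AUC handles the degenerate and perfect cases", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "undefined")
  r <- roc_auc(c(1, 2, 3, 4, 2, 3), c(F, F, T, T, T, F))
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_true(all(r$ci >= 0 & r$ci <= 1))
  # curve is monotone nondecreasing and anchored at (0,0) and (1,1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
})

test_that("AUC agrees with pROC and with the bootstrap CI option", {
  set.seed(77)
  scores <- round(rnorm(120), 1)   # rounding forces ties
  labels <- runif(120) < plogis(scores)
  if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(ours$ci[1], as.numeric(ci[1]), tolerance = 1e-6)
  expect_equal(ours$ci[2], as.numeric(ci[3]), tolerance = 1e-6)
  boot <- roc_auc(scores, labels, ci_method = "bootstrap", boot_reps = 400,
                  boot_seed = 5)
  expect_true(boot$ci[1] <= boot$auc && boot$auc <= boot$ci[2])
  boot2 <- roc_auc(scores, labels, ci_method = "bootstrap", boot_reps = 400,
                   boot_seed = 5)
  expect_identical(boot$ci, boot2$ci)
})

test_that("pooled ROC averages per-imputation AUCs and CIs", {
  set.seed(31)
  obs <- c(rnorm(40, 35, 1), rnorm(160, 39.5, 1.2))
  per <- sapply(1:5, function(k) obs + rnorm(200, 0, 1))
  est <- make_estimates(per, obs)
  r <- roc_auc_mi(est)
  expect_equal(r$auc, mean(r$per_imputation_auc))
  expect_length(r$per_imputation_auc, 5)
  expect_true(r$ci[1] < r$auc && r$auc < r$ci[2])
  expect_gt(r$auc, 0.8)
})

test_that("stratified reports nest SGA strata and match hand-computed RMSE", {
  co <- tiny_cohort(n = 400, seed = 71, missing_rate = 0)
  chart <- default_reference_chart(tiny_config(n = 400, seed = 71))
  rec <- co$records
  set.seed(5)
  pred <- rec$ga_obs_weeks + rnorm(nrow(rec), 0, 1)
  est <- make_estimates(pred, rec$ga_obs_weeks, sample_id = rec$sample_id)
  rep_ <- stratified_report(est, rec, chart)
  expect_setequal(rep_$stratum, c("overall", "SGA10", "SGA3", "<2500g",
                                  ">=37wk", "32-36wk", "<32wk"))
  n_of <- function(s) rep_$n[rep_$stratum == s]
  expect_lte(n_of("SGA3"), n_of("SGA10"))
  expect_identical(n_of("overall"), nrow(rec))
  expect_identical(n_of(">=37wk") + n_of("32-36wk") + n_of("<32wk"), nrow(rec))
  # hand-computed overall metrics
  expect_equal(rep_$rmse_weeks[rep_$stratum == "overall"],
               rmse(pred, rec$ga_obs_weeks))
  expect_identical(rep_$within2_count[rep_$stratum == "overall"],
                   sum(abs(pred - rec$ga_obs_weeks) <= 2))
  # empty strata carry n = 0 and NA metrics
  if (n_of("<32wk") == 0) {
    expect_true(is.na(rep_$rmse_weeks[rep_$stratum == "<32wk"]))
  }
  sga10 <- classify_sga(rec$birthweight_g, rec$ga_obs_weeks, rec$sex,
                        chart, "P10")
  expect_equal(rep_$rmse_weeks[rep_$stratum == "SGA10"],
               rmse(pred[sga10], rec$ga_obs_weeks[sga10]))
})

test_that("cohort summaries reproduce Table-1-style arithmetic", {
  co <- tiny_cohort(n = 500, seed = 72)
  heel <- co
  heel$records <- co$records[co$records$sample_type == "heel", ]
  s <- summarize_cohort(heel)
  n <- nrow(heel$records)
  term_n <- sum(heel$records$ga_obs_weeks >= 37)
  expect_equal(s$percent[s$section == "ga_category" & s$level == ">=37wk"],
               round(100 * term_n / n, 1))
  expect_equal(s$n[s$section == "birthweight_category" & s$level == "<2500g"],
               sum(heel$records$birthweight_g < 2500))
  expect_equal(s$mean[s$section == "ga_weeks"],
               mean(heel$records$ga_obs_weeks))
  # single male term singleton: 100% everywhere relevant
  one <- co
  one$records <- co$records[which(co$records$sex == "male" &
                                    co$records$ga_obs_weeks >= 37)[1], ]
  s1 <- summarize_cohort(one)
  expect_equal(s1$percent[s1$section == "sex" & s1$level == "male"], 100.0)
  expect_equal(s1$percent[s1$section == "ga_category" & s1$level == ">=37wk"],
               100.0)
  expect_error(summarize_cohort(simulate_cohort(simulation_config(n_infants = 0))),
               "empty")
})
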