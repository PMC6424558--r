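# Preterm discrimination (ROC/AUC at the dichotomous 37-week threshold, CIs
# pooled over imputations) and calibration-slope recalibration of the full
# model on the external cohort.

source("analysis/00_config.R")

cfg <- read_pipeline_config(file.path(OUT, "config.yaml"))
screened <- read_cohort(file.path(OUT, "external_screened.csv"))
imp_dir <- file.path(OUT, "imputations")
copies <- lapply(sprintf("imputation_%02d.csv", seq_len(cfg$m_imputations)),
                 function(f) read_cohort(file.path(imp_dir, f))$records)
imp <- structure(list(copies = copies, m = cfg$m_imputations,
                      seed = NA_integer_, method = "chained_ridge_noise",
                      input_digest = NA_character_),
                 class = "imputation_set")

table3 <- NULL
recal <- NULL
for (st in cfg$sample_types) {
  idx <- screened$records$sample_type == st
  imp_st <- metabGA:::subset_imputation_set(imp, idx)
  for (mid in cfg$models) {
    model <- read_ga_model(file.path(OUT, sprintf("model_%s_model%d.json",
                                                  st, mid)))
    est <- predict_ga(model, imp_st)
    r <- roc_auc_mi(est)
    table3 <- rbind(table3, data.frame(
      sample_type = st, model_id = mid, auc = round(r$auc, 3),
      ci_lower = round(r$ci[1], 3), ci_upper = round(r$ci[2], 3)))
    if (mid == 3) {
      rc <- recalibrate(est)
      recal <- rbind(recal, data.frame(
        sample_type = st,
        calibration_intercept = rc$intercept,
        calibration_slope = rc$slope,
        rmse_raw = round(rmse(est$pooled, est$observed), 2),
        rmse_recalibrated = round(rmse(rc$adjusted$pooled, est$observed), 2)))
    }
  }
}
write.csv(table3, file.path(OUT, "table3_auc.csv"), row.names = FALSE)
write.csv(recal, file.path(OUT, "calibration.csv"), row.names = FALSE)

cat("preterm discrimination (<37 wk):\n")
print(table3, row.names = FALSE)
cat("\ncalibration of the full model (observed ~ predicted):\n")
print(recal, row.names = FALSE)
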