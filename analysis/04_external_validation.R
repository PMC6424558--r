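# Score the external cohort with the fitted models, pooling predictions over
# the 10 imputations, and report the Table-2-style validation surface:
# overall and stratified (SGA10 / SGA3 / <2500 g / GA category) RMSE and
# within-1/2-week accuracy, plus residual tables by observed GA.

source("analysis/00_config.R")

cfg <- read_pipeline_config(file.path(OUT, "config.yaml"))
screened <- read_cohort(file.path(OUT, "external_screened.csv"))
chart <- read_reference_chart(file.path(OUT, "reference_chart.csv"))
imp_dir <- file.path(OUT, "imputations")
copies <- lapply(sprintf("imputation_%02d.csv", seq_len(cfg$m_imputations)),
                 function(f) read_cohort(file.path(imp_dir, f))$records)
imp <- structure(list(copies = copies, m = cfg$m_imputations,
                      seed = NA_integer_, method = "chained_ridge_noise",
                      input_digest = NA_character_),
                 class = "imputation_set")

table2 <- NULL
for (st in cfg$sample_types) {
  idx <- screened$records$sample_type == st
  rec <- screened$records[idx, ]
  imp_st <- metabGA:::subset_imputation_set(imp, idx)
  for (mid in cfg$models) {
    model <- read_ga_model(file.path(OUT, sprintf("model_%s_model%d.json",
                                                  st, mid)))
    est <- predict_ga(model, imp_st)
    write.csv(data.frame(sample_id = est$sample_id, observed = est$observed,
                         pooled = est$pooled, residual = est$residual),
              file.path(OUT, sprintf("scores_%s_model%d.csv", st, mid)),
              row.names = FALSE)
    rep2 <- cbind(sample_type = st, stratified_report(est, rec, chart))
    table2 <- rbind(table2, rep2)
    rt <- residual_table(est)
    write.csv(rt, file.path(OUT, sprintf("residuals_%s_model%d.csv", st, mid)),
              row.names = FALSE)
    cm <- attr(rt, "category_means")
    cat(sprintf("%s model %d: mean residual %.2f wk (<37 wk, n=%d), %.2f wk (37-42)\n",
                st, mid, cm$mean_residual[1], cm$n[1], cm$mean_residual[2]))
  }
}
table2$rmse_weeks <- round(table2$rmse_weeks, 2)
write.csv(table2, file.path(OUT, "table2_performance.csv"), row.names = FALSE)

ov <- table2[table2$stratum == "overall", ]
cat("\noverall external performance:\n")
print(ov[, c("sample_type", "model_id", "n", "rmse_weeks",
             "within1_percent", "within2_percent")], row.names = FALSE)
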