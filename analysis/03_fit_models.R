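# Fit the three-model hierarchy on the development cohort, separately for
# heel and cord samples: Model 1 (sex, multiple birth, birthweight),
# Model 2 (sex, multiple birth, analytes + pairwise interactions among the
# strong predictors), Model 3 (everything). Elastic net, 10-fold CV.

source("analysis/00_config.R")

cfg <- read_pipeline_config(file.path(OUT, "config.yaml"))
train <- read_cohort(file.path(OUT, "train_cohort.csv"))

for (st in cfg$sample_types) {
  rec <- train$records[train$records$sample_type == st, ]
  for (mid in cfg$models) {
    spec <- model_spec(mid, panel = train$panel,
                       interaction_pairs = cfg$interaction_pairs,
                       alpha = cfg$alpha)
    design <- build_design_matrix(rec, spec)
    fit <- fit_ga_model(design, rec$ga_obs_weeks, spec,
                        seed = metabGA:::child_seed(
                          metabGA:::child_seed(cfg$seed, "fit"), mid))
    write_ga_model(fit, file.path(OUT, sprintf("model_%s_model%d.json",
                                               st, mid)))
    active <- names(which(fit$coefficients != 0))
    cat(sprintf("%s model %d: %d/%d active terms, CV RMSE %.2f wk (lambda %.4g)\n",
                st, mid, length(active), length(fit$coefficients),
                fit$training$cv_rmse, fit$training$lambda))
    if (mid == 3) {
      main_active <- setdiff(active, grep(":", active, value = TRUE))
      cat("  active main effects:",
          paste(head(sort(main_active), 12), collapse = ", "), "...\n")
    }
  }
}
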