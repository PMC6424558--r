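# Screen the external cohort (drop fully missing samples, flag the rest for
# imputation) and multiply impute the remaining missing analyte values
# (m = 10 chained-equation copies).

source("analysis/00_config.R")

cfg <- read_pipeline_config(file.path(OUT, "config.yaml"))
external <- read_cohort(file.path(OUT, "external_cohort.csv"))

screening <- screen_samples(external)
print(screening)
write.csv(screening$excluded, file.path(OUT, "excluded_samples.csv"),
          row.names = FALSE)

imp <- impute_missing(screening$cohort, m = cfg$m_imputations,
                      seed = metabGA:::child_seed(cfg$seed, "impute"))
print(imp)
write_imputation_set(imp, file.path(OUT, "imputations"))
write_cohort(screening$cohort, file.path(OUT, "external_screened.csv"))

cat(sprintf("flagged for imputation: %d of %d kept samples\n",
            length(screening$flagged_for_imputation), length(screening$kept)))
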