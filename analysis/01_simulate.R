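# Simulate the two cohorts the validation study needs: a development cohort
# (every infant contributes paired heel and cord samples, no missingness --
# the models are refit on it) and an external field cohort (mostly cord
# samples, sparse missingness, slightly wider gestational-age spread).

source("analysis/00_config.R")

cfg <- analysis_config()
write_pipeline_config(cfg, file.path(OUT, "config.yaml"))

train <- simulate_cohort(
  metabGA:::sim_config_from(cfg$train,
                            metabGA:::child_seed(cfg$seed, "simulate_train")))
external <- simulate_cohort(
  metabGA:::sim_config_from(cfg$external,
                            metabGA:::child_seed(cfg$seed, "simulate_external")))

write_cohort(train, file.path(OUT, "train_cohort.csv"))
write_cohort(external, file.path(OUT, "external_cohort.csv"))
chart <- default_reference_chart(
  metabGA:::sim_config_from(cfg$external,
                            metabGA:::child_seed(cfg$seed, "simulate_external")))
write_reference_chart(chart, file.path(OUT, "reference_chart.csv"))

print(train)
print(external)

# Table-1-style characteristics of the external cohort, by sample type
table1 <- do.call(rbind, lapply(c("heel", "cord"), function(st) {
  sub <- external
  sub$records <- external$records[external$records$sample_type == st, ]
  cbind(sample_type = st, summarize_cohort(sub))
}))
write.csv(table1, file.path(OUT, "table1_characteristics.csv"),
          row.names = FALSE)

ga <- table1[table1$section == "ga_weeks", ]
cat(sprintf("external GA: heel %.1f +/- %.1f wk, cord %.1f +/- %.1f wk\n",
            ga$mean[1], ga$sd[1], ga$mean[2], ga$sd[2]))
pre <- table1[table1$section == "ga_category" & table1$level != ">=37wk", ]
cat(sprintf("preterm samples: heel %.1f%%, cord %.1f%%\n",
            sum(pre$percent[pre$sample_type == "heel"]),
            sum(pre$percent[pre$sample_type == "cord"])))
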