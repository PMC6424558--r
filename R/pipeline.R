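# End-to-end orchestration: simulate a development (training) cohort and an
# external validation cohort, screen and multiply impute the external data,
# fit the three-model hierarchy per sample type on the training data, score
# the external cohort with pooling across imputations, optionally
# recalibrate, and emit Table-1/2/3-style report files plus a run manifest.

#' Default pipeline configuration
#'
#' A nested list: global seed and pooling settings plus two simulation
#' configurations. `train` emulates a development cohort (heel and cord
#' samples from every infant, no missingness); `external` emulates a
#' field-validation cohort with sparse missingness and a slightly wider
#' gestational-age spread than training.
#'
#' @param seed global integer seed fanned out to per-stage child seeds.
#' @param n_train,n_external cohort sizes (infants).
#' @param m_imputations imputations for the external cohort (default 10).
#' @param models which of models 1:3 to fit.
#' @param sample_types which sample types to fit/score.
#' @param recalibrate also report calibration-slope-adjusted performance.
#' @param interaction_pairs passed to [model_spec()].
#' @param alpha elastic-net mixing parameter.
#' @param train,external named lists of [simulation_config()] overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 20190319, n_train = 5000,
                            n_external = 1500, m_imputations = 10,
                            models = 1:3,
                            sample_types = c("heel", "cord"),
                            recalibrate = FALSE,
                            interaction_pairs = "strong", alpha = 0.5,
                            train = list(), external = list()) {
  train_defaults <- list(n_infants = n_train, ga_mean_weeks = 39.3,
                         ga_sd_weeks = 1.5, preterm_target_fraction = 0.07,
                         paired_fraction = 1.0, missing_rate = 0)
  external_defaults <- list(n_infants = n_external, ga_mean_weeks = 39.0,
                            ga_sd_weeks = 1.7, preterm_target_fraction = 0.10,
                            paired_fraction = 0.42,
                            unpaired_heel_fraction = 0.054)
  cfg <- list(
    seed = as.integer(seed), m_imputations = m_imputations,
    models = models, sample_types = sample_types,
    recalibrate = recalibrate, interaction_pairs = interaction_pairs,
    alpha = alpha,
    train = utils::modifyList(train_defaults, train),
    external = utils::modifyList(external_defaults, external)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as structured text (YAML)
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

sim_config_from <- function(overrides, seed) {
  overrides$seed <- seed
  do.call(simulation_config, overrides)
}

subset_imputation_set <- function(imp, idx) {
  out <- imp
  out$copies <- lapply(imp$copies, function(cp) {
    r <- cp[idx, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate training and external cohorts; screen the
#' external cohort (fully missing samples are excluded); multiply impute its
#' remaining missing analytes; fit models per sample type on the training
#' cohort; score the external cohort pooling over imputations; optionally
#' recalibrate; compute cohort summaries, stratified performance, residual
#' tables and preterm ROC/AUC; write all report files and a run manifest to
#' `out_dir`. Fully reproducible from the config seed; report files are
#' byte-identical across reruns.
#'
#' @param config a [pipeline_config()] or path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @return A `run_manifest` (invisibly the full results list with `manifest`,
#'   `fits`, `scores`, `reports`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(
    config_digest = object_digest(unclass(config)),
    seeds = list(global = seed,
                 simulate_train = child_seed(seed, "simulate_train"),
                 simulate_external = child_seed(seed, "simulate_external"),
                 impute = child_seed(seed, "impute"),
                 fit = child_seed(seed, "fit")),
    generator_version = "1",
    started = format(Sys.time(), tz = "UTC"),
    outputs = character(), stages = list()
  )
  files <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      manifest$outputs <<- files
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }
  emit <- function(obj, fname, writer = utils::write.csv, ...) {
    path <- file.path(out_dir, fname)
    writer(obj, path, ...)
    files <<- c(files, fname)
    path
  }

  train_cfg <- sim_config_from(config$train, manifest$seeds$simulate_train)
  ext_cfg <- sim_config_from(config$external, manifest$seeds$simulate_external)
  train <- stage("simulate_train", simulate_cohort(train_cfg))
  external <- stage("simulate_external", simulate_cohort(ext_cfg))
  emit(train, "train_cohort.csv", write_cohort)
  emit(external, "external_cohort.csv", write_cohort)

  screening <- stage("screen", screen_samples(external))
  kept <- screening$cohort
  imp <- stage("impute",
               impute_missing(kept, m = config$m_imputations,
                              seed = manifest$seeds$impute))
  chart <- default_reference_chart(ext_cfg)
  emit(chart, "reference_chart.csv", write_reference_chart)

  fits <- list(); scores <- list()
  table2 <- NULL; table3 <- NULL; table1 <- NULL
  for (st in config$sample_types) {
    tr_rec <- train$records[train$records$sample_type == st, , drop = FALSE]
    ext_idx <- kept$records$sample_type == st
    ext_rec <- kept$records[ext_idx, , drop = FALSE]
    imp_st <- subset_imputation_set(imp, ext_idx)
    sub <- kept; sub$records <- ext_rec
    t1 <- summarize_cohort(sub)
    t1 <- cbind(sample_type = st, t1)
    table1 <- rbind(table1, t1)
    for (mid in config$models) {
      key <- sprintf("%s_model%d", st, mid)
      spec <- model_spec(mid, panel = train$panel,
                         interaction_pairs = config$interaction_pairs,
                         alpha = config$alpha)
      fit <- stage(paste0("fit_", key), {
        d <- build_design_matrix(tr_rec, spec)
        fit_ga_model(d, tr_rec$ga_obs_weeks, spec,
                     seed = child_seed(manifest$seeds$fit, mid))
      })
      fits[[key]] <- fit
      emit(fit, sprintf("model_%s.json", key), write_ga_model)
      est <- stage(paste0("score_", key), predict_ga(fit, imp_st))
      if (isTRUE(config$recalibrate)) {
        rc <- recalibrate(est)
        est <- rc$adjusted
        est$calibration <- c(intercept = rc$intercept, slope = rc$slope)
      }
      scores[[key]] <- est
      emit(data.frame(sample_id = est$sample_id, observed = est$observed,
                      pooled = est$pooled, residual = est$residual),
           sprintf("scores_%s.csv", key), row.names = FALSE)
      rep2 <- stratified_report(est, ext_rec, chart)
      rep2 <- cbind(sample_type = st, rep2)
      rep2$rmse_weeks <- round(rep2$rmse_weeks, 2)
      table2 <- rbind(table2, rep2)
      rt <- residual_table(est)
      emit(rt, sprintf("residuals_%s.csv", key), row.names = FALSE)
      roc <- stage(paste0("roc_", key), {
        if (sum(est$observed < 37) > 0 && sum(est$observed >= 37) > 0) {
          r <- roc_auc_mi(est)
          data.frame(sample_type = st, model_id = mid,
                     auc = round(r$auc, 3),
                     ci_lower = round(r$ci[1], 3),
                     ci_upper = round(r$ci[2], 3))
        } else {
          data.frame(sample_type = st, model_id = mid, auc = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_)
        }
      })
      table3 <- rbind(table3, roc)
    }
  }
  emit(table1, "table1_characteristics.csv", row.names = FALSE)
  emit(table2, "table2_performance.csv", row.names = FALSE)
  emit(table3, "table3_auc.csv", row.names = FALSE)
  emit(data.frame(sample_id = screening$excluded$sample_id,
                  reason = screening$excluded$reason),
       "excluded_samples.csv", row.names = FALSE)

  manifest$outputs <- files
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(manifest = manifest, config = config, screening = screening,
              fits = fits, scores = scores, chart = chart,
              tables = list(table1 = table1, table2 = table2,
                            table3 = table3))
  class(out) <- "pipeline_result"
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  t2 <- x$tables$table2
  ov <- t2[t2$stratum == "overall", c("sample_type", "model_id", "rmse_weeks",
                                      "within1_percent", "within2_percent")]
  print(ov, row.names = FALSE)
  invisible(x)
}
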