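# Table-style reporting: cohort characteristics (Table-1 analogue) and
# per-stratum model performance (Table-2 analogue). All metrics are computed
# per imputation and pooled: scalars by their mean, counts by the
# rounded-mean rule.

#' Per-stratum performance report
#'
#' One row per stratum: overall, SGA10, SGA3, birthweight < 2500 g, and
#' gestational-age categories (>= 37, 32 to 36+6, < 32 completed weeks).
#' Reports n, pooled RMSE (mean of per-imputation RMSEs), and pooled
#' within-1/within-2-week counts and percentages. Empty strata keep n = 0
#' with metrics set `NA` rather than fabricated.
#'
#' @param estimates a `ga_estimates` with observed GA.
#' @param records the scored cohort records (clinical covariates aligned with
#'   `estimates$sample_id`).
#' @param chart a `reference_chart` for the SGA strata.
#' @return data.frame: model_id, stratum, n, rmse_weeks, within1_count,
#'   within1_percent, within2_count, within2_percent.
#' @export
stratified_report <- function(estimates, records, chart) {
  stopifnot(identical(records$sample_id, estimates$sample_id))
  sga10 <- classify_sga(records$birthweight_g, records$ga_obs_weeks,
                        records$sex, chart, "P10")
  sga3 <- classify_sga(records$birthweight_g, records$ga_obs_weeks,
                       records$sex, chart, "P3")
  ga <- records$ga_obs_weeks
  strata <- list(
    overall = rep(TRUE, nrow(records)),
    SGA10 = sga10,
    SGA3 = sga3,
    "<2500g" = records$birthweight_g < 2500,
    ">=37wk" = ga >= 37,
    "32-36wk" = ga >= 32 & ga < 37,
    "<32wk" = ga < 32
  )
  rows <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    n <- sum(idx)
    if (n == 0) {
      return(data.frame(model_id = estimates$model_id, stratum = s, n = 0L,
                        rmse_weeks = NA_real_, within1_count = NA_integer_,
                        within1_percent = NA_real_, within2_count = NA_integer_,
                        within2_percent = NA_real_))
    }
    per <- estimates$per_imputation[idx, , drop = FALSE]
    obs <- estimates$observed[idx]
    rmses <- apply(per, 2, rmse, observed = obs)
    w1 <- within_k_mi(per, obs, 1)
    w2 <- within_k_mi(per, obs, 2)
    data.frame(model_id = estimates$model_id, stratum = s, n = n,
               rmse_weeks = pool_scalar(rmses),
               within1_count = w1$count, within1_percent = w1$percent,
               within2_count = w2$count, within2_percent = w2$percent)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort characteristics summary (Table-1 style)
#'
#' Counts and one-decimal percentages by sex, gestational-age category
#' (>= 37, 32 to 36+6, < 32 completed weeks), birthweight category
#' (cutpoints 1000 / 1500 / 2500 / 4000 g) and multiple birth; means and SDs
#' of gestational age, birthweight (overall, term-only, preterm-only) and
#' age at collection (overall, term, preterm).
#'
#' @param cohort a `cohort` (typically one sample type).
#' @return data.frame with columns section, level, n, percent, mean, sd.
#' @export
summarize_cohort <- function(cohort) {
  rec <- cohort$records
  if (nrow(rec) == 0) stop("cannot summarize an empty cohort")
  n <- nrow(rec)
  term <- rec$ga_obs_weeks >= 37
  count_row <- function(section, level, k) {
    data.frame(section = section, level = level, n = k,
               percent = fmt_pct(100 * k / n), mean = NA_real_, sd = NA_real_)
  }
  stat_row <- function(section, level, x) {
    data.frame(section = section, level = level, n = length(x),
               percent = NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  bw <- rec$birthweight_g
  bw_cat <- cut(bw, c(-Inf, 1000, 1500, 2500, 4000, Inf), right = FALSE,
                labels = c("<1000g", "1000-1499g", "1500-2499g",
                           "2500-3999g", ">=4000g"))
  out <- rbind(
    count_row("samples", "total", n),
    count_row("sex", "male", sum(rec$sex == "male")),
    count_row("sex", "female", sum(rec$sex == "female")),
    count_row("ga_category", ">=37wk", sum(term)),
    count_row("ga_category", "32-36wk",
              sum(rec$ga_obs_weeks >= 32 & rec$ga_obs_weeks < 37)),
    count_row("ga_category", "<32wk", sum(rec$ga_obs_weeks < 32)),
    do.call(rbind, lapply(rev(levels(bw_cat)), function(l) {
      count_row("birthweight_category", l, sum(bw_cat == l))
    })),
    count_row("birthweight_category", "<2500g", sum(bw < 2500)),
    count_row("multiple_birth", "yes", sum(rec$multiple_birth)),
    stat_row("ga_weeks", "overall", rec$ga_obs_weeks),
    stat_row("birthweight_g", "overall", bw),
    stat_row("birthweight_g", "term", bw[term]),
    stat_row("birthweight_g", "preterm", bw[!term]),
    stat_row("collection_age_h", "overall", rec$age_at_collection_h),
    stat_row("collection_age_h", "term", rec$age_at_collection_h[term]),
    stat_row("collection_age_h", "preterm", rec$age_at_collection_h[!term])
  )
  rownames(out) <- NULL
  out
}
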