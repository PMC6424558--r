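# External-validation surfaces: RMSE, within-+/-k-week accuracy, residual
# diagnostics by gestational-age category, and discrimination of the
# dichotomous preterm threshold (<37 wk) by ROC/AUC. The AUC is the midrank
# (Mann-Whitney) statistic; its default confidence interval uses the DeLong
# variance estimator.

#' Root mean square error of gestational-age predictions
#' @param predicted,observed equal-length numeric vectors (weeks).
#' @return RMSE in weeks.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0) stop("rmse of an empty vector")
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (!all(is.finite(predicted)) || !all(is.finite(observed))) {
    stop("rmse requires finite inputs")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Within-k-week accuracy
#'
#' Count and percentage of samples with `|predicted - observed| <= k`
#' (closed interval: a residual of exactly k weeks counts as within).
#' Percent is reported to one decimal.
#'
#' @param predicted,observed numeric vectors (weeks).
#' @param k_weeks positive tolerance in weeks.
#' @return list with `count` and `percent`.
#' @export
within_k <- function(predicted, observed, k_weeks) {
  if (length(predicted) == 0) stop("within_k of an empty vector")
  stopifnot(k_weeks > 0, length(predicted) == length(observed))
  count <- sum(abs(predicted - observed) <= k_weeks)
  list(count = count, percent = fmt_pct(100 * count / length(predicted)))
}

# per-imputation within-k counts pooled by the count rule
within_k_mi <- function(per_imputation, observed, k_weeks) {
  counts <- apply(per_imputation, 2, function(p) {
    sum(abs(p - observed) <= k_weeks)
  })
  n <- length(observed)
  count <- pool_count(counts)
  list(count = count, percent = fmt_pct(100 * count / n))
}

#' Residual table by gestational-age category
#'
#' Residual = predicted - observed. Categories: preterm (<37 wk), term
#' (37-42 wk inclusive), post-term (>42 wk); per-category mean residuals are
#' attached for residual-plot style diagnostics.
#'
#' @param estimates a `ga_estimates` with observed GA.
#' @return data.frame (sample_id, observed, pooled, residual, ga_category)
#'   with a `category_means` attribute (data.frame of category, n,
#'   mean_residual).
#' @export
residual_table <- function(estimates) {
  if (all(is.na(estimates$observed))) stop("observed GA required")
  cat_of <- function(ga) {
    ifelse(ga < 37, "<37", ifelse(ga <= 42, "37-42", ">42"))
  }
  tab <- data.frame(
    sample_id = estimates$sample_id,
    observed = estimates$observed,
    pooled = estimates$pooled,
    residual = estimates$residual,
    ga_category = cat_of(estimates$observed),
    stringsAsFactors = FALSE
  )
  lev <- c("<37", "37-42", ">42")
  cm <- data.frame(
    category = lev,
    n = vapply(lev, function(l) sum(tab$ga_category == l), integer(1)),
    mean_residual = vapply(lev, function(l) {
      r <- tab$residual[tab$ga_category == l]
      if (length(r)) mean(r) else NA_real_
    }, numeric(1)),
    row.names = NULL
  )
  attr(tab, "category_means") <- cm
  tab
}

mw_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

delong_var <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  n1 <- length(pos)
  n0 <- length(neg)
  # placement values
  v10 <- vapply(pos, function(s) (sum(s > neg) + 0.5 * sum(s == neg)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n1,
                numeric(1))
  stats::var(v10) / n1 + stats::var(v01) / n0
}

#' ROC curve and AUC for preterm discrimination
#'
#' The score convention is "higher = more preterm-like"; when discriminating
#' preterm birth from pooled GA predictions, pass the negated prediction.
#' AUC is the trapezoidal area of the empirical ROC with midrank tie
#' handling and equals the Mann-Whitney U statistic divided by `n1 * n0`.
#' The 95% CI uses the DeLong variance estimator by default, or a seeded
#' stratified bootstrap.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive class, preterm).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_reps,boot_seed bootstrap replicates and seed.
#' @param conf_level confidence level (default 0.95).
#' @return A `roc_result`: list with `points` (data.frame fpr, tpr), `auc`,
#'   `ci` (lower, upper), `ci_method`, `positive_class`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_reps = 2000, boot_seed = 1L, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("AUC undefined: both classes must be present")
  }
  auc <- mw_auc(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  points <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delong") {
    se <- sqrt(delong_var(scores, labels))
    ci <- c(auc - z * se, auc + z * se)
  } else {
    boots <- with_seed(boot_seed, {
      ipos <- which(labels)
      ineg <- which(!labels)
      vapply(seq_len(boot_reps), function(b) {
        idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
        mw_auc(scores[idx], labels[idx])
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c((1 - conf_level) / 2,
                                          1 - (1 - conf_level) / 2)))
  }
  ci <- pmin(pmax(ci, 0), 1)
  ci <- c(min(ci[1], auc), max(ci[2], auc))
  res <- list(points = points, auc = auc, ci = ci, ci_method = ci_method,
              positive_class = "preterm (<37 wk)",
              n_pos = sum(labels), n_neg = sum(!labels))
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.0f%% CI %.3f, %.3f; %s), %d pos / %d neg\n",
              x$auc, 95, x$ci[1], x$ci[2], x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pooled preterm ROC/AUC across imputations
#'
#' Computes the ROC per imputation with score `-prediction` against the
#' preterm label `observed < 37`, then pools AUC and CI bounds by their mean.
#'
#' @param estimates a `ga_estimates` with observed GA.
#' @param ... passed to [roc_auc()].
#' @return list with pooled `auc`, `ci`, per-imputation AUCs, and the
#'   `roc_result` of the pooled predictions (for curve plotting).
#' @export
roc_auc_mi <- function(estimates, ...) {
  labels <- estimates$observed < 37
  per <- lapply(seq_len(estimates$m), function(k) {
    roc_auc(-estimates$per_imputation[, k], labels, ...)
  })
  aucs <- vapply(per, function(r) r$auc, numeric(1))
  lo <- vapply(per, function(r) r$ci[1], numeric(1))
  hi <- vapply(per, function(r) r$ci[2], numeric(1))
  list(auc = pool_scalar(aucs), ci = c(pool_scalar(lo), pool_scalar(hi)),
       per_imputation_auc = aucs,
       pooled_curve = roc_auc(-estimates$pooled, labels, ...))
}
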