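# Sample screening, multiple imputation of missing analytes (m = 10 by
# default), and the pooling rules applied to every downstream result:
# scalars are averaged across imputations; counts are averaged and rounded
# to the closest integer (half away from zero).

#' Screen samples for analyzability
#'
#' Samples whose missing-analyte fraction is at least `exclusion_threshold`
#' are excluded (default 1.0: only fully missing samples are dropped,
#' mirroring a data-preparation step that removed a single 100%-missing cord
#' sample). Retained samples with any missing analyte are flagged for
#' imputation.
#'
#' @param cohort a `cohort`.
#' @param exclusion_threshold missing fraction at or above which a sample is
#'   excluded.
#' @return A `screening_result`: list with `kept` (sample ids), `excluded`
#'   (data.frame of sample_id, reason), `missing_counts` (per-sample),
#'   `flagged_for_imputation` (ids), and `cohort` (the kept subset).
#' @export
screen_samples <- function(cohort, exclusion_threshold = 1.0) {
  rec <- cohort$records
  analytes <- cohort$panel$name
  if (nrow(rec) == 0) {
    warning("screening an empty cohort")
    res <- list(kept = character(),
                excluded = data.frame(sample_id = character(),
                                      reason = character()),
                missing_counts = integer(), flagged_for_imputation = character(),
                cohort = cohort)
    class(res) <- "screening_result"
    return(res)
  }
  miss <- rowSums(is.na(rec[, analytes, drop = FALSE]))
  frac <- miss / length(analytes)
  drop <- frac >= exclusion_threshold
  reason <- ifelse(frac[drop] >= 1, "all_missing", "excess_missing")
  kept_rec <- rec[!drop, , drop = FALSE]
  rownames(kept_rec) <- NULL
  out_cohort <- cohort
  out_cohort$records <- kept_rec
  res <- list(
    kept = rec$sample_id[!drop],
    excluded = data.frame(sample_id = rec$sample_id[drop], reason = reason,
                          stringsAsFactors = FALSE),
    missing_counts = stats::setNames(miss, rec$sample_id),
    flagged_for_imputation = rec$sample_id[!drop & miss > 0],
    cohort = out_cohort
  )
  class(res) <- "screening_result"
  res
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> kept %d, excluded %d (flagged for imputation: %d)\n",
              length(x$kept), nrow(x$excluded), length(x$flagged_for_imputation)))
  invisible(x)
}

# ridge-regularised least squares that tolerates n < p and collinearity;
# returns fitted-value function and residual SD on the observed rows
ridge_fit <- function(X, y) {
  keep <- apply(X, 2, function(c) stats::sd(c) > 0)
  Xk <- X[, keep, drop = FALSE]
  ctr <- colMeans(Xk)
  scl <- apply(Xk, 2, stats::sd)
  Xs <- scale(Xk, ctr, scl)
  lambda <- 1e-3 * nrow(Xs)
  A <- crossprod(Xs) + diag(lambda, ncol(Xs))
  beta <- solve(A, crossprod(Xs, y - mean(y)))
  pred_obs <- as.numeric(Xs %*% beta) + mean(y)
  df_resid <- max(nrow(Xs) - sum(keep) - 1, 2)
  sigma <- sqrt(sum((y - pred_obs)^2) / df_resid)
  list(
    predict = function(Xnew) {
      Xns <- scale(Xnew[, keep, drop = FALSE], ctr, scl)
      as.numeric(Xns %*% beta) + mean(y)
    },
    sigma = sigma
  )
}

#' Multiply impute missing analyte values
#'
#' Chained-equations stochastic regression imputation: missing cells are
#' initialised at column means, then each incomplete analyte is regressed
#' (ridge-regularised least squares) on all other analytes plus sex,
#' birthweight, multiple-birth status and sample type, over the rows where it
#' was observed, and missing cells are replaced by the prediction plus a
#' Gaussian residual draw. Gestational age is deliberately never used as a
#' conditioning variable because it is the downstream prediction target.
#' Observed cells are never altered; the m copies differ only at originally
#' missing cells. Deterministic given `seed`.
#'
#' @param cohort a screened `cohort` (no fully missing samples).
#' @param m number of imputations (default 10).
#' @param seed integer seed.
#' @param n_iter chained-equation sweeps per copy.
#' @return An `imputation_set`: list with `copies` (m record data.frames),
#'   `m`, `seed`, `method`, `input_digest`.
#' @export
impute_missing <- function(cohort, m = 10, seed = 1L, n_iter = 3) {
  stopifnot(m >= 1)
  rec <- cohort$records
  analytes <- cohort$panel$name
  A <- as.matrix(rec[, analytes, drop = FALSE])
  mask <- is.na(A)
  all_missing <- colnames(A)[colSums(!mask) == 0]
  if (nrow(rec) > 0 && length(all_missing)) {
    stop("cannot impute: analyte(s) missing in every sample: ",
         paste(all_missing, collapse = ", "))
  }
  clin <- cbind(
    sex = as.numeric(rec$sex == "male"),
    multiple_birth = as.numeric(rec$multiple_birth),
    birthweight_g = rec$birthweight_g,
    sample_type = as.numeric(rec$sample_type == "cord")
  )
  copies <- vector("list", m)
  if (!any(mask)) {
    for (k in seq_len(m)) copies[[k]] <- rec
  } else {
    incomplete <- colnames(A)[colSums(mask) > 0]
    for (k in seq_len(m)) {
      Ak <- with_seed(child_seed(seed, 100L + k), {
        Afill <- A
        for (j in incomplete) {
          Afill[mask[, j], j] <- mean(A[!mask[, j], j])
        }
        for (it in seq_len(n_iter)) {
          for (j in incomplete) {
            obs <- !mask[, j]
            X <- cbind(Afill[, setdiff(analytes, j), drop = FALSE], clin)
            fit <- ridge_fit(X[obs, , drop = FALSE], Afill[obs, j])
            mis <- which(mask[, j])
            Afill[mis, j] <- pmax(
              fit$predict(X[mis, , drop = FALSE]) +
                rnorm(length(mis), 0, fit$sigma),
              0)
          }
        }
        Afill
      })
      ck <- rec
      ck[, analytes] <- as.data.frame(Ak)
      copies[[k]] <- ck
    }
  }
  res <- list(copies = copies, m = m, seed = as.integer(seed),
              method = "chained_ridge_noise",
              input_digest = object_digest(rec$sample_id))
  class(res) <- "imputation_set"
  res
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed copies of %d samples (method %s, seed %d)\n",
              x$m, nrow(x$copies[[1]]), x$method, x$seed))
  invisible(x)
}

#' Pool a scalar metric across imputations
#'
#' The pooled value of any scalar result (prediction, RMSE, AUC, ...) is the
#' arithmetic mean over the m imputations.
#'
#' @param values numeric vector of per-imputation values.
#' @param m expected number of imputations.
#' @return pooled scalar.
#' @export
pool_scalar <- function(values, m = length(values)) {
  if (length(values) != m) {
    stop("contract error: expected ", m, " values, got ", length(values))
  }
  mean(values)
}

#' Pool an integer count across imputations
#'
#' Counts are averaged over imputations and rounded to the closest integer,
#' half away from zero (so a mean of 310.9 pools to 311).
#'
#' @param counts numeric vector of per-imputation counts.
#' @param m expected number of imputations.
#' @return pooled integer count.
#' @export
pool_count <- function(counts, m = length(counts)) {
  if (length(counts) != m) {
    stop("contract error: expected ", m, " counts, got ", length(counts))
  }
  round_half_away(mean(counts))
}

#' Persist / load an imputation set as delimited text plus a manifest
#' @param imp an `imputation_set`.
#' @param dir output directory (created if needed).
#' @export
write_imputation_set <- function(imp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(imp$m)) {
    utils::write.csv(imp$copies[[k]],
                     file.path(dir, sprintf("imputation_%02d.csv", k)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(m = imp$m, seed = imp$seed, method = imp$method,
                   input_digest = imp$input_digest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
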