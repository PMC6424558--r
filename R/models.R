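# The three-model hierarchy for continuous gestational-age estimation:
#   Model 1 (baseline): sex, multiple birth, birthweight
#   Model 2 (analyte):  sex, multiple birth, analytes + pairwise interactions
#   Model 3 (full):     all of the above
# Fitting is elastic-net penalised least squares (glmnet) with seeded k-fold
# cross-validation selecting lambda; heel and cord cohorts are fit separately.

CLINICAL_ORDER <- c("sex", "multiple_birth", "birthweight_g")

#' Specify one model of the hierarchy
#'
#' @param model_id 1 (baseline clinical), 2 (analyte), or 3 (full).
#' @param panel an [analyte_panel()]; ignored for model 1.
#' @param analyte_terms analyte subset to use as main effects (default: the
#'   whole panel for models 2 and 3).
#' @param interaction_pairs `"strong"` (all pairs among [strong_analytes()]
#'   present in `analyte_terms`), `"all"` (all pairs of `analyte_terms`),
#'   `"none"`, or a 2-column character matrix of pairs.
#' @param standardize center/scale continuous predictors before fitting and
#'   form interactions on the standardized main effects.
#' @param alpha elastic-net mixing parameter in `[0,1]` (0.5 default).
#' @param lambda_grid optional decreasing positive lambda sequence; `NULL`
#'   lets cross-validation build its own path.
#' @param log_transform apply `log1p` to analyte values before standardizing.
#' @return a `model_spec`.
#' @export
model_spec <- function(model_id, panel = analyte_panel(),
                       analyte_terms = NULL,
                       interaction_pairs = "strong",
                       standardize = TRUE, alpha = 0.5,
                       lambda_grid = NULL, log_transform = FALSE) {
  stopifnot(model_id %in% 1:3)
  clinical_terms <- switch(model_id,
    `1` = c("sex", "multiple_birth", "birthweight_g"),
    `2` = c("sex", "multiple_birth"),
    `3` = c("sex", "multiple_birth", "birthweight_g"))
  if (model_id == 1) {
    analyte_terms <- character()
    pairs <- matrix(character(), ncol = 2)
  } else {
    analyte_terms <- sort(analyte_terms %||% panel$name)
    if (!all(analyte_terms %in% panel$name)) {
      stop("analyte_terms not in panel: ",
           paste(setdiff(analyte_terms, panel$name), collapse = ", "))
    }
    pairs <- resolve_pairs(interaction_pairs, analyte_terms)
  }
  spec <- list(model_id = model_id, clinical_terms = clinical_terms,
               analyte_terms = analyte_terms, interaction_pairs = pairs,
               standardize = standardize, alpha = alpha,
               lambda_grid = lambda_grid, log_transform = log_transform)
  class(spec) <- "model_spec"
  spec
}

resolve_pairs <- function(interaction_pairs, analyte_terms) {
  if (is.character(interaction_pairs) && length(interaction_pairs) == 1) {
    base <- switch(interaction_pairs,
      strong = intersect(strong_analytes(), analyte_terms),
      all = analyte_terms,
      none = character(),
      stop("interaction_pairs must be 'strong', 'all', 'none' or a matrix"))
    if (length(base) < 2) return(matrix(character(), ncol = 2))
    cmb <- t(utils::combn(sort(base), 2))
  } else {
    cmb <- t(apply(as.matrix(interaction_pairs), 1, sort))
  }
  if (!all(cmb %in% analyte_terms)) {
    stop("interaction pairs reference undeclared analyte terms")
  }
  cmb <- cmb[order(cmb[, 1], cmb[, 2]), , drop = FALSE]
  cmb
}

term_names <- function(spec) {
  c(spec$clinical_terms,
    spec$analyte_terms,
    if (nrow(spec$interaction_pairs)) {
      paste(spec$interaction_pairs[, 1], spec$interaction_pairs[, 2], sep = ":")
    })
}

#' Build the model design matrix
#'
#' Column order is deterministic: clinical terms (sex, multiple_birth,
#' birthweight_g as applicable), analyte main effects alphabetically, then
#' interaction products in lexicographic pair order. Sex is coded female = 0 /
#' male = 1 and multiple birth no = 0 / yes = 1. Continuous columns
#' (birthweight and analytes) are standardized with training-set parameters;
#' interactions are products of the standardized main effects.
#'
#' @param records cohort records data.frame (no missing analytes among the
#'   spec's terms; impute upstream).
#' @param spec a [model_spec()].
#' @param standardization optional list (center, scale) from a previous call;
#'   when `NULL`, parameters are estimated from `records`.
#' @return list with `X` (matrix), `standardization`, `terms`.
#' @export
build_design_matrix <- function(records, spec, standardization = NULL) {
  needed <- c(spec$clinical_terms, spec$analyte_terms)
  needed_cols <- setdiff(needed, c("sex", "multiple_birth"))
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("schema error: records lack term column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (trm in needed_cols) {
    bad <- which(is.na(records[[trm]]))
    if (length(bad)) {
      stop("MISSING value for term '", trm, "' in sample ",
           records$sample_id[bad[1]], " (impute before modelling)")
    }
  }
  n <- nrow(records)
  cols <- list()
  for (trm in spec$clinical_terms) {
    cols[[trm]] <- switch(trm,
      sex = as.numeric(records$sex == "male"),
      multiple_birth = as.numeric(records$multiple_birth),
      birthweight_g = records$birthweight_g)
  }
  for (a in spec$analyte_terms) {
    v <- records[[a]]
    cols[[a]] <- if (spec$log_transform) log1p(v) else v
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  continuous <- c(intersect("birthweight_g", spec$clinical_terms),
                  spec$analyte_terms)
  if (spec$standardize && length(continuous)) {
    if (is.null(standardization)) {
      center <- colMeans(X[, continuous, drop = FALSE])
      scl <- apply(X[, continuous, drop = FALSE], 2, stats::sd)
      scl[!is.finite(scl) | scl == 0] <- 1
      standardization <- list(center = center, scale = scl)
    }
    X[, continuous] <- sweep(
      sweep(X[, continuous, drop = FALSE], 2, standardization$center, "-"),
      2, standardization$scale, "/")
  } else {
    standardization <- standardization %||%
      list(center = stats::setNames(numeric(0), character(0)),
           scale = stats::setNames(numeric(0), character(0)))
  }
  if (nrow(spec$interaction_pairs)) {
    inter <- apply(spec$interaction_pairs, 1, function(pr) {
      X[, pr[1]] * X[, pr[2]]
    })
    if (!is.matrix(inter)) inter <- matrix(inter, nrow = n)
    colnames(inter) <- paste(spec$interaction_pairs[, 1],
                             spec$interaction_pairs[, 2], sep = ":")
    X <- cbind(X, inter)
  }
  list(X = X, standardization = standardization, terms = colnames(X))
}

#' Fit a gestational-age model by penalised regression
#'
#' Elastic net over a lambda path with seeded k-fold cross-validation;
#' lambda at minimum CV error. The intercept is left unpenalised. Columns
#' with zero variance are dropped with a warning. Deterministic given `seed`.
#'
#' @param design output of [build_design_matrix()] on the training records.
#' @param ga_obs observed gestational ages (weeks), same row order.
#' @param spec the [model_spec()] used to build the design.
#' @param seed integer seed (controls CV fold assignment).
#' @param nfolds CV folds (default 10).
#' @return A `fitted_ga_model`: spec, intercept, named coefficient vector
#'   over the spec's terms, standardization, and training metadata.
#' @export
fit_ga_model <- function(design, ga_obs, spec, seed = 1L, nfolds = 10) {
  X <- design$X
  n <- nrow(X)
  if (n <= nfolds) stop("need more samples than CV folds")
  if (!all(is.finite(ga_obs))) stop("ga_obs must be finite")
  if (stats::sd(ga_obs) == 0) stop("constant outcome: cannot fit")
  keep <- apply(X, 2, function(c) stats::sd(c) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xk <- X[, keep, drop = FALSE]
  cv <- with_seed(seed, {
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    glmnet::cv.glmnet(Xk, ga_obs, alpha = spec$alpha, foldid = foldid,
                      lambda = spec$lambda_grid, standardize = FALSE,
                      family = "gaussian")
  })
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta[rownames(cf)[-1]] <- cf[-1, 1]
  model <- list(
    spec = spec,
    intercept = cf[1, 1],
    coefficients = beta,
    standardization = design$standardization,
    dropped_terms = colnames(X)[!keep],
    training = list(n = n, seed = as.integer(seed),
                    lambda = cv$lambda.min, nfolds = nfolds,
                    cv_rmse = sqrt(min(cv$cvm)))
  )
  class(model) <- "fitted_ga_model"
  model
}

#' @export
print.fitted_ga_model <- function(x, ...) {
  cat(sprintf("<fitted_ga_model> model %d: %d terms (%d active), n = %d, lambda = %.4g, CV RMSE = %.3f wk\n",
              x$spec$model_id, length(x$coefficients),
              sum(x$coefficients != 0), x$training$n, x$training$lambda,
              x$training$cv_rmse))
  invisible(x)
}

#' Predict gestational age
#'
#' Scores cohort records (or every copy of an [impute_missing()] set, pooling
#' per-sample predictions by their mean across imputations) with a fitted
#' model. Residuals (pooled minus observed) are populated when observed GA is
#' present.
#'
#' @param model a `fitted_ga_model`.
#' @param newdata a `cohort`, a records data.frame, or an `imputation_set`.
#' @param clip optional length-2 range (weeks) to clip predictions to;
#'   `NULL` (default) leaves predictions unclipped.
#' @return A `ga_estimates`: data.frame-backed list with `sample_id`,
#'   `observed`, per-imputation prediction matrix, `pooled`, `residual`.
#' @export
predict_ga <- function(model, newdata, clip = NULL) {
  copies <- if (inherits(newdata, "imputation_set")) {
    newdata$copies
  } else if (inherits(newdata, "cohort")) {
    list(newdata$records)
  } else {
    list(newdata)
  }
  m <- length(copies)
  score_one <- function(rec) {
    d <- build_design_matrix(rec, model$spec, model$standardization)
    as.numeric(d$X %*% model$coefficients) + model$intercept
  }
  preds <- vapply(copies, score_one, numeric(nrow(copies[[1]])))
  if (nrow(copies[[1]]) == 1) preds <- matrix(preds, nrow = 1)
  if (!is.null(clip)) preds <- pmin(pmax(preds, clip[1]), clip[2])
  pooled <- rowMeans(preds)
  observed <- copies[[1]]$ga_obs_weeks %||% rep(NA_real_, length(pooled))
  est <- list(
    sample_id = copies[[1]]$sample_id,
    observed = observed,
    per_imputation = preds,
    pooled = pooled,
    residual = pooled - observed,
    m = m,
    model_id = model$spec$model_id
  )
  class(est) <- "ga_estimates"
  est
}

#' @export
print.ga_estimates <- function(x, ...) {
  cat(sprintf("<ga_estimates> model %s: %d samples, m = %d imputation(s)\n",
              as.character(x$model_id), length(x$pooled), x$m))
  if (!all(is.na(x$observed))) {
    cat(sprintf("  pooled RMSE %.3f wk\n", rmse(x$pooled, x$observed)))
  }
  invisible(x)
}

#' Calibration-slope recalibration
#'
#' Ordinary least squares of observed on predicted gestational age
#' (calibration-in-the-large intercept and calibration slope); adjusted
#' predictions are `intercept + slope * prediction`. A slope below 1 means
#' predictions are too extreme; above 1, too shrunken toward the mean.
#'
#' @param estimates a `ga_estimates` with observed GA on at least 3 samples.
#' @return list with `intercept`, `slope`, `raw` (input), `adjusted`
#'   (a `ga_estimates` with adjusted predictions).
#' @export
recalibrate <- function(estimates) {
  ok <- !is.na(estimates$observed)
  if (sum(ok) < 3) stop("need at least 3 samples with observed GA")
  if (stats::sd(estimates$pooled[ok]) == 0) {
    stop("zero-variance predictions: calibration slope undefined")
  }
  fit <- stats::lm(estimates$observed[ok] ~ estimates$pooled[ok])
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  adj <- estimates
  adj$per_imputation <- a + b * estimates$per_imputation
  adj$pooled <- a + b * estimates$pooled
  adj$residual <- adj$pooled - adj$observed
  list(intercept = a, slope = b, raw = estimates, adjusted = adj)
}

#' Serialize / load a fitted model as JSON
#'
#' Versioned structured-text schema: spec, standardization, coefficients
#' keyed by term name. A reloaded model reproduces predictions to numerical
#' round-off.
#'
#' @param model a `fitted_ga_model`.
#' @param path file path.
#' @export
write_ga_model <- function(model, path) {
  payload <- list(
    schema_version = 1L,
    spec = list(
      model_id = model$spec$model_id,
      clinical_terms = model$spec$clinical_terms,
      analyte_terms = model$spec$analyte_terms,
      interaction_pairs = model$spec$interaction_pairs,
      standardize = model$spec$standardize,
      alpha = model$spec$alpha,
      log_transform = model$spec$log_transform
    ),
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    standardization = list(
      center = as.list(model$standardization$center),
      scale = as.list(model$standardization$scale)
    ),
    dropped_terms = model$dropped_terms,
    training = model$training
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ga_model
#' @export
read_ga_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- p$spec$interaction_pairs
  if (is.null(pairs) || length(pairs) == 0) {
    pairs <- matrix(character(), ncol = 2)
  } else {
    pairs <- matrix(as.character(pairs), ncol = 2)
  }
  spec <- list(model_id = p$spec$model_id,
               clinical_terms = p$spec$clinical_terms,
               analyte_terms = as.character(p$spec$analyte_terms %||% character()),
               interaction_pairs = pairs,
               standardize = p$spec$standardize, alpha = p$spec$alpha,
               lambda_grid = NULL, log_transform = p$spec$log_transform)
  class(spec) <- "model_spec"
  model <- list(
    spec = spec,
    intercept = p$intercept,
    coefficients = unlist(p$coefficients),
    standardization = list(center = unlist(p$standardization$center),
                           scale = unlist(p$standardization$scale)),
    dropped_terms = as.character(p$dropped_terms %||% character()),
    training = p$training
  )
  if (is.null(model$standardization$center)) {
    model$standardization <- list(center = stats::setNames(numeric(0), character(0)),
                                  scale = stats::setNames(numeric(0), character(0)))
  }
  class(model) <- "fitted_ga_model"
  model
}
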