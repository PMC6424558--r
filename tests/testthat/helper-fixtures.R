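# Fixtures built in code: small seeded cohorts and hand-made estimate sets.

tiny_config <- function(n = 80, seed = 42L, ...) {
  simulation_config(n_infants = n, seed = seed, ...)
}

tiny_cohort <- function(n = 80, seed = 42L, ...) {
  simulate_cohort(tiny_config(n = n, seed = seed, ...))
}

# a ga_estimates object built directly from a prediction matrix
make_estimates <- function(per_imputation, observed, model_id = 3L,
                           sample_id = sprintf("S%04d", seq_along(observed))) {
  per_imputation <- as.matrix(per_imputation)
  pooled <- rowMeans(per_imputation)
  est <- list(
    sample_id = sample_id,
    observed = observed,
    per_imputation = per_imputation,
    pooled = pooled,
    residual = pooled - observed,
    m = ncol(per_imputation),
    model_id = model_id
  )
  class(est) <- "ga_estimates"
  est
}

# intercept-only fitted model (all coefficients zero)
constant_model <- function(intercept = 39) {
  spec <- model_spec(1)
  m <- list(
    spec = spec,
    intercept = intercept,
    coefficients = stats::setNames(rep(0, 3), spec$clinical_terms),
    standardization = list(center = c(birthweight_g = 3000),
                           scale = c(birthweight_g = 400)),
    dropped_terms = character(),
    training = list(n = 0L, seed = 0L, lambda = NA_real_, nfolds = 0L,
                    cv_rmse = NA_real_)
  )
  class(m) <- "fitted_ga_model"
  m
}

# exhaustive pairwise Mann-Whitney AUC oracle (ties count 1/2)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# training + external pair used by the model-hierarchy checks
hierarchy_fixture <- function(seed = 1L, n_train = 5000, n_external = 1500) {
  cfg <- pipeline_config(seed = seed, n_train = n_train,
                         n_external = n_external)
  train <- simulate_cohort(
    metabGA:::sim_config_from(cfg$train,
                              metabGA:::child_seed(seed, "simulate_train")))
  external <- simulate_cohort(
    metabGA:::sim_config_from(cfg$external,
                              metabGA:::child_seed(seed, "simulate_external")))
  list(cfg = cfg, train = train, external = external)
}
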