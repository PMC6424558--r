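# Seeded simulation of newborn-screening cohorts: clinical covariates drawn
# from a term/preterm gestational-age mixture, birthweight conditional on GA
# and sex, heel/cord dried-blood-spot samples with GA- and postnatal-age-
# dependent analyte levels, and sparse missingness.

#' Simulation configuration
#'
#' Defaults emulate the composition of a South-Asian field-validation cohort:
#' mean gestational age 39.0 weeks (SD 1.6), roughly 9% preterm, an even sex
#' split, under 2% multiples, term birthweight near 2900 g, heel-prick
#' collection at about 15 +/- 6.5 h versus cord collection at birth, and about
#' 42% of infants contributing both a heel and a cord sample.
#'
#' @param n_infants number of infants (each contributes 1 or 2 samples).
#' @param ga_mean_weeks,ga_sd_weeks target marginal mean/SD of gestational age.
#' @param preterm_target_fraction probability an infant is preterm (<37 wk).
#' @param sex_male_fraction,multiple_birth_fraction proportions in `[0,1]`.
#' @param birthweight_term_mean_g,birthweight_term_sd_g,birthweight_preterm_mean_g,birthweight_preterm_sd_g
#'   birthweight moments by term status used to anchor the conditional
#'   birthweight model.
#' @param heel_collection_mean_h,heel_collection_sd_h,cord_collection_mean_h,cord_collection_sd_h
#'   age at sample collection (hours); cord collection is truncated at 2.1 h.
#' @param paired_fraction proportion of infants contributing both sample types.
#' @param unpaired_heel_fraction among unpaired infants, proportion giving a
#'   heel sample (the remainder give cord).
#' @param panel an [analyte_panel()].
#' @param analyte_effects effect table as from [default_analyte_effects()].
#' @param correlation_strength share of analyte noise variance carried by a
#'   latent per-infant, per-analyte-group factor (in `[0,1]`); induces both
#'   cross-analyte and cord/heel correlation.
#' @param missing_rate per-cell probability an analyte value is missing.
#' @param missing_mechanism `"mcar"` or `"mar_sample_type"` (cord cells missing
#'   at 0.35 times the heel rate).
#' @param max_missing_per_sample cap on missing analytes per sample.
#' @param birthweight_chart optional [build_reference_chart()] object; when
#'   supplied, birthweight is drawn directly from the chart's (sex, completed
#'   week) normal distribution instead of the linear-in-GA model.
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_infants = 1069,
                              ga_mean_weeks = 39.1,
                              ga_sd_weeks = 1.6,
                              preterm_target_fraction = 0.09,
                              sex_male_fraction = 0.51,
                              multiple_birth_fraction = 0.017,
                              birthweight_term_mean_g = 2900,
                              birthweight_term_sd_g = 395,
                              birthweight_preterm_mean_g = 2330,
                              birthweight_preterm_sd_g = 530,
                              heel_collection_mean_h = 14.97,
                              heel_collection_sd_h = 6.54,
                              cord_collection_mean_h = 0.06,
                              cord_collection_sd_h = 0.25,
                              paired_fraction = 0.42,
                              unpaired_heel_fraction = 0.054,
                              panel = analyte_panel(),
                              analyte_effects = default_analyte_effects(panel),
                              correlation_strength = 0.3,
                              missing_rate = 0.00125,
                              missing_mechanism = c("mcar", "mar_sample_type"),
                              max_missing_per_sample = 5,
                              birthweight_chart = NULL,
                              seed = 1L) {
  cfg <- list(
    n_infants = n_infants, ga_mean_weeks = ga_mean_weeks,
    ga_sd_weeks = ga_sd_weeks,
    preterm_target_fraction = preterm_target_fraction,
    sex_male_fraction = sex_male_fraction,
    multiple_birth_fraction = multiple_birth_fraction,
    birthweight_term_mean_g = birthweight_term_mean_g,
    birthweight_term_sd_g = birthweight_term_sd_g,
    birthweight_preterm_mean_g = birthweight_preterm_mean_g,
    birthweight_preterm_sd_g = birthweight_preterm_sd_g,
    heel_collection_mean_h = heel_collection_mean_h,
    heel_collection_sd_h = heel_collection_sd_h,
    cord_collection_mean_h = cord_collection_mean_h,
    cord_collection_sd_h = cord_collection_sd_h,
    paired_fraction = paired_fraction,
    unpaired_heel_fraction = unpaired_heel_fraction,
    panel = panel, analyte_effects = analyte_effects,
    correlation_strength = correlation_strength,
    missing_rate = missing_rate,
    missing_mechanism = match.arg(missing_mechanism),
    max_missing_per_sample = max_missing_per_sample,
    birthweight_chart = birthweight_chart,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c("preterm_target_fraction", "sex_male_fraction",
             "multiple_birth_fraction", "paired_fraction",
             "unpaired_heel_fraction", "correlation_strength", "missing_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("configuration error: ", p, " must be a proportion in [0,1]")
    }
  }
  sds <- c("ga_sd_weeks", "birthweight_term_sd_g", "birthweight_preterm_sd_g",
           "heel_collection_sd_h", "cord_collection_sd_h")
  for (p in sds) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) {
      stop("configuration error: ", p, " must be > 0")
    }
  }
  if (cfg$n_infants < 0) stop("configuration error: n_infants must be >= 0")
  if (cfg$max_missing_per_sample > nrow(cfg$panel)) {
    stop("configuration error: max_missing_per_sample exceeds panel size")
  }
  unknown <- setdiff(cfg$analyte_effects$analyte, cfg$panel$name)
  if (length(unknown)) {
    stop("configuration error: effects reference unknown analyte(s): ",
         paste(unknown, collapse = ", "))
  }
  missing_eff <- setdiff(cfg$panel$name, cfg$analyte_effects$analyte)
  if (length(missing_eff)) {
    stop("configuration error: no effects defined for analyte(s): ",
         paste(missing_eff, collapse = ", "))
  }
  invisible(cfg)
}

# Mixture used for gestational age: with probability f an infant is preterm
# and GA = 37 - E with E a truncated exponential tail (mean ~1.8 wk, support
# (0, 11]); otherwise GA is a normal truncated to [37, 43] whose (mu, sd) are
# solved numerically so the mixture hits the configured marginal mean and SD.
PRETERM_TAIL_MEAN <- 1.8
PRETERM_TAIL_MAX <- 11

preterm_tail_moments <- function(theta = PRETERM_TAIL_MEAN,
                                 cap = PRETERM_TAIL_MAX) {
  z <- 1 - exp(-cap / theta)
  m1 <- theta - cap * exp(-cap / theta) / z
  # E[E^2] for exponential truncated to (0, cap]
  m2 <- (2 * theta^2 - exp(-cap / theta) * (cap^2 + 2 * theta * cap + 2 * theta^2)) / z
  list(mean = 37 - m1, var = m2 - m1^2)
}

solve_term_component <- function(target_mean, target_sd, preterm_fraction) {
  pm <- preterm_tail_moments()
  f <- preterm_fraction
  obj <- function(par) {
    mu <- par[1]; sd <- exp(par[2])
    tm <- tnorm_moments(mu, sd, 37, 43)
    mix_mean <- f * pm$mean + (1 - f) * tm$mean
    mix_var <- f * (pm$var + pm$mean^2) + (1 - f) * (tm$var + tm$mean^2) -
      mix_mean^2
    (mix_mean - target_mean)^2 + (sqrt(max(mix_var, 0)) - target_sd)^2
  }
  fit <- optim(c(target_mean, log(max(target_sd * 0.8, 0.2))), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sd = exp(fit$par[2]))
}

draw_ga <- function(n, cfg) {
  f <- cfg$preterm_target_fraction
  is_pre <- runif(n) < f
  ga <- numeric(n)
  if (f > 0 && any(is_pre)) {
    z <- 1 - exp(-PRETERM_TAIL_MAX / PRETERM_TAIL_MEAN)
    u <- runif(sum(is_pre)) * z
    ga[is_pre] <- 37 - (-PRETERM_TAIL_MEAN * log(1 - u))
  }
  if (any(!is_pre)) {
    tc <- solve_term_component(cfg$ga_mean_weeks, cfg$ga_sd_weeks, f)
    ga[!is_pre] <- rtnorm(sum(!is_pre), tc$mu, tc$sd, 37, 43)
  }
  pmin(pmax(ga, 20), 45)
}

# linear conditional birthweight model anchored to the configured term and
# preterm means; slope derived from the GA gap between the two components.
birthweight_model <- function(cfg) {
  pm <- preterm_tail_moments()
  tc <- solve_term_component(cfg$ga_mean_weeks, cfg$ga_sd_weeks,
                             max(cfg$preterm_target_fraction, 0.01))
  term_mean_ga <- tnorm_moments(tc$mu, tc$sd, 37, 43)$mean
  slope <- (cfg$birthweight_term_mean_g - cfg$birthweight_preterm_mean_g) /
    (term_mean_ga - pm$mean)
  intercept40 <- cfg$birthweight_term_mean_g + slope * (40 - term_mean_ga)
  list(intercept40 = intercept40, slope = slope,
       sd = cfg$birthweight_term_sd_g, sex_shift = 40)
}

draw_birthweight <- function(ga, sex, cfg) {
  n <- length(ga)
  if (!is.null(cfg$birthweight_chart)) {
    wk <- floor(ga)
    chart <- cfg$birthweight_chart
    key <- paste(sex, wk)
    idx <- match(key, paste(chart$sex, chart$ga_week))
    if (anyNA(idx)) {
      stop("birthweight chart does not cover GA week(s): ",
           paste(sort(unique(wk[is.na(idx)])), collapse = ", "))
    }
    bw <- rnorm(n, chart$location_g[idx], chart$scale_g[idx])
  } else {
    bm <- birthweight_model(cfg)
    mu <- bm$intercept40 + bm$slope * (ga - 40) +
      ifelse(sex == "male", bm$sex_shift, -bm$sex_shift)
    bw <- rnorm(n, mu, bm$sd)
  }
  pmin(pmax(bw, 300), 6000)
}

#' Simulate analyte values for a set of samples
#'
#' Each analyte follows `intercept + slope_ga * (GA - 40) + slope_age * age +
#' cord_shift * [cord] + noise`, truncated at zero. Noise is split between a
#' latent factor shared within an infant's analyte group (weight
#' `correlation_strength`) and independent error, which induces correlation
#' among analytes of the same group and between an infant's cord and heel
#' samples. Under the default effects the fetal/adult hemoglobin ratio is
#' strictly decreasing in both gestational and postnatal age, and TSH means
#' differ between cord (age ~ 0) and heel (age ~ 15 h) draws.
#'
#' @param ga_obs_weeks,age_at_collection_h,sample_type,sex parallel vectors
#'   describing one sample per element (`sex` is accepted for interface
#'   completeness; the default generating model carries no sex effect).
#' @param config a [simulation_config()].
#' @param latent optional n x n_groups matrix of latent group factors (rows
#'   aligned with samples); supply the same rows for an infant's two samples
#'   to induce cord/heel correlation. Drawn i.i.d. standard normal if `NULL`.
#' @return matrix (samples x analytes) of nonnegative values.
#' @export
simulate_analytes <- function(ga_obs_weeks, age_at_collection_h, sample_type,
                              sex = NULL, config = simulation_config(),
                              latent = NULL) {
  eff <- config$analyte_effects
  unknown <- setdiff(eff$analyte, config$panel$name)
  if (length(unknown)) {
    stop("configuration error: effects reference unknown analyte(s): ",
         paste(unknown, collapse = ", "))
  }
  eff <- eff[match(config$panel$name, eff$analyte), ]
  n <- length(ga_obs_weeks)
  p <- nrow(eff)
  groups <- config$panel$group
  glev <- unique(groups)
  if (is.null(latent)) {
    latent <- matrix(rnorm(n * length(glev)), n, length(glev),
                     dimnames = list(NULL, glev))
  }
  rho <- config$correlation_strength
  is_cord <- as.numeric(sample_type == "cord")
  vals <- matrix(0, n, p, dimnames = list(NULL, eff$analyte))
  eps <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(p)) {
    mu <- eff$intercept[j] + eff$slope_ga[j] * (ga_obs_weeks - 40) +
      eff$slope_age[j] * age_at_collection_h + eff$cord_shift[j] * is_cord
    noise <- eff$noise_sd[j] *
      (sqrt(rho) * latent[, groups[j], drop = TRUE] + sqrt(1 - rho) * eps[, j])
    vals[, j] <- pmax(mu + noise, 0)
  }
  vals
}

#' Simulate a newborn-screening cohort
#'
#' Draws infants (sex, multiple-birth status, gestational age from the
#' term/preterm mixture, birthweight conditional on GA and sex), assigns each
#' infant one or both sample types, draws collection ages and analyte values,
#' and returns a `cohort` object. Deterministic given `config$seed`; paired
#' samples share all clinical covariates.
#'
#' @param config a [simulation_config()].
#' @return A `cohort` object: list with `records` (one row per sample),
#'   `panel`, and `provenance` (seed, config digest, generator version).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_sim_config(config)
  prov <- list(seed = config$seed,
               config_digest = object_digest(config[setdiff(names(config), "panel")]),
               generator_version = "1")
  panel <- config$panel
  n <- config$n_infants
  if (n == 0) {
    rec <- empty_records(panel)
    return(new_cohort(rec, panel, prov))
  }
  records <- with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$sex_male_fraction, "male", "female")
    multiple <- runif(n) < config$multiple_birth_fraction
    ga <- draw_ga(n, config)
    bw <- draw_birthweight(ga, sex, config)
    paired <- runif(n) < config$paired_fraction
    heel_only <- !paired & (runif(n) < config$unpaired_heel_fraction)
    has_heel <- paired | heel_only
    has_cord <- paired | (!paired & !heel_only)
    glev <- unique(panel$group)
    latent <- matrix(rnorm(n * length(glev)), n, length(glev),
                     dimnames = list(NULL, glev))
    build_rows <- function(type, idx) {
      m <- length(idx)
      if (m == 0) return(NULL)
      age <- if (type == "heel") {
        rtnorm(m, config$heel_collection_mean_h, config$heel_collection_sd_h,
               0.4, 40.5)
      } else {
        rtnorm(m, config$cord_collection_mean_h, config$cord_collection_sd_h,
               0, 2.1)
      }
      vals <- simulate_analytes(ga[idx], age, rep(type, m), sex[idx],
                                config, latent = latent[idx, , drop = FALSE])
      cbind(
        data.frame(
          infant_id = sprintf("I%05d", idx),
          sample_id = sprintf("I%05d_%s", idx, type),
          sample_type = type,
          sex = sex[idx],
          multiple_birth = multiple[idx],
          birthweight_g = bw[idx],
          ga_obs_weeks = ga[idx],
          age_at_collection_h = age,
          stringsAsFactors = FALSE
        ),
        as.data.frame(vals)
      )
    }
    rec <- rbind(build_rows("heel", which(has_heel)),
                 build_rows("cord", which(has_cord)))
    rec[order(rec$infant_id, rec$sample_type), , drop = FALSE]
  })
  rownames(records) <- NULL
  cohort <- new_cohort(records, panel, prov)
  if (config$missing_rate > 0) {
    cohort <- apply_missingness(cohort, config)
  }
  cohort
}

empty_records <- function(panel) {
  rec <- data.frame(
    infant_id = character(), sample_id = character(),
    sample_type = character(), sex = character(),
    multiple_birth = logical(), birthweight_g = numeric(),
    ga_obs_weeks = numeric(), age_at_collection_h = numeric(),
    stringsAsFactors = FALSE
  )
  for (a in panel$name) rec[[a]] <- numeric()
  rec
}

new_cohort <- function(records, panel, provenance) {
  stopifnot(!anyDuplicated(records$sample_id))
  structure(list(records = records, panel = panel, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples from %d infants; %d-analyte panel (seed %s)\n",
              nrow(x$records), length(unique(x$records$infant_id)),
              nrow(x$panel), as.character(x$provenance$seed)))
  tab <- table(x$records$sample_type)
  if (length(tab)) {
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply sparse missingness to a complete cohort
#'
#' Sets analyte cells missing (NA) completely at random at `missing_rate`
#' (or, under `mar_sample_type`, at 0.35 times that rate for cord samples),
#' capping missing analytes per sample at `max_missing_per_sample`.
#' Deterministic given `seed`.
#'
#' @param cohort a `cohort` with complete analyte data.
#' @param config a [simulation_config()] (rate, mechanism, cap).
#' @param seed RNG seed; defaults to a child of the config seed.
#' @param inject_fully_missing if `TRUE`, additionally blanks every analyte of
#'   the first cord sample (or first sample) to exercise screening exclusions.
#' @return the cohort with missingness applied.
#' @export
apply_missingness <- function(cohort, config, seed = NULL,
                              inject_fully_missing = FALSE) {
  if (config$max_missing_per_sample > nrow(cohort$panel)) {
    stop("configuration error: max_missing_per_sample exceeds panel size")
  }
  rec <- cohort$records
  if (nrow(rec) == 0 || config$missing_rate == 0) {
    if (!inject_fully_missing || nrow(rec) == 0) return(cohort)
  }
  seed <- seed %||% child_seed(config$seed, "missingness")
  analytes <- cohort$panel$name
  rec <- with_seed(seed, {
    rate <- rep(config$missing_rate, nrow(rec))
    if (config$missing_mechanism == "mar_sample_type") {
      rate[rec$sample_type == "cord"] <- rate[rec$sample_type == "cord"] * 0.35
    }
    mask <- matrix(runif(nrow(rec) * length(analytes)), nrow(rec)) < rate
    # cap per sample: keep a random subset of the drawn cells
    for (i in which(rowSums(mask) > config$max_missing_per_sample)) {
      hits <- which(mask[i, ])
      keep <- sample(hits, config$max_missing_per_sample)
      mask[i, ] <- FALSE
      mask[i, keep] <- TRUE
    }
    if (inject_fully_missing) {
      tgt <- which(rec$sample_type == "cord")[1]
      if (is.na(tgt)) tgt <- 1L
      mask[tgt, ] <- TRUE
    }
    for (j in seq_along(analytes)) {
      rec[mask[, j], analytes[j]] <- NA_real_
    }
    rec
  })
  cohort$records <- rec
  cohort
}

#' Write / read a cohort as delimited text
#'
#' One row per sample, comma-separated, UTF-8, header row; missing analyte
#' values encoded as empty fields.
#' @param cohort a `cohort`.
#' @param path output file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param panel panel to validate the analyte columns against.
#' @export
read_cohort <- function(path, panel = analyte_panel()) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  clinical <- c("infant_id", "sample_id", "sample_type", "sex",
                "multiple_birth", "birthweight_g", "ga_obs_weeks",
                "age_at_collection_h")
  missing_cols <- setdiff(c(clinical, panel$name), names(rec))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rec$multiple_birth <- as.logical(rec$multiple_birth)
  new_cohort(rec, panel, list(seed = NA_integer_, config_digest = NA_character_,
                              generator_version = "1"))
}
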