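# Cohort simulator: configuration contracts, determinism, marginal moment
# recovery, pairing integrity, analyte generating model, missingness.

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(preterm_target_fraction = 1.2), "proportion")
  expect_error(simulation_config(ga_sd_weeks = 0), "> 0")
  expect_error(simulation_config(max_missing_per_sample = 48),
               "exceeds panel size")
  panel <- analyte_panel()
  eff <- default_analyte_effects(panel)
  eff$analyte[1] <- "NOT_AN_ANALYTE"
  expect_error(simulation_config(analyte_effects = eff), "unknown analyte")
})

test_that("n_infants = 0 yields an empty cohort with valid provenance", {
  co <- simulate_cohort(simulation_config(n_infants = 0, seed = 3))
  expect_s3_class(co, "cohort")
  expect_identical(nrow(co$records), 0L)
  expect_identical(co$provenance$seed, 3L)
  expect_true(nchar(co$provenance$config_digest) == 32)
  expect_true(all(co$panel$name %in% names(co$records)))
})

test_that("same config and seed give byte-identical cohorts", {
  cfg <- tiny_config(n = 120, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("marginal moments and preterm fraction are recovered at n = 5000", {
  cfg <- simulation_config(n_infants = 5000, seed = 7)
  co <- simulate_cohort(cfg)
  inf <- co$records[!duplicated(co$records$infant_id), ]
  n <- nrow(inf)
  se_mean <- cfg$ga_sd_weeks / sqrt(n)
  expect_lt(abs(mean(inf$ga_obs_weeks) - 39.1), 3 * se_mean)
  p <- cfg$preterm_target_fraction
  se_p <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(inf$ga_obs_weeks < 37) - p), 3 * se_p)
  heel <- co$records[co$records$sample_type == "heel", ]
  se_age <- cfg$heel_collection_sd_h / sqrt(nrow(heel))
  expect_lt(abs(mean(heel$age_at_collection_h) - cfg$heel_collection_mean_h),
            4 * se_age)
  bw_se <- cfg$birthweight_term_sd_g / sqrt(sum(inf$ga_obs_weeks >= 37))
  expect_lt(abs(mean(inf$birthweight_g[inf$ga_obs_weeks >= 37]) -
                  cfg$birthweight_term_mean_g), 4 * bw_se)
})

test_that("record-level invariants hold", {
  co <- tiny_cohort(n = 300, seed = 5)
  rec <- co$records
  expect_true(all(rec$ga_obs_weeks >= 20 & rec$ga_obs_weeks <= 45))
  expect_true(all(rec$birthweight_g >= 300 & rec$birthweight_g <= 6000))
  cord <- rec[rec$sample_type == "cord", ]
  expect_true(all(cord$age_at_collection_h <= 2.1))
  expect_true(all(rec$age_at_collection_h >= 0))
  expect_false(anyDuplicated(rec$sample_id) > 0)
  # at most one heel and one cord per infant
  tab <- table(rec$infant_id, rec$sample_type)
  expect_true(all(tab <= 1))
})

test_that("paired samples share all clinical covariates", {
  co <- tiny_cohort(n = 400, seed = 8, paired_fraction = 0.6)
  rec <- co$records
  paired_ids <- names(which(table(rec$infant_id) == 2))
  expect_gt(length(paired_ids), 0)
  clin <- c("sex", "multiple_birth", "birthweight_g", "ga_obs_weeks")
  for (id in paired_ids) {
    rows <- rec[rec$infant_id == id, clin]
    expect_equal(unname(as.list(rows[1, ])), unname(as.list(rows[2, ])))
  }
  # paired count is binomially plausible
  n_paired <- length(paired_ids)
  expect_lt(abs(n_paired - 400 * 0.6), 3 * sqrt(400 * 0.6 * 0.4) + 1)
})

test_that("hemoglobin ratio mean is higher at GA 30 than GA 40", {
  cfg <- tiny_config()
  set.seed(11)
  v30 <- simulate_analytes(rep(30, 400), rep(15, 400), rep("heel", 400),
                           config = cfg)
  set.seed(11)
  v40 <- simulate_analytes(rep(40, 400), rep(15, 400), rep("heel", 400),
                           config = cfg)
  expect_gt(mean(v30[, "HBF_HBA_RATIO"]), mean(v40[, "HBF_HBA_RATIO"]))
  # and strictly decreasing in postnatal age as well
  set.seed(12)
  a0 <- simulate_analytes(rep(38, 400), rep(0, 400), rep("heel", 400),
                          config = cfg)
  set.seed(12)
  a30 <- simulate_analytes(rep(38, 400), rep(30, 400), rep("heel", 400),
                           config = cfg)
  expect_gt(mean(a0[, "HBF_HBA_RATIO"]), mean(a30[, "HBF_HBA_RATIO"]))
})

test_that("TSH differs between cord and heel collection under defaults", {
  co <- tiny_cohort(n = 600, seed = 13, paired_fraction = 1,
                    missing_rate = 0)
  rec <- co$records
  tsh_heel <- mean(rec$TSH[rec$sample_type == "heel"])
  tsh_cord <- mean(rec$TSH[rec$sample_type == "cord"])
  expect_gt(tsh_heel - tsh_cord, 2)
})

test_that("zero effect slopes give analytes independent of GA", {
  panel <- analyte_panel()
  eff <- default_analyte_effects(panel)
  eff$slope_ga <- 0
  eff$slope_age <- 0
  co <- tiny_cohort(n = 800, seed = 21, analyte_effects = eff,
                    missing_rate = 0, paired_fraction = 0,
                    unpaired_heel_fraction = 1)
  rec <- co$records
  cors <- vapply(strong_analytes(), function(a) {
    cor(rec[[a]], rec$ga_obs_weeks)
  }, numeric(1))
  expect_true(all(abs(cors) < 3.5 / sqrt(nrow(rec))))
})

test_that("cord shift and postnatal slope of zero make sample types match", {
  panel <- analyte_panel()
  eff <- default_analyte_effects(panel)
  eff$cord_shift <- 0
  eff$slope_age <- 0
  cfg <- tiny_config(analyte_effects = eff)
  set.seed(31)
  heel <- simulate_analytes(rep(39, 2000), rep(15, 2000), rep("heel", 2000),
                            config = cfg)
  set.seed(31)
  cord <- simulate_analytes(rep(39, 2000), rep(0, 2000), rep("cord", 2000),
                            config = cfg)
  expect_equal(colMeans(heel), colMeans(cord), tolerance = 1e-10)
})

test_that("missingness respects rate zero, the per-sample cap and the seed", {
  cfg0 <- tiny_config(n = 150, seed = 2, missing_rate = 0)
  co <- simulate_cohort(cfg0)
  expect_identical(apply_missingness(co, cfg0)$records, co$records)

  cfg <- tiny_config(n = 150, seed = 2, missing_rate = 0.08)
  co2 <- simulate_cohort(cfg)
  miss <- rowSums(is.na(co2$records[, co2$panel$name]))
  expect_true(all(miss <= cfg$max_missing_per_sample))
  expect_gt(sum(miss), 0)

  complete <- simulate_cohort(cfg0)
  m1 <- apply_missingness(complete, cfg, seed = 77)
  m2 <- apply_missingness(complete, cfg, seed = 77)
  expect_identical(m1$records, m2$records)

  inj <- apply_missingness(complete, cfg0, seed = 5,
                           inject_fully_missing = TRUE)
  miss_inj <- rowSums(is.na(inj$records[, inj$panel$name]))
  expect_identical(sum(miss_inj == nrow(inj$panel)), 1L)
})

test_that("cohorts round-trip through delimited text", {
  co <- tiny_cohort(n = 60, seed = 17, missing_rate = 0.05)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f, panel = co$panel)
  expect_equal(back$records$ga_obs_weeks, co$records$ga_obs_weeks,
               tolerance = 1e-12)
  expect_identical(back$records$sample_id, co$records$sample_id)
  expect_identical(is.na(back$records$TSH), is.na(co$records$TSH))
  unlink(f)
  expect_error(suppressWarnings(read_cohort(tempfile(), panel = co$panel)))
})
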