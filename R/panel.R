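# Default newborn-screening analyte panel and the simulator's effect table.

#' Construct an analyte panel
#'
#' A panel is an ordered set of unique analyte names, each assigned to a
#' biochemical group. The default panel has exactly 47 analytes: 12 amino
#' acids, 31 acylcarnitines, two endocrine markers (TSH, 17-OHP),
#' immunoreactive trypsinogen, and the fetal/adult hemoglobin ratio. The
#' identities beyond the named strong predictors are a configurable stand-in
#' for a screening laboratory's panel, not a fixed reference.
#'
#' @param names character vector of unique analyte names.
#' @param groups character vector (same length) with values in
#'   `amino_acid`, `acylcarnitine`, `endocrine`, `enzyme`, `hemoglobin`,
#'   `other`.
#' @return An `analyte_panel` object (data.frame with columns `name`, `group`).
#' @export
analyte_panel <- function(names = NULL, groups = NULL) {
  if (is.null(names)) {
    aa <- c("ALA", "ARG", "ASA", "CIT", "GLY", "LEU", "MET", "ORN",
            "PHE", "PRO", "TYR", "VAL")
    ac <- c("C0", "C2", "C3", "C3DC", "C4", "C4DC", "C4OH", "C5", "C5.1",
            "C5DC", "C5OH", "C6", "C6DC", "C8", "C8.1", "C10", "C10.1",
            "C10.2", "C12", "C12.1", "C14", "C14.1", "C14.2", "C14OH",
            "C16", "C16.1", "C16.1OH", "C16OH", "C18", "C18.1", "C18.2")
    names <- c(aa, ac, "TSH", "OHP17", "IRT", "HBF_HBA_RATIO")
    groups <- c(rep("amino_acid", length(aa)),
                rep("acylcarnitine", length(ac)),
                "endocrine", "endocrine", "other", "hemoglobin")
  }
  stopifnot(length(names) == length(groups))
  if (anyDuplicated(names)) stop("analyte names must be unique")
  ok <- c("amino_acid", "acylcarnitine", "endocrine", "enzyme",
          "hemoglobin", "other")
  if (!all(groups %in% ok)) {
    stop("unknown analyte group(s): ", paste(setdiff(groups, ok), collapse = ", "))
  }
  out <- data.frame(name = names, group = groups, stringsAsFactors = FALSE)
  class(out) <- c("analyte_panel", "data.frame")
  out
}

#' Strong gestational-age predictors
#'
#' The analytes that carry most of the gestational-age signal in metabolic
#' dating models: the fetal/adult hemoglobin ratio, TSH, 17-OHP, alanine,
#' isovalerylcarnitine (C5), methylmalonylcarnitine (C4DC) and tyrosine.
#' Pairwise interaction terms default to all pairs among this subset.
#'
#' @return character vector of analyte names.
#' @export
strong_analytes <- function() {
  c("ALA", "C4DC", "C5", "HBF_HBA_RATIO", "OHP17", "TSH", "TYR")
}

#' Default analyte effect table for the cohort simulator
#'
#' One row per panel analyte giving the linear generating model
#' `value = intercept + slope_ga * (GA - 40) + slope_age * age_h +
#' cord_shift * [cord] + noise`, truncated at zero. Intercepts are in
#' plausible screening units (umol/L for amino acids and acylcarnitines,
#' mIU/L for TSH, nmol/L for 17-OHP, ug/L for IRT, unitless hemoglobin
#' ratio). Slope and noise magnitudes are calibration constants of the
#' simulator chosen so a refit full model reaches a heel RMSE of about one
#' week at n = 5000; they are not published assay values.
#'
#' @param panel an [analyte_panel()].
#' @return data.frame with columns `analyte`, `intercept`, `slope_ga`,
#'   `slope_age`, `noise_sd`, `cord_shift`.
#' @export
default_analyte_effects <- function(panel = analyte_panel()) {
  base_int <- c(amino_acid = 150, acylcarnitine = 0.4, endocrine = 10,
                enzyme = 50, hemoglobin = 4, other = 20)
  eff <- data.frame(
    analyte = panel$name,
    intercept = unname(base_int[panel$group]),
    slope_ga = 0,
    slope_age = 0,
    noise_sd = NA_real_,
    cord_shift = 0,
    stringsAsFactors = FALSE
  )
  eff$noise_sd <- eff$intercept * 0.25
  set_eff <- function(eff, name, ...) {
    vals <- list(...)
    i <- match(name, eff$analyte)
    for (k in names(vals)) eff[i, k] <- vals[[k]]
    eff
  }
  # strong predictors: the hemoglobin ratio declines steeply with both
  # gestational and postnatal age; TSH surges after birth; 17-OHP and the
  # short-chain acylcarnitines run higher in preterm infants.
  eff <- set_eff(eff, "HBF_HBA_RATIO", intercept = 4.2, slope_ga = -0.31,
                 slope_age = -0.006, noise_sd = 0.85, cord_shift = 0)
  eff <- set_eff(eff, "TSH", intercept = 6, slope_ga = -0.55,
                 slope_age = 0.35, noise_sd = 2.6, cord_shift = -0.5)
  eff <- set_eff(eff, "OHP17", intercept = 18, slope_ga = -1.5,
                 slope_age = -0.15, noise_sd = 8, cord_shift = 5)
  eff <- set_eff(eff, "ALA", intercept = 300, slope_ga = 7,
                 slope_age = 0.9, noise_sd = 45, cord_shift = -20)
  eff <- set_eff(eff, "C5", intercept = 0.12, slope_ga = -0.005,
                 slope_age = 0.0008, noise_sd = 0.030, cord_shift = 0.01)
  eff <- set_eff(eff, "C4DC", intercept = 0.35, slope_ga = -0.015,
                 slope_age = 0, noise_sd = 0.085, cord_shift = 0.02)
  eff <- set_eff(eff, "TYR", intercept = 130, slope_ga = 5.5,
                 slope_age = 1.0, noise_sd = 38, cord_shift = -8)
  # mild secondary signal on a few routine markers
  eff <- set_eff(eff, "PHE", intercept = 55, slope_ga = 1.2,
                 slope_age = 0.1, noise_sd = 12)
  eff <- set_eff(eff, "MET", intercept = 22, slope_ga = 0.5,
                 slope_age = 0.05, noise_sd = 6)
  eff <- set_eff(eff, "C0", intercept = 22, slope_ga = 0.6,
                 slope_age = 0.15, noise_sd = 7, cord_shift = -2)
  eff <- set_eff(eff, "C2", intercept = 18, slope_ga = 0.5,
                 slope_age = 0.12, noise_sd = 6, cord_shift = -1.5)
  eff <- set_eff(eff, "C3", intercept = 1.6, slope_ga = 0.04,
                 slope_age = 0.005, noise_sd = 0.5)
  eff <- set_eff(eff, "C16", intercept = 3.5, slope_ga = 0.08,
                 slope_age = 0.01, noise_sd = 1.1)
  eff <- set_eff(eff, "IRT", intercept = 22, slope_ga = 0.4,
                 slope_age = 0.08, noise_sd = 9, cord_shift = -2)
  eff
}
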