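# Birthweight-for-gestational-age reference charts and small-for-gestational-
# age (SGA) classification. SGA10/SGA3 are calls of birthweight strictly below
# the 10th/3rd percentile within categories of completed gestational week and
# infant sex, against a North-American-style reference distribution.

#' Build a birthweight-for-GA reference chart
#'
#' The chart is a Gaussian location/scale family per (sex, completed week):
#' percentiles P3/P10/P50/P90 are normal quantiles of the row's distribution.
#' The published North American reference is not reproduced here; the chart
#' format lets users supply a real reference via [read_reference_chart()].
#'
#' @param location function(sex, week) -> location in grams, or a data.frame
#'   with columns `sex`, `ga_week`, `location_g`, `scale_g`.
#' @param scale function(sex, week) -> SD in grams (ignored when `location`
#'   is a data.frame).
#' @param weeks integer vector of completed GA weeks to cover (both sexes are
#'   emitted for every week).
#' @return A `reference_chart` data.frame with columns `sex`, `ga_week`,
#'   `location_g`, `scale_g`, `p03_g`, `p10_g`, `p50_g`, `p90_g`.
#' @export
build_reference_chart <- function(location, scale = NULL, weeks = 24:43) {
  if (is.data.frame(location)) {
    rows <- location[, c("sex", "ga_week", "location_g", "scale_g")]
  } else {
    grid <- expand.grid(sex = c("female", "male"), ga_week = weeks,
                        stringsAsFactors = FALSE)
    rows <- data.frame(
      sex = grid$sex, ga_week = grid$ga_week,
      location_g = mapply(location, grid$sex, grid$ga_week),
      scale_g = mapply(scale, grid$sex, grid$ga_week)
    )
  }
  if (any(rows$scale_g <= 0)) stop("chart construction error: scale_g must be > 0")
  rows$p03_g <- qnorm(0.03, rows$location_g, rows$scale_g)
  rows$p10_g <- qnorm(0.10, rows$location_g, rows$scale_g)
  rows$p50_g <- rows$location_g
  rows$p90_g <- qnorm(0.90, rows$location_g, rows$scale_g)
  bad <- with(rows, !(p03_g < p10_g & p10_g < p50_g & p50_g < p90_g))
  if (any(bad)) {
    stop("chart construction error: non-monotone percentiles in ",
         sum(bad), " row(s)")
  }
  wk <- sort(unique(rows$ga_week))
  if (length(wk) > 1 && any(diff(wk) != 1)) {
    stop("chart construction error: covered GA weeks must be contiguous")
  }
  for (w in wk) {
    if (!all(c("female", "male") %in% rows$sex[rows$ga_week == w])) {
      stop("chart construction error: both sexes required for week ", w)
    }
  }
  rows <- rows[order(rows$sex, rows$ga_week), ]
  rownames(rows) <- NULL
  class(rows) <- c("reference_chart", "data.frame")
  rows
}

#' Default reference chart matched to the cohort simulator
#'
#' Location increases linearly with gestational week using the same
#' conditional birthweight model as [simulate_cohort()] under `config`;
#' constant scale. Classifying a cohort whose birthweights were drawn from
#' this chart recovers the nominal 10%/3% SGA rates.
#'
#' @param config a [simulation_config()] anchoring location and scale.
#' @param weeks completed GA weeks to cover.
#' @return a `reference_chart`.
#' @export
default_reference_chart <- function(config = simulation_config(),
                                    weeks = 24:43) {
  bm <- birthweight_model(config)
  build_reference_chart(
    location = function(sex, week) {
      bm$intercept40 + bm$slope * (week + 0.5 - 40) +
        if (sex == "male") bm$sex_shift else -bm$sex_shift
    },
    scale = function(sex, week) bm$sd,
    weeks = weeks
  )
}

#' Classify small-for-gestational-age status
#'
#' `TRUE` iff birthweight is strictly below the cut percentile for the
#' infant's sex and completed gestational week (floor of observed GA).
#' SGA3 calls are always a subset of SGA10 calls.
#'
#' @param birthweight_g,ga_obs_weeks,sex parallel vectors.
#' @param chart a `reference_chart`.
#' @param cut `"P10"` or `"P3"`.
#' @return logical vector.
#' @export
classify_sga <- function(birthweight_g, ga_obs_weeks, sex, chart,
                         cut = c("P10", "P3")) {
  cut <- match.arg(cut)
  wk <- floor(ga_obs_weeks)
  idx <- match(paste(sex, wk), paste(chart$sex, chart$ga_week))
  if (anyNA(idx)) {
    bad <- sort(unique(wk[is.na(idx)]))
    stop("gestational week(s) outside chart coverage: ",
         paste(bad, collapse = ", "))
  }
  ref <- if (cut == "P10") chart$p10_g[idx] else chart$p03_g[idx]
  birthweight_g < ref
}

#' Write / read a reference chart as delimited text
#' @param chart a `reference_chart`.
#' @param path file path.
#' @export
write_reference_chart <- function(chart, path) {
  utils::write.csv(as.data.frame(chart), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_chart
#' @export
read_reference_chart <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_reference_chart(rows[, c("sex", "ga_week", "location_g", "scale_g")])
}
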