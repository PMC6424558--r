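# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic tie rule used when pooling integer counts across imputations:
#' 310.5 rounds to 311, -310.5 to -311. `base::round()` rounds half to even,
#' which would make pooled counts depend on parity.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Evaluate code with a private RNG stream
#'
#' Saves and restores `.Random.seed` so package functions that seed the RNG do
#' not perturb the caller's random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a per-stage child seed from a base seed
#'
#' A single pipeline seed is fanned out to stage seeds by a fixed affine map
#' modulo 2^31 - 1, so stages are individually reproducible while remaining
#' jointly determined by one integer.
#' @keywords internal
child_seed <- function(seed, stage) {
  offsets <- c(
    simulate_train = 11L, simulate_external = 23L, missingness = 37L,
    impute = 51L, fit = 67L, score = 83L, bootstrap = 97L
  )
  if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown pipeline stage: ", stage)
    stage <- offsets[[stage]]
  }
  as.integer((as.double(seed) * 48271 + stage) %% 2147483647)
}

# truncated normal draw via inverse CDF (vectorised, exact given RNG state)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# mean and variance of a normal truncated to [lower, upper]
tnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, var = v)
}

# md5 digest of an R object via its canonical JSON serialisation
object_digest <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

fmt_pct <- function(x) round(x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
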