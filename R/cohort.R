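# Synthetic claims-cohort generator.
#
# Emulates the statistical shape of a large state-Medicaid diabetes cohort:
# 5 continuous and 12 binary covariates with a Gaussian-copula dependence
# structure, a mutually exclusive race indicator block, a complementary
# eligibility-category pair, and exposure/outcome labels generated from
# logistic models whose intercepts are calibrated so the marginal exposure
# prevalence and outcome risk hit configured targets (defaults 10.55% and
# 27.75%).

RACE_LEVELS <- c("race_white", "race_black", "race_amerind",
                 "race_asian", "race_hispanic", "race_unknown")
ELIG_PAIR <- c("elig_blind_disabled", "elig_adult")
FREE_BINARIES <- c("female", "tanf", "urban", "insulin")
CONTINUOUS_NAMES <- c("age", "distance", "elig_months", "mc_months",
                      "elixhauser")
BINARY_NAMES <- c("female", RACE_LEVELS, ELIG_PAIR, "tanf", "urban",
                  "insulin")
COVARIATE_NAMES <- c(CONTINUOUS_NAMES, BINARY_NAMES)

# One latent Gaussian dimension per continuous covariate and per free
# binary; the race block shares a single latent dimension (cut at
# cumulative category quantiles) and the eligibility pair shares one
# (complementary indicators cannot carry independent correlations).
LATENT_NAMES <- c(CONTINUOUS_NAMES, "female", "race", "eligibility",
                  "tanf", "urban", "insulin")

#' Default marginal specifications for the five continuous covariates
#'
#' Age is truncated normal on [18, 64] (working-age adults); distance to
#' the usual source of care is lognormal; months of Medicaid eligibility
#' and of managed-care enrollment are discretized truncated normals on
#' [0, 12]; the Elixhauser comorbidity count is a discretized lognormal.
#' All parameters are conventional right-shaped choices and fully
#' overridable through \code{\link{cohort_config}}.
#'
#' @return A named list of marginal specification lists.
#' @export
default_continuous_specs <- function() {
  list(
    age         = list(dist = "truncnorm", mean = 44, sd = 12,
                       lower = 18, upper = 64, discrete = FALSE),
    distance    = list(dist = "lognormal", meanlog = 1.8, sdlog = 0.9,
                       discrete = FALSE),
    elig_months = list(dist = "truncnorm", mean = 10, sd = 3.5,
                       lower = 0, upper = 12, discrete = TRUE),
    mc_months   = list(dist = "truncnorm", mean = 8, sd = 4.5,
                       lower = 0, upper = 12, discrete = TRUE),
    elixhauser  = list(dist = "lognormal", meanlog = 0.6, sdlog = 0.75,
                       discrete = TRUE)
  )
}

#' Default target prevalences for the twelve binary covariates
#'
#' The female proportion matches the anchor value 0.6359; the race block
#' sums to one; the blind/disabled and adult eligibility indicators are
#' complementary.  The remaining prevalences are plausible claims-cohort
#' values and are configurable.
#'
#' @return Named numeric vector of length 12.
#' @export
default_binary_prevalences <- function() {
  c(female = 0.6359,
    race_white = 0.36, race_black = 0.25, race_amerind = 0.02,
    race_asian = 0.05, race_hispanic = 0.24, race_unknown = 0.08,
    elig_blind_disabled = 0.35, elig_adult = 0.65,
    tanf = 0.15, urban = 0.75, insulin = 0.30)
}

#' Default latent correlation over the copula dimensions
#'
#' Moderate, clinically-signed associations: comorbidity burden rises
#' with age and insulin use, eligibility and managed-care months track
#' each other, distance falls with urban residence, and the
#' blind/disabled eligibility category is older and sicker.
#'
#' @return A symmetric positive-definite matrix with unit diagonal over
#'   \code{length(LATENT_NAMES)} dimensions.
#' @export
default_latent_correlation <- function() {
  d <- length(LATENT_NAMES)
  R <- diag(d)
  dimnames(R) <- list(LATENT_NAMES, LATENT_NAMES)
  set_pair <- function(a, b, rho) {
    R[a, b] <<- rho
    R[b, a] <<- rho
  }
  set_pair("age", "elixhauser", 0.35)
  set_pair("elixhauser", "insulin", 0.35)
  set_pair("age", "insulin", 0.15)
  set_pair("elig_months", "mc_months", 0.50)
  set_pair("distance", "urban", -0.40)
  set_pair("female", "tanf", 0.20)
  set_pair("age", "tanf", -0.25)
  set_pair("eligibility", "elixhauser", 0.30)
  set_pair("eligibility", "age", 0.25)
  set_pair("elig_months", "elixhauser", 0.15)
  R
}

#' Default exposure-model log-odds coefficients
#'
#' Applied to standardized continuous covariates and raw 0/1 indicators;
#' magnitudes are moderate (within \[-0.5, 0.5\]) and more than half of
#' the 17 covariates also appear in the outcome model, making them
#' confounders.
#'
#' @return Named numeric vector over the 17 covariates.
#' @export
default_exposure_coefficients <- function() {
  c(age = 0.10, distance = -0.35, elig_months = -0.30, mc_months = -0.25,
    elixhauser = -0.25, female = -0.15,
    race_white = -0.20, race_black = 0.20, race_amerind = 0,
    race_asian = -0.15, race_hispanic = 0.05, race_unknown = 0.10,
    elig_blind_disabled = -0.10, elig_adult = 0,
    tanf = 0.05, urban = 0.15, insulin = -0.10)
}

#' Default outcome-model log-odds coefficients
#'
#' @return Named numeric vector over the 17 covariates.
#' @export
default_outcome_coefficients <- function() {
  c(age = 0.30, distance = 0.05, elig_months = 0.20, mc_months = 0,
    elixhauser = 0.50, female = -0.10,
    race_white = -0.10, race_black = 0.15, race_amerind = 0,
    race_asian = -0.10, race_hispanic = 0, race_unknown = 0.05,
    elig_blind_disabled = 0.35, elig_adult = 0,
    tanf = 0.10, urban = -0.05, insulin = 0.30)
}

#' Build and validate a cohort-generator configuration
#'
#' @param n_subjects Number of subjects (default 42628, the empirical
#'   cohort size the generator emulates).
#' @param continuous_specs Named list of marginal specs, see
#'   \code{\link{default_continuous_specs}}.
#' @param binary_prevalences Named vector of 12 target prevalences.
#' @param latent_correlation Correlation matrix over the latent copula
#'   dimensions (\code{LATENT_NAMES} order).
#' @param exposure_coefficients,outcome_coefficients Named log-odds
#'   vectors over the covariates (missing names are treated as zero).
#' @param target_exposure_prevalence Marginal exposure target
#'   (default 0.1055).
#' @param target_outcome_risk Marginal outcome target (default 0.2775).
#' @param seed Integer RNG seed.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 42628,
                          continuous_specs = default_continuous_specs(),
                          binary_prevalences = default_binary_prevalences(),
                          latent_correlation = default_latent_correlation(),
                          exposure_coefficients = default_exposure_coefficients(),
                          outcome_coefficients = default_outcome_coefficients(),
                          target_exposure_prevalence = 0.1055,
                          target_outcome_risk = 0.2775,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              continuous_specs = continuous_specs,
              binary_prevalences = binary_prevalences,
              latent_correlation = latent_correlation,
              exposure_coefficients = exposure_coefficients,
              outcome_coefficients = outcome_coefficients,
              target_exposure_prevalence = target_exposure_prevalence,
              target_outcome_risk = target_outcome_risk,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @noRd
validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects <= 0L) stop("n_subjects must be positive", call. = FALSE)
  if (!is_probability(cfg$target_exposure_prevalence) ||
      !is_probability(cfg$target_outcome_risk)) {
    stop("targets must be probabilities strictly inside (0, 1)",
         call. = FALSE)
  }
  p <- cfg$binary_prevalences
  if (!all(BINARY_NAMES %in% names(p))) {
    stop("binary_prevalences must name all of: ",
         paste(BINARY_NAMES, collapse = ", "), call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("binary prevalences must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (abs(sum(p[RACE_LEVELS]) - 1) > 1e-8) {
    stop("race-block prevalences must sum to 1 (mutually exclusive block)",
         call. = FALSE)
  }
  if (abs(sum(p[ELIG_PAIR]) - 1) > 1e-8) {
    stop("eligibility-pair prevalences must sum to 1 (complementary pair)",
         call. = FALSE)
  }
  R <- cfg$latent_correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)) ||
      any(abs(diag(R) - 1) > 1e-10)) {
    stop("latent_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("latent_correlation is not positive definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  if (!setequal(names(cfg$continuous_specs), CONTINUOUS_NAMES)) {
    stop("continuous_specs must name: ",
         paste(CONTINUOUS_NAMES, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# quantile transform for one continuous marginal, u in (0,1)
#' @noRd
continuous_quantile <- function(u, spec) {
  x <- switch(spec$dist,
    truncnorm = {
      a <- stats::pnorm((spec$lower - spec$mean) / spec$sd)
      b <- stats::pnorm((spec$upper - spec$mean) / spec$sd)
      spec$mean + spec$sd * stats::qnorm(a + u * (b - a))
    },
    lognormal = stats::qlnorm(u, meanlog = spec$meanlog, sdlog = spec$sdlog),
    stop("unknown continuous distribution '", spec$dist, "'", call. = FALSE)
  )
  if (isTRUE(spec$discrete)) {
    x <- round(x)
    if (!is.null(spec$lower)) x <- pmax(x, spec$lower)
    if (!is.null(spec$upper)) x <- pmin(x, spec$upper)
  }
  x
}

#' Generate a synthetic base cohort
#'
#' Draws a multivariate standard normal with the configured latent
#' correlation, thresholds the binary dimensions at quantiles matching
#' the target prevalences (the race block is cut at cumulative category
#' quantiles of a single latent dimension; the eligibility pair is one
#' threshold and its complement), transforms the continuous dimensions
#' through their marginal inverse CDFs, then generates exposure and
#' outcome from logistic models with intercepts calibrated so the
#' marginal prevalence and risk meet the configured targets.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A \code{data.frame} with columns \code{subject_id},
#'   \code{source_id}, the 17 covariates, \code{exposure}, and
#'   \code{outcome}.  Cohort metadata (covariate roles, continuous
#'   standardization constants, realized rates, seed) is attached as
#'   attribute \code{"meta"}.
#' @export
#' @examples
#' cohort <- generate_base_cohort(cohort_config(n_subjects = 500, seed = 7))
#' mean(cohort$exposure)
generate_base_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  d <- length(LATENT_NAMES)
  L <- chol(config$latent_correlation)
  Z <- matrix(stats::rnorm(n * d), n, d) %*% L
  colnames(Z) <- LATENT_NAMES
  U <- stats::pnorm(Z)

  out <- data.frame(subject_id = seq_len(n), source_id = seq_len(n))
  for (nm in CONTINUOUS_NAMES) {
    out[[nm]] <- continuous_quantile(U[, nm], config$continuous_specs[[nm]])
  }
  p <- config$binary_prevalences
  for (nm in FREE_BINARIES) {
    out[[nm]] <- as.integer(U[, nm] > 1 - p[nm])
  }
  # race block: one latent cut at cumulative quantiles -> exactly one
  # indicator per subject
  cuts <- c(0, cumsum(p[RACE_LEVELS]))
  cuts[length(cuts)] <- 1
  race_cat <- cut(U[, "race"], breaks = cuts, labels = FALSE,
                  include.lowest = TRUE)
  for (i in seq_along(RACE_LEVELS)) {
    out[[RACE_LEVELS[i]]] <- as.integer(race_cat == i)
  }
  out$elig_blind_disabled <-
    as.integer(U[, "eligibility"] > 1 - p["elig_blind_disabled"])
  out$elig_adult <- 1L - out$elig_blind_disabled
  out <- out[, c("subject_id", "source_id", COVARIATE_NAMES)]

  cont_center <- vapply(out[CONTINUOUS_NAMES], mean, numeric(1))
  cont_scale <- vapply(out[CONTINUOUS_NAMES], stats::sd, numeric(1))
  meta <- list(covariate_names = COVARIATE_NAMES,
               continuous_names = CONTINUOUS_NAMES,
               binary_names = BINARY_NAMES,
               race_block = RACE_LEVELS,
               elig_pair = ELIG_PAIR,
               cont_center = cont_center,
               cont_scale = cont_scale,
               target_exposure_prevalence = config$target_exposure_prevalence,
               target_outcome_risk = config$target_outcome_risk,
               seed = config$seed)
  attr(out, "meta") <- meta

  X <- sim_model_matrix(out, meta)
  a_score <- drop(X %*% coef_over(config$exposure_coefficients, COVARIATE_NAMES))
  a0 <- calibrate_intercept(a_score, config$target_exposure_prevalence)
  out$exposure <- stats::rbinom(n, 1, stats::plogis(a0 + a_score))

  g_score <- drop(X %*% coef_over(config$outcome_coefficients, COVARIATE_NAMES))
  g0 <- calibrate_intercept(g_score, config$target_outcome_risk)
  out$outcome <- stats::rbinom(n, 1, stats::plogis(g0 + g_score))

  meta$realized_exposure_prevalence <- mean(out$exposure)
  meta$realized_outcome_risk <- mean(out$outcome)
  meta$exposure_intercept <- a0
  meta$outcome_intercept <- g0
  attr(out, "meta") <- meta
  out
}

# expand a (possibly partial) named coefficient vector over `names`,
# missing entries -> 0
#' @noRd
coef_over <- function(coefs, names) {
  out <- stats::setNames(numeric(length(names)), names)
  known <- intersect(names(coefs), names)
  unknown <- setdiff(names(coefs), names)
  if (length(unknown)) {
    stop("unknown covariate name(s) in coefficient vector: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out[known] <- coefs[known]
  out
}

#' Cohort metadata accessor
#'
#' @param cohort A cohort \code{data.frame}.
#' @return The metadata list attached by \code{\link{generate_base_cohort}}
#'   (or a minimal reconstruction from column names when absent, e.g. after
#'   external round-trips).
#' @export
cohort_meta <- function(cohort) {
  meta <- attr(cohort, "meta")
  if (!is.null(meta)) return(meta)
  covs <- intersect(COVARIATE_NAMES, names(cohort))
  list(covariate_names = covs,
       continuous_names = intersect(CONTINUOUS_NAMES, covs),
       binary_names = intersect(BINARY_NAMES, covs),
       race_block = intersect(RACE_LEVELS, covs),
       elig_pair = intersect(ELIG_PAIR, covs),
       cont_center = NULL, cont_scale = NULL)
}

# model matrix used by the exposure/outcome *simulation* models:
# standardized continuous covariates, raw binaries.  Standardization
# constants come from the BASE cohort so coefficients keep their meaning
# across plasmode replicates.
#' @noRd
sim_model_matrix <- function(cohort, meta = cohort_meta(cohort)) {
  X <- as.matrix(cohort[, meta$covariate_names, drop = FALSE])
  cn <- meta$continuous_names
  center <- meta$cont_center %||% vapply(cohort[cn], mean, numeric(1))
  scale <- meta$cont_scale %||% vapply(cohort[cn], stats::sd, numeric(1))
  X[, cn] <- sweep(sweep(X[, cn, drop = FALSE], 2, center), 2, scale, "/")
  X
}

#' Summarize a cohort (crude Table-1-style description)
#'
#' Per-covariate group means and crude standardized mean differences
#' (reported x100), plus overall exposure prevalence and outcome risk.
#'
#' @param cohort A cohort \code{data.frame}.
#' @return A \code{data.frame} with one row per covariate and columns
#'   \code{mean_exposed}, \code{mean_unexposed}, \code{smd}; attributes
#'   \code{exposure_prevalence}, \code{outcome_risk} and \code{n}.
#' @export
describe_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  meta <- cohort_meta(cohort)
  z <- cohort$exposure
  covs <- meta$covariate_names
  res <- data.frame(covariate = covs,
                    mean_exposed = NA_real_, mean_unexposed = NA_real_,
                    smd = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(covs)) {
    x <- cohort[[covs[i]]]
    m1 <- mean(x[z == 1])
    m0 <- mean(x[z == 0])
    sdp <- pooled_sd(x, z)
    res$mean_exposed[i] <- m1
    res$mean_unexposed[i] <- m0
    res$smd[i] <- if (sdp > 0) 100 * (m1 - m0) / sdp else NA_real_
  }
  attr(res, "exposure_prevalence") <- mean(z)
  attr(res, "outcome_risk") <- mean(cohort$outcome)
  attr(res, "n") <- nrow(cohort)
  res
}

# pooled (unweighted, groupwise) SD used by all SMD computations
#' @noRd
pooled_sd <- function(x, z) {
  v1 <- if (sum(z == 1) > 1) stats::var(x[z == 1]) else 0
  v0 <- if (sum(z == 0) > 1) stats::var(x[z == 0]) else 0
  sqrt((v1 + v0) / 2)
}

#' Write / read a cohort as delimited text plus a JSON metadata sidecar
#'
#' @param cohort Cohort \code{data.frame}.
#' @param path CSV file path; the metadata sidecar is written next to it
#'   with suffix \code{"_meta.json"}.
#' @return \code{write_cohort}: the CSV path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  meta <- cohort_meta(cohort)
  # named vectors must serialize as JSON objects, not bare arrays
  for (f in c("cont_center", "cont_scale")) {
    if (!is.null(meta[[f]])) meta[[f]] <- as.list(meta[[f]])
  }
  jsonlite::write_json(meta, cohort_meta_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  mp <- cohort_meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    meta$cont_center <- unlist(meta$cont_center)
    meta$cont_scale <- unlist(meta$cont_scale)
    attr(cohort, "meta") <- meta
  }
  cohort
}

#' @noRd
cohort_meta_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_meta.json")
}

# subset rows of a cohort, preserving metadata
#' @noRd
cohort_subset <- function(cohort, idx) {
  out <- cohort[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- attr(cohort, "meta")
  out
}
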