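# Plasmode-style simulation: resample base-cohort covariate rows with
# replacement (preserving their joint distribution), then regenerate
# exposure and/or outcome from logistic models with intercepts calibrated
# to the scenario's target prevalence/risk and a homogeneous or
# heterogeneous treatment effect injected into the outcome model.

#' Build and validate a simulation scenario configuration
#'
#' @param outcome_risk Target marginal outcome risk in (0,1), or the
#'   token \code{"observed"} to calibrate to the base cohort's realized
#'   risk.
#' @param exposure_prevalence Target exposure prevalence in (0,1), or
#'   \code{"observed"} to keep the resampled base-cohort exposure labels.
#' @param effect_type One of \code{"homogeneous"},
#'   \code{"heterogeneous_binary"}, \code{"heterogeneous_continuous"}.
#' @param effect_coefficient True treatment coefficient on the logit
#'   scale (default 1).
#' @param moderator_name Effect moderator for heterogeneous effects
#'   (default \code{"female"}; for the continuous case age is
#'   standardized to mean 0, SD 1 before use).
#' @param n_per_replicate Replicate sample size (default 4000).
#' @param n_replicates Number of replicates (default 500).
#' @param exposure_model_coefficients,outcome_model_coefficients Named
#'   log-odds vectors over covariates; defaults reuse the cohort
#'   generator's defaults.
#' @param truth_override Optional explicit true marginal effect;
#'   required for \code{heterogeneous_continuous} when the moderator
#'   mean is 0 (relative bias is undefined at truth 0).
#' @param master_seed Integer master seed; replicate \code{r} uses
#'   \code{\link{child_seed}(master_seed, r)}.
#' @param scenario_id Optional label carried into summaries.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(outcome_risk = "observed",
                            exposure_prevalence = "observed",
                            effect_type = c("homogeneous",
                                            "heterogeneous_binary",
                                            "heterogeneous_continuous"),
                            effect_coefficient = 1,
                            moderator_name = NULL,
                            n_per_replicate = 4000L,
                            n_replicates = 500L,
                            exposure_model_coefficients =
                              default_exposure_coefficients(),
                            outcome_model_coefficients =
                              default_outcome_coefficients(),
                            truth_override = NULL,
                            master_seed = 1L,
                            scenario_id = NULL) {
  effect_type <- match.arg(effect_type)
  if (is.null(moderator_name)) {
    moderator_name <- switch(effect_type,
                             heterogeneous_binary = "female",
                             heterogeneous_continuous = "age",
                             NA_character_)
  }
  check_rate <- function(x, what) {
    if (identical(x, "observed")) return(invisible())
    if (!is_probability(x)) {
      stop(what, " must be a probability in (0,1) or the token 'observed'",
           call. = FALSE)
    }
  }
  check_rate(outcome_risk, "outcome_risk")
  check_rate(exposure_prevalence, "exposure_prevalence")
  if (n_per_replicate <= 0 || n_replicates <= 0) {
    stop("n_per_replicate and n_replicates must be positive", call. = FALSE)
  }
  cfg <- list(outcome_risk = outcome_risk,
              exposure_prevalence = exposure_prevalence,
              effect_type = effect_type,
              effect_coefficient = effect_coefficient,
              moderator_name = moderator_name,
              n_per_replicate = as.integer(n_per_replicate),
              n_replicates = as.integer(n_replicates),
              exposure_model_coefficients = exposure_model_coefficients,
              outcome_model_coefficients = outcome_model_coefficients,
              truth_override = truth_override,
              master_seed = as.integer(master_seed),
              scenario_id = scenario_id %||% default_scenario_id(
                outcome_risk, exposure_prevalence, effect_type))
  class(cfg) <- "scenario_config"
  cfg
}

#' @noRd
default_scenario_id <- function(risk, prev, effect_type) {
  fmt <- function(x) if (identical(x, "observed")) "obs" else
    paste0(format(100 * x, trim = TRUE), "pct")
  paste0(effect_type, "_y", fmt(risk), "_z", fmt(prev))
}

#' Resample covariate rows with replacement
#'
#' Draws \code{n} rows uniformly with replacement from the base cohort;
#' covariate rows (and the base exposure/outcome labels) are copied
#' verbatim, \code{source_id} records the originating base
#' \code{subject_id} (the clustering unit for robust variance), and new
#' unique \code{subject_id}s are assigned.
#'
#' @param base Base cohort \code{data.frame}.
#' @param n Number of rows to draw.
#' @param seed Optional integer seed (\code{NULL} = use current RNG
#'   state).
#' @return A cohort of \code{n} rows.
#' @export
resample_covariates <- function(base, n, seed = NULL) {
  if (nrow(base) == 0L) stop("base cohort is empty", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(base), n, replace = TRUE)
  })
  out <- cohort_subset(base, idx)
  out$source_id <- base$subject_id[idx]
  out$subject_id <- seq_len(n)
  out
}

#' Calibrate a logistic-model intercept to a target marginal probability
#'
#' Finds \code{c} such that \code{mean(plogis(c + linear_scores))} equals
#' \code{target} to within \code{tol}, by monotone bisection on
#' \code{c} in \[-50, 50\].
#'
#' @param linear_scores Finite numeric vector of per-subject linear
#'   predictor contributions (excluding the intercept).
#' @param target Target probability in (0,1).
#' @param tol Tolerance on the marginal probability (default 1e-8).
#' @return The calibrated intercept, a single numeric.
#' @export
calibrate_intercept <- function(linear_scores, target, tol = 1e-8) {
  if (!all(is.finite(linear_scores))) {
    stop("linear_scores must be finite", call. = FALSE)
  }
  if (!is_probability(target)) {
    stop("target must be strictly inside (0, 1)", call. = FALSE)
  }
  f <- function(c) mean(stats::plogis(c + linear_scores)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibration failure: target ", target,
         " not bracketed for intercept in [-50, 50]", call. = FALSE)
  }
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  mid
}

#' Simulate exposure from a calibrated logistic model
#'
#' Draws \code{Bernoulli(plogis(c + alpha'x))} with the intercept
#' calibrated on the replicate at hand so the mean assignment
#' probability equals the scenario target.  When the scenario uses the
#' \code{"observed"} exposure token the resampled base labels are kept
#' and this operation is bypassed by the orchestrator.
#'
#' @param cohort Replicate cohort.
#' @param scenario A \code{\link{scenario_config}} with numeric
#'   \code{exposure_prevalence}.
#' @param seed Optional integer seed.
#' @return The cohort with its \code{exposure} column replaced; the
#'   realized prevalence is attached as attribute
#'   \code{"realized_prevalence"}.
#' @export
simulate_exposure <- function(cohort, scenario, seed = NULL) {
  if (identical(scenario$exposure_prevalence, "observed")) {
    stop("scenario uses observed exposure labels; simulate_exposure ",
         "should be bypassed", call. = FALSE)
  }
  meta <- cohort_meta(cohort)
  X <- sim_model_matrix(cohort, meta)
  score <- drop(X %*% coef_over(scenario$exposure_model_coefficients,
                                meta$covariate_names))
  c0 <- calibrate_intercept(score, scenario$exposure_prevalence)
  with_seed(seed, {
    cohort$exposure <- stats::rbinom(nrow(cohort), 1,
                                     stats::plogis(c0 + score))
  })
  attr(cohort, "realized_prevalence") <- mean(cohort$exposure)
  cohort
}

# moderator values on the scale used in the outcome linear predictor:
# binary moderators raw, continuous moderators standardized by the BASE
# cohort's mean/SD
#' @noRd
moderator_values <- function(cohort, scenario, meta) {
  m <- scenario$moderator_name
  if (!m %in% meta$covariate_names) {
    stop("unknown moderator '", m, "'", call. = FALSE)
  }
  x <- cohort[[m]]
  if (m %in% meta$continuous_names) {
    center <- (meta$cont_center %||% stats::setNames(mean(x), m))[m]
    scale <- (meta$cont_scale %||% stats::setNames(stats::sd(x), m))[m]
    x <- (x - center) / scale
  }
  x
}

#' True marginal effect implied by a scenario
#'
#' Homogeneous: the treatment coefficient itself.  Heterogeneous: the
#' coefficient times the BASE-cohort mean of the moderator (so all
#' replicates of a scenario share one truth); for a continuous moderator
#' standardized to mean 0 this is degenerate for relative bias, and an
#' explicit \code{truth_override} is required.
#'
#' @param scenario A \code{\link{scenario_config}}.
#' @param base Base cohort (source of the moderator mean).
#' @return A single numeric.
#' @export
true_marginal_effect <- function(scenario, base) {
  if (!is.null(scenario$truth_override)) return(scenario$truth_override)
  switch(scenario$effect_type,
    homogeneous = scenario$effect_coefficient,
    heterogeneous_binary = {
      meta <- cohort_meta(base)
      scenario$effect_coefficient *
        mean(moderator_values(base, scenario, meta))
    },
    heterogeneous_continuous = {
      stop("heterogeneous_continuous scenarios require an explicit ",
           "truth_override: the standardized moderator has mean 0, so ",
           "the implied marginal effect is 0 and relative bias is ",
           "undefined", call. = FALSE)
    })
}

#' Simulate the outcome with an injected treatment effect
#'
#' Draws \code{Bernoulli(plogis(c + gamma'x + T))} where \code{T} is
#' \code{beta * Z} (homogeneous) or \code{beta * Z * M} (heterogeneous,
#' with moderator \code{M}; continuous moderators are standardized
#' first).  The intercept is calibrated on the replicate with its
#' assigned exposures so the marginal risk matches the target.
#'
#' @param cohort Replicate cohort with exposure assigned.
#' @param scenario A \code{\link{scenario_config}}.
#' @param seed Optional integer seed.
#' @param base Base cohort used for the truth bookkeeping (defaults to
#'   \code{cohort}, which is only appropriate when analysing the base
#'   itself).
#' @param replicate_index Replicate number recorded in the result.
#' @return A \code{simulated_dataset}: list with elements \code{cohort},
#'   \code{scenario}, \code{replicate_index}, \code{realized_prevalence},
#'   \code{realized_risk}, \code{true_marginal_effect}.
#' @export
simulate_outcome <- function(cohort, scenario, seed = NULL, base = cohort,
                             replicate_index = NA_integer_) {
  meta <- cohort_meta(cohort)
  X <- sim_model_matrix(cohort, meta)
  score <- drop(X %*% coef_over(scenario$outcome_model_coefficients,
                                meta$covariate_names))
  z <- cohort$exposure
  beta <- scenario$effect_coefficient
  treat_term <- switch(scenario$effect_type,
    homogeneous = beta * z,
    heterogeneous_binary = ,
    heterogeneous_continuous =
      beta * z * moderator_values(cohort, scenario, meta))
  target <- if (identical(scenario$outcome_risk, "observed")) {
    cohort_meta(base)$realized_outcome_risk %||% mean(base$outcome)
  } else scenario$outcome_risk
  c0 <- calibrate_intercept(score + treat_term, target)
  with_seed(seed, {
    cohort$outcome <- stats::rbinom(nrow(cohort), 1,
                                    stats::plogis(c0 + score + treat_term))
  })
  structure(list(cohort = cohort,
                 scenario = scenario,
                 replicate_index = replicate_index,
                 realized_prevalence = mean(z),
                 realized_risk = mean(cohort$outcome),
                 true_marginal_effect = true_marginal_effect(scenario, base)),
            class = "simulated_dataset")
}

#' Produce one complete simulation replicate
#'
#' Resamples covariates from the base cohort, simulates exposure (unless
#' the scenario keeps observed labels) and then the outcome, using a
#' child seed derived from the scenario's master seed and the replicate
#' index.
#'
#' @param base Base cohort.
#' @param scenario A \code{\link{scenario_config}}.
#' @param replicate_index Replicate number (1-based).
#' @return A \code{simulated_dataset}.
#' @export
simulate_replicate <- function(base, scenario, replicate_index) {
  seed <- child_seed(scenario$master_seed, replicate_index)
  set.seed(seed)
  cohort <- resample_covariates(base, scenario$n_per_replicate)
  if (!identical(scenario$exposure_prevalence, "observed")) {
    cohort <- simulate_exposure(cohort, scenario)
  }
  simulate_outcome(cohort, scenario, base = base,
                   replicate_index = replicate_index)
}
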