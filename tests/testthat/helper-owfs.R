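# Shared fixtures, all generated in code.

# Minimal cohort with arbitrary covariates and hand-attached metadata
# (no exhaustive blocks), for unit tests that do not need the full
# 17-covariate generator.
make_toy_cohort <- function(covs, exposure, outcome = NULL,
                            source_id = NULL) {
  n <- length(exposure)
  df <- data.frame(subject_id = seq_len(n),
                   source_id = source_id %||% seq_len(n))
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  df$exposure <- exposure
  df$outcome <- outcome %||% rep(0L, n)
  binary <- names(covs)[vapply(covs, function(x) all(x %in% c(0, 1)),
                               logical(1))]
  cont <- setdiff(names(covs), binary)
  attr(df, "meta") <- list(
    covariate_names = names(covs),
    continuous_names = cont,
    binary_names = binary,
    race_block = character(0),
    elig_pair = character(0),
    cont_center = vapply(df[cont], mean, numeric(1)),
    cont_scale = vapply(df[cont], stats::sd, numeric(1)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random confounded fixture: 4 continuous + 1 binary covariate,
# logistic exposure; small n for weight-identity sweeps.
random_fixture <- function(seed, n = 250, prevalence_logit = -0.8) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4)
  b <- rbinom(n, 1, 0.4)
  eta <- prevalence_logit + 0.5 * x[, 1] - 0.4 * x[, 2] + 0.6 * b
  z <- rbinom(n, 1, plogis(eta))
  make_toy_cohort(list(x1 = x[, 1], x2 = x[, 2], x3 = x[, 3],
                       x4 = x[, 4], b1 = b),
                  exposure = z,
                  outcome = rbinom(n, 1, 0.3))
}

# Hand-built propensity "fit" for tests that exercise weighting logic
# with known scores.
fake_ps_fit <- function(scores, converged = TRUE) {
  structure(list(scores = scores, converged = converged,
                 separation = FALSE, n_iterations = 0L,
                 coefficients = numeric(0)),
            class = "ps_fit")
}

# Small shared base cohort for scenario-level tests (module scale).
small_base <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_base_cohort(cohort_config(n_subjects = 3000,
                                                   seed = 424242))
    }
    cache
  }
})
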