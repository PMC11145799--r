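test_that("calibrate_intercept solves the marginal probability equation", {
  # closed forms with all-zero scores
  expect_equal(calibrate_intercept(rep(0, 50), 0.5), 0, tolerance = 1e-7)
  expect_equal(calibrate_intercept(rep(0, 50), 0.1055),
               log(0.1055 / 0.8945), tolerance = 1e-6)
  # heterogeneous scores, rare target: verify by direct averaging
  set.seed(8)
  s <- rnorm(5000, sd = 1.3)
  c0 <- calibrate_intercept(s, 0.01)
  expect_lt(abs(mean(plogis(c0 + s)) - 0.01), 1e-7)
  expect_error(calibrate_intercept(c(0, Inf), 0.5), "finite")
  expect_error(calibrate_intercept(rep(0, 5), 1.5), "inside")
})

test_that("resample_covariates copies rows verbatim with provenance", {
  base <- small_base()
  one <- cohort_subset(base, 17)
  r <- resample_covariates(one, 5, seed = 1)
  expect_equal(nrow(r), 5)
  expect_true(all(r$source_id == one$subject_id))
  expect_true(all(r$age == one$age))
  expect_equal(r$subject_id, 1:5)
  expect_error(resample_covariates(base, 0), "positive")
})

test_that("resampling matches the occupancy-formula oracle", {
  base <- cohort_subset(small_base(), 1:500)
  N <- nrow(base); n <- 200
  expected_distinct <- N * (1 - (1 - 1 / N)^n)
  distinct <- vapply(1:40, function(s) {
    length(unique(resample_covariates(base, n, seed = s)$source_id))
  }, numeric(1))
  expect_lt(abs(mean(distinct) - expected_distinct),
            3 * sd(distinct) / sqrt(40) + 1)
})

test_that("resampled covariate means obey the CLT oracle", {
  base <- small_base()
  mu <- mean(base$age); s <- sd(base$age); n <- 1000
  hits <- vapply(1:20, function(seed) {
    abs(mean(resample_covariates(base, n, seed = seed)$age) - mu) <
      3 * s / sqrt(n)
  }, logical(1))
  expect_gte(sum(hits), 18)  # ~99.7% nominal; allow sampling slack
})

test_that("simulate_exposure hits targets and respects the null", {
  base <- small_base()
  co <- resample_covariates(base, 4000, seed = 2)
  # alpha = 0: no confounding at 30%
  sc0 <- scenario_config(exposure_prevalence = 0.30,
                         exposure_model_coefficients = c(age = 0))
  e0 <- simulate_exposure(co, sc0, seed = 3)
  expect_lt(abs(mean(e0$exposure) - 0.30), 3 * sqrt(0.3 * 0.7 / 4000))
  expect_lt(abs(cor(e0$exposure, e0$elixhauser)), 0.05)
  # rare target: expected exposed count n * p = 100
  sc <- scenario_config(exposure_prevalence = 0.025)
  counts <- vapply(1:50, function(s)
    sum(simulate_exposure(co, sc, seed = s)$exposure), numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sd(counts) / sqrt(50))
  # monotonicity: higher linear score -> higher empirical exposure rate
  meta <- cohort_meta(co)
  X <- as.matrix(co[, meta$covariate_names])
  X[, meta$continuous_names] <- scale(X[, meta$continuous_names],
                                      center = meta$cont_center,
                                      scale = meta$cont_scale)
  score <- drop(X %*% default_exposure_coefficients())
  sc2 <- scenario_config(exposure_prevalence = 0.30)
  e2 <- simulate_exposure(co, sc2, seed = 9)
  top <- score >= quantile(score, 0.9)
  bottom <- score <= quantile(score, 0.1)
  expect_gt(mean(e2$exposure[top]), mean(e2$exposure[bottom]))
  expect_error(simulate_exposure(co, scenario_config(), seed = 1),
               "observed")
})

test_that("simulate_outcome injects the effect and records the truth", {
  base <- small_base()
  co <- resample_covariates(base, 4000, seed = 4)
  co <- simulate_exposure(co, scenario_config(exposure_prevalence = 0.1),
                          seed = 5)
  # null effect: crude estimate centered at 0 over replicate draws
  sc_null <- scenario_config(outcome_risk = 0.3, effect_coefficient = 0)
  ests <- vapply(1:25, function(s) {
    sim <- simulate_outcome(co, sc_null, seed = s, base = base)
    estimate_effect(sim, crude_weights(sim$cohort))$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(25))
  # heterogeneous-by-sex truth = beta x base female proportion
  sc_het <- scenario_config(outcome_risk = 0.3,
                            effect_type = "heterogeneous_binary")
  sim <- simulate_outcome(co, sc_het, seed = 6, base = base)
  expect_equal(sim$true_marginal_effect, mean(base$female))
  # rare outcome: expected events = n x risk = 40
  sc_rare <- scenario_config(outcome_risk = 0.01)
  ev <- vapply(1:60, function(s)
    sum(simulate_outcome(co, sc_rare, seed = s,
                         base = base)$cohort$outcome), numeric(1))
  expect_lt(abs(mean(ev) - 40), 3 * sd(ev) / sqrt(60))
  expect_error(
    simulate_outcome(co, scenario_config(outcome_risk = 0.3,
                                         effect_type = "heterogeneous_binary",
                                         moderator_name = "nope"),
                     seed = 1, base = base),
    "unknown moderator")
})

test_that("calibration holds at scenario level across replicates", {
  base <- small_base()
  sc <- scenario_config(outcome_risk = 0.10, exposure_prevalence = 0.10,
                        n_per_replicate = 1000, master_seed = 77)
  risks <- prevs <- numeric(100)
  for (r in 1:100) {
    sim <- simulate_replicate(base, sc, r)
    risks[r] <- sim$realized_risk
    prevs[r] <- sim$realized_prevalence
  }
  expect_lt(abs(mean(risks) - 0.10), 3 * sd(risks) / sqrt(100))
  expect_lt(abs(mean(prevs) - 0.10), 3 * sd(prevs) / sqrt(100))
})

test_that("seed discipline: identical configs give identical streams", {
  base <- small_base()
  sc <- scenario_config(outcome_risk = 0.2, exposure_prevalence = 0.2,
                        n_per_replicate = 300, master_seed = 5)
  a <- simulate_replicate(base, sc, 3)
  b <- simulate_replicate(base, sc, 3)
  expect_identical(a$cohort, b$cohort)
  # different replicate index -> different draw
  c3 <- simulate_replicate(base, sc, 4)
  expect_false(identical(a$cohort$source_id, c3$cohort$source_id))
  expect_identical(child_seed(1, 5), child_seed(1, 5))
  expect_false(child_seed(1, 5) == child_seed(1, 6))
  expect_true(child_seed(2^30, 10^6) < 2^31)
})

test_that("continuous-moderator scenarios demand an explicit truth", {
  base <- small_base()
  sc <- scenario_config(outcome_risk = 0.3,
                        effect_type = "heterogeneous_continuous")
  expect_error(true_marginal_effect(sc, base), "truth_override")
  sc2 <- scenario_config(outcome_risk = 0.3,
                         effect_type = "heterogeneous_continuous",
                         truth_override = 0.5)
  expect_equal(true_marginal_effect(sc2, base), 0.5)
})
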