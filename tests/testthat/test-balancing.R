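test_that("overlap weights follow the definitional assignment", {
  co <- make_toy_cohort(list(x = c(0.5, -0.5)), exposure = c(1, 0))
  fit <- fake_ps_fit(c(0.3, 0.3))
  wa <- overlap_weights(fit, co)
  expect_equal(wa$weights, c(0.7, 0.3))  # treated 1-PS, control PS
  expect_true(all(wa$included))
  expect_equal(wa$n_used, 2L)
  expect_warning(overlap_weights(fake_ps_fit(c(0.3, 0.3), converged = FALSE),
                                 co), "non-converged")
})

test_that("overlap weights equalize group totals on converged MLE fits", {
  for (seed in c(11, 12, 13)) {
    co <- random_fixture(seed, n = 600)
    fit <- fit_propensity(co)
    wa <- overlap_weights(fit, co)
    z <- co$exposure
    expect_lt(abs(sum(wa$weights[z == 1]) - sum(wa$weights[z == 0])), 1e-6)
    expect_true(all(wa$weights > 0 & wa$weights < 1))
  }
})

test_that("fine stratification follows the exposed-quantile rule", {
  # 40 exposed with distinct scores, k = 20 -> exactly 2 exposed each
  set.seed(1)
  ps_exp <- sort(runif(40, 0.1, 0.9))
  ps_ctl <- runif(30, 0.15, 0.85)
  co <- make_toy_cohort(list(x = rnorm(70)),
                        exposure = c(rep(1L, 40), rep(0L, 30)))
  st <- fine_stratify(fake_ps_fit(c(ps_exp, ps_ctl)), co, 20)
  expect_equal(st$n_exposed, rep(2L, 20))
  # controls all inside the exposed range -> no non-overlap exclusions
  expect_equal(st$excluded_nonoverlap, 0L)

  # a control strictly above the exposed maximum is excluded
  co2 <- make_toy_cohort(list(x = rnorm(22)),
                         exposure = c(rep(1L, 21), 0L))
  st2 <- fine_stratify(fake_ps_fit(c(seq(0.2, 0.8, length.out = 21), 0.95)),
                       co2, 21)
  expect_equal(st2$excluded_nonoverlap, 1L)
  expect_true(is.na(st2$stratum_id[22]))

  expect_error(fine_stratify(fake_ps_fit(runif(10)), co[1:10, ], 20),
               "fewer exposed")
})

test_that("stratum weights match the published ATE formulas", {
  # one stratum: N_i = 10, N_exp_i = 2, N_unexp_i = 8
  co <- make_toy_cohort(list(x = rnorm(10)),
                        exposure = c(rep(1L, 2), rep(0L, 8)))
  st <- structure(list(boundaries = c(0, 1),
                       stratum_id = rep(1L, 10),
                       n_total = 10L, n_exposed = 2L, n_unexposed = 8L,
                       retained = TRUE, excluded_nonoverlap = 0L),
                  class = "stratification")
  equ <- fs_weights(st, co, "equ")
  expect_equal(unique(equ$weights[co$exposure == 1]), 5)     # N_i/N_exp_i
  expect_equal(unique(equ$weights[co$exposure == 0]), 1.25)  # N_i/N_unexp_i
  # two strata so totals differ from stratum counts:
  # stratum 1 as above inside N = 100, N_exp = 10
  co2 <- make_toy_cohort(list(x = rnorm(100)),
                         exposure = c(rep(1L, 2), rep(0L, 8),
                                      rep(1L, 8), rep(0L, 82)))
  st2 <- structure(list(boundaries = c(0, 0.5, 1),
                        stratum_id = rep(c(1L, 2L), c(10, 90)),
                        n_total = c(10L, 90L), n_exposed = c(2L, 8L),
                        n_unexposed = c(8L, 82L), retained = c(TRUE, TRUE),
                        excluded_nonoverlap = 0L),
                   class = "stratification")
  unequ <- fs_weights(st2, co2, "unequ")
  # (N_i/N)/(N_exp_i/N_exp) = (10/100)/(2/10) = 0.5
  expect_equal(unequ$weights[1], 0.5)
  expect_error(fs_weights(st, co, "nope"))
})

test_that("weight-total identities hold on fitted stratifications", {
  for (seed in c(21, 22)) {
    co <- random_fixture(seed, n = 700, prevalence_logit = -0.4)
    fit <- fit_propensity(co)
    st <- fine_stratify(fit, co, 10)
    z <- co$exposure
    equ <- fs_weights(st, co, "equ")
    inc <- equ$included
    n_ret <- sum(inc)
    # equ: each group's weights total the retained sample size
    expect_equal(sum(equ$weights[z == 1]), n_ret, tolerance = 1e-9)
    expect_equal(sum(equ$weights[z == 0]), n_ret, tolerance = 1e-9)
    # and per-stratum group weight sums both equal N_i
    for (s in which(st$retained)) {
      in_s <- !is.na(equ$stratum_id) & equ$stratum_id == s
      expect_equal(sum(equ$weights[in_s & z == 1]), sum(in_s),
                   tolerance = 1e-9)
      expect_equal(sum(equ$weights[in_s & z == 0]), sum(in_s),
                   tolerance = 1e-9)
    }
    # unequ: group totals equal the retained group sizes
    unequ <- fs_weights(st, co, "unequ")
    expect_equal(sum(unequ$weights[z == 1]), sum(inc & z == 1),
                 tolerance = 1e-9)
    expect_equal(sum(unequ$weights[z == 0]), sum(inc & z == 0),
                 tolerance = 1e-9)
  }
})

test_that("non-overlap exclusions never decrease with more strata", {
  co <- random_fixture(33, n = 900, prevalence_logit = -1.5)
  fit <- fit_propensity(co)
  excl <- vapply(c(5, 10, 20, 40),
                 function(k) fine_stratify(fit, co, k)$excluded_nonoverlap,
                 numeric(1))
  expect_true(all(diff(excl) >= 0))
})

test_that("pruning removes single-group cells and is idempotent", {
  # every cell occupied by both groups -> identity
  co <- make_toy_cohort(list(b1 = rep(c(0, 1), each = 4),
                             b2 = rep(c(0, 0, 1, 1), 2)),
                        exposure = rep(c(1, 0), 4))
  p1 <- prune_unmatched(co, c("b1", "b2"))
  expect_equal(nrow(p1), nrow(co))
  expect_equal(attr(p1, "n_removed"), 0L)

  # a cell occupied only by controls is removed
  co2 <- make_toy_cohort(list(b1 = c(0, 0, 1, 1, 1), b2 = c(0, 0, 0, 0, 0)),
                         exposure = c(1L, 0L, 0L, 0L, 0L))
  p2 <- prune_unmatched(co2, c("b1", "b2"))
  expect_equal(attr(p2, "n_removed"), 3L)
  expect_true(all(p2$b1 == 0))

  # idempotent
  p3 <- prune_unmatched(p2, c("b1", "b2"))
  expect_equal(p3[names(p3)], p2[names(p2)])
  expect_equal(attr(p3, "n_removed"), 0L)

  # all cells unmatched -> error
  co3 <- make_toy_cohort(list(b1 = c(0, 1)), exposure = c(1L, 0L))
  expect_error(prune_unmatched(co3, "b1"), "every subject")
  expect_error(prune_unmatched(co2, "nope"), "not found")
})

test_that("pruning magnitude on a base-like cohort is small", {
  base <- small_base()
  pruned <- prune_unmatched(base)
  # the pruned fraction shrinks with cohort size (rare cells fill in);
  # at n = 3000 a few percent is expected, far below any mass pruning
  frac <- attr(pruned, "n_removed") / nrow(base)
  expect_gt(frac, 0)
  expect_lt(frac, 0.10)
})
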