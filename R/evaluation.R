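# Monte Carlo evaluation harness: run scenarios x methods x replicates
# and compute the evaluation criteria (mean MB, relative bias and its
# SD, rMSE, mean robust SE, coverage, coverageT, significance, mean N
# used) with Monte Carlo errors.

ALL_METHODS <- c("crude", "OW_F", "OW_X",
                 "FS_F_equ", "FS_X_equ", "FS_F_unequ", "FS_X_unequ")

#' Run one simulation scenario across methods and replicates
#'
#' For each replicate: resample covariates from the base cohort,
#' simulate exposure and/or outcome per the scenario, build the full
#' ("F") and pruned ("X") analyzed datasets, fit the propensity model on
#' each (refit after pruning), derive each method's weights, compute the
#' balance report, and estimate the effect.  Per-replicate failures are
#' recorded as failed records; they never abort the scenario.
#'
#' @param scenario A \code{\link{scenario_config}}.
#' @param base Base cohort.
#' @param methods Subset of
#'   \code{c("crude","OW_F","OW_X","FS_F_equ","FS_X_equ","FS_F_unequ",
#'   "FS_X_unequ")}.
#' @param k_strata Number of fine-stratification strata (default 20).
#' @param n_replicates Optional override of the scenario's replicate
#'   count.
#' @return A list of \code{estimate_record}s (length replicates x
#'   methods), with attributes \code{scenario} and \code{truth}.
#' @export
run_scenario <- function(scenario, base, methods = ALL_METHODS,
                         k_strata = 20L, n_replicates = NULL) {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  R <- n_replicates %||% scenario$n_replicates
  truth <- true_marginal_effect(scenario, base)
  needs_F_ps <- any(c("OW_F", "FS_F_equ", "FS_F_unequ") %in% methods)
  needs_X <- any(c("OW_X", "FS_X_equ", "FS_X_unequ") %in% methods)
  needs_F_fs <- any(c("FS_F_equ", "FS_F_unequ") %in% methods)
  needs_X_fs <- any(c("FS_X_equ", "FS_X_unequ") %in% methods)
  records <- vector("list", R * length(methods))
  k <- 0L
  for (r in seq_len(R)) {
    sim <- simulate_replicate(base, scenario, r)
    F_cohort <- sim$cohort
    fit_F <- strat_F <- NULL
    X_cohort <- fit_X <- strat_X <- NULL
    prep_err <- NULL
    tryCatch({
      if (needs_F_ps) {
        fit_F <- fit_propensity(F_cohort)
        if (needs_F_fs) strat_F <- fine_stratify(fit_F, F_cohort, k_strata)
      }
      if (needs_X) {
        X_cohort <- prune_unmatched(F_cohort)
        fit_X <- fit_propensity(X_cohort)
        if (needs_X_fs) strat_X <- fine_stratify(fit_X, X_cohort, k_strata)
      }
    }, error = function(e) prep_err <<- conditionMessage(e))
    for (m in methods) {
      k <- k + 1L
      records[[k]] <- tryCatch({
        if (!is.null(prep_err)) stop(prep_err, call. = FALSE)
        dat <- if (grepl("_X", m, fixed = TRUE)) X_cohort else F_cohort
        wa <- switch(m,
          crude = crude_weights(F_cohort),
          OW_F = overlap_weights(fit_F, F_cohort, "OW_F"),
          OW_X = overlap_weights(fit_X, X_cohort, "OW_X"),
          FS_F_equ = fs_weights(strat_F, F_cohort, "equ", "FS_F_equ"),
          FS_F_unequ = fs_weights(strat_F, F_cohort, "unequ", "FS_F_unequ"),
          FS_X_equ = fs_weights(strat_X, X_cohort, "equ", "FS_X_equ"),
          FS_X_unequ = fs_weights(strat_X, X_cohort, "unequ", "FS_X_unequ"))
        bal <- balance_report(dat, wa)
        estimate_effect(dat, wa, balance = bal, replicate_index = r)
      }, error = function(e) failed_record(m, r, conditionMessage(e)))
    }
  }
  structure(records, scenario = scenario, truth = truth)
}

#' @noRd
failed_record <- function(method_label, replicate_index, message) {
  structure(list(method_label = method_label,
                 replicate_index = replicate_index,
                 estimate = NA_real_, robust_se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, n_used = NA_integer_,
                 converged = FALSE, separation_flag = TRUE,
                 fallback_family = NA_character_, balance = NULL,
                 error = message),
            class = "estimate_record")
}

#' Flatten estimate records into a data frame
#'
#' @param records List of \code{estimate_record}s (e.g. from
#'   \code{\link{run_scenario}}).
#' @return One row per record with estimate, robust SE, CI, p-value,
#'   flags, N used, and the record's MB.
#' @export
records_to_dataframe <- function(records) {
  getn <- function(f, default = NA_real_) {
    vapply(records, function(r) r[[f]] %||% default, default)
  }
  data.frame(
    method = getn("method_label", NA_character_),
    replicate = vapply(records, function(r)
      as.integer(r$replicate_index %||% NA_integer_), integer(1)),
    estimate = getn("estimate"),
    robust_se = getn("robust_se"),
    ci_low = getn("ci_low"),
    ci_high = getn("ci_high"),
    p_value = getn("p_value"),
    n_used = vapply(records, function(r)
      as.integer(r$n_used %||% NA_integer_), integer(1)),
    converged = vapply(records, function(r) isTRUE(r$converged), logical(1)),
    separation_flag = vapply(records, function(r)
      isTRUE(r$separation_flag), logical(1)),
    mb = vapply(records, function(r)
      if (is.null(r$balance)) NA_real_ else r$balance$mb, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Monte Carlo error of a mean
#'
#' \code{sd(values) / sqrt(length(values))}.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param stat Statistic the MCE refers to; only \code{"mean"} is
#'   defined.
#' @return A single numeric.
#' @export
monte_carlo_error <- function(values, stat = "mean") {
  stat <- match.arg(stat, "mean")
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("Monte Carlo error undefined for fewer than 2 values",
         call. = FALSE)
  }
  stats::sd(values) / sqrt(length(values))
}

#' Summarize one method's records into the evaluation criteria
#'
#' Relative bias is \code{100 * (estimate - truth) / truth}; rMSE is
#' \code{sqrt(mean((estimate - truth)^2))} (squared bias on the raw
#' scale plus variance); coverage is the percentage of 95\% CIs
#' containing the truth; coverageT additionally requires the CI to
#' exclude zero; significance is the percentage with two-sided
#' \code{p < 0.05}.  Records that failed or did not converge contribute
#' to bookkeeping but not to the means; separation-flagged records are
#' excluded only when \code{exclude_flagged} (the sensitivity rerun).
#'
#' @param records List of \code{estimate_record}s for ONE method (mixed
#'   input is split by \code{\link{summarize_scenario}}).
#' @param truth True marginal effect (must be nonzero).
#' @param exclude_flagged Exclude separation-flagged records.
#' @param scenario_id,method_label Labels for the output row.
#' @return A one-row \code{data.frame} of class criteria:
#'   \code{mean_mb}, \code{mean_rbias}, \code{sd_rbias}, \code{rmse},
#'   \code{mean_se}, \code{coverage}, \code{coverageT},
#'   \code{significance}, \code{mean_n_used}, \code{mce_rbias},
#'   \code{mce_mb}, \code{n_replicates_used}, \code{flagged_excluded}.
#' @export
summarize_criteria <- function(records, truth, exclude_flagged = FALSE,
                               scenario_id = NA_character_,
                               method_label = NULL) {
  if (!is.finite(truth) || truth == 0) {
    stop("relative-bias criteria are undefined at truth = 0; supply a ",
         "nonzero truth (see truth_override for continuous-moderator ",
         "scenarios)", call. = FALSE)
  }
  df <- records_to_dataframe(records)
  method_label <- method_label %||% df$method[1L]
  usable <- df$converged & is.finite(df$estimate) & is.finite(df$robust_se)
  if (exclude_flagged) usable <- usable & !df$separation_flag
  if (!any(usable)) {
    stop("no usable records to summarize for method '", method_label, "'",
         call. = FALSE)
  }
  d <- df[usable, , drop = FALSE]
  rbias <- 100 * (d$estimate - truth) / truth
  covers <- d$ci_low <= truth & truth <= d$ci_high
  coversT <- covers & (d$ci_low > 0 | d$ci_high < 0)
  data.frame(
    scenario_id = scenario_id,
    method = method_label,
    mean_mb = mean(d$mb),
    mean_rbias = mean(rbias),
    sd_rbias = stats::sd(rbias),
    rmse = sqrt(mean((d$estimate - truth)^2)),
    mean_se = mean(d$robust_se),
    coverage = 100 * mean(covers),
    coverageT = 100 * mean(coversT),
    significance = 100 * mean(d$p_value < 0.05),
    mean_n_used = mean(d$n_used),
    mce_rbias = if (nrow(d) > 1L) monte_carlo_error(rbias) else NA_real_,
    mce_mb = if (nrow(d) > 1L) monte_carlo_error(d$mb) else NA_real_,
    n_replicates_used = nrow(d),
    n_replicates_total = length(unique(df$replicate)),
    flagged_excluded = exclude_flagged,
    stringsAsFactors = FALSE)
}

#' Summarize every method in a scenario's record set
#'
#' @param records Output of \code{\link{run_scenario}} (attributes
#'   \code{scenario} and \code{truth} are used when present).
#' @param truth Optional truth override.
#' @param exclude_flagged Passed to \code{\link{summarize_criteria}}.
#' @return A \code{data.frame}, one row per method.
#' @export
summarize_scenario <- function(records, truth = NULL,
                               exclude_flagged = FALSE) {
  truth <- truth %||% attr(records, "truth")
  scenario <- attr(records, "scenario")
  sid <- if (!is.null(scenario)) scenario$scenario_id else NA_character_
  methods <- unique(vapply(records, `[[`, "", "method_label"))
  do.call(rbind, lapply(methods, function(m) {
    recs <- records[vapply(records, function(r)
      identical(r$method_label, m), logical(1))]
    summarize_criteria(recs, truth, exclude_flagged,
                       scenario_id = sid, method_label = m)
  }))
}

#' The default scenario grid
#'
#' Homogeneous and sex-moderated heterogeneous effects crossed with
#' outcome risks 1\%/10\%/30\% at observed or 2.5\% exposure, and
#' exposure prevalences 2.5\%/10\%/30\% at observed or 1\% outcome
#' risk; duplicates removed.  The heterogeneous 1\%-outcome x
#' 2.5\%-exposure cell ships disabled (rare event x rare exposure:
#' separation-dominated).  Defaults: 500 replicates of n = 4000, true
#' effect coefficient 1.
#'
#' @param n_replicates,n_per_replicate,master_seed Passed through to
#'   every \code{\link{scenario_config}}.
#' @return A \code{data.frame} describing the grid, with an
#'   \code{enabled} flag and list-column \code{config}.
#' @export
default_scenario_grid <- function(n_replicates = 500L,
                                  n_per_replicate = 4000L,
                                  master_seed = 1L) {
  cells <- list()
  for (eff in c("homogeneous", "heterogeneous_binary")) {
    for (prev in list("observed", 0.025)) {
      for (risk in list(0.01, 0.10, 0.30)) {
        cells[[length(cells) + 1L]] <- list(risk = risk, prev = prev,
                                            effect = eff)
      }
    }
    for (risk in list("observed", 0.01)) {
      for (prev in list(0.025, 0.10, 0.30)) {
        cells[[length(cells) + 1L]] <- list(risk = risk, prev = prev,
                                            effect = eff)
      }
    }
  }
  key <- vapply(cells, function(c)
    default_scenario_id(c$risk, c$prev, c$effect), "")
  cells <- cells[!duplicated(key)]
  rows <- lapply(seq_along(cells), function(i) {
    c0 <- cells[[i]]
    cfg <- scenario_config(outcome_risk = c0$risk,
                           exposure_prevalence = c0$prev,
                           effect_type = c0$effect,
                           n_per_replicate = n_per_replicate,
                           n_replicates = n_replicates,
                           master_seed = child_seed(master_seed, i))
    enabled <- !(identical(c0$effect, "heterogeneous_binary") &&
                   identical(c0$risk, 0.01) && identical(c0$prev, 0.025))
    data.frame(scenario_id = cfg$scenario_id,
               effect_type = c0$effect,
               outcome_risk = if (identical(c0$risk, "observed"))
                 "observed" else format(c0$risk),
               exposure_prevalence = if (identical(c0$prev, "observed"))
                 "observed" else format(c0$prev),
               enabled = enabled,
               stringsAsFactors = FALSE) -> row
    row$config <- list(cfg)
    row
  })
  do.call(rbind, rows)
}
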