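# Effect estimation: weighted GLM of outcome on exposure alone with a
# log link (log relative risk), cluster-robust sandwich standard errors
# with plasmode duplicates of one base subject sharing a cluster, and
# separation / nonconvergence flagging.  After balancing, no covariate
# adjustment is performed: a weighted difference in (log) means on the
# balanced data estimates the causal effect.

#' Cluster-robust sandwich variance for a fitted GLM
#'
#' \eqn{(X'WX)^{-1} (\sum_c s_c s_c') (X'WX)^{-1}} with per-cluster
#' score sums \eqn{s_c}; no small-sample correction (clusters are
#' numerous in the plasmode design).  Weights are treated as probability
#' weights.
#'
#' @param fit A \code{glm} (or \code{glm.fit}-shaped) object.
#' @param cluster Cluster identifier, one per observation.
#' @param X Model matrix (defaults to \code{model.matrix(fit)}).
#' @return The robust covariance matrix of the coefficients.
#' @export
cluster_robust_vcov <- function(fit, cluster, X = stats::model.matrix(fit)) {
  W <- fit$weights            # working weights: w * (dmu/deta)^2 / V(mu)
  r <- fit$residuals          # working residuals: (y - mu) / (dmu/deta)
  estfun <- X * (W * r)       # per-observation score contributions
  bread <- solve(crossprod(X * sqrt(W)))
  scores_c <- rowsum(estfun, group = cluster)
  meat <- crossprod(scores_c)
  bread %*% meat %*% bread
}

#' Estimate the exposure effect on a weighted analyzed dataset
#'
#' Fits \code{outcome ~ exposure} by a weighted GLM with log link
#' (binomial family; Poisson-family fallback on nonconvergence) on the
#' included subjects, computes the cluster-robust standard error with
#' clusters defined by \code{source_id}, and returns the estimate on
#' the log relative-risk scale with a 95\% Wald interval and two-sided
#' p-value.  Separation is flagged, not dropped.
#'
#' @param data A \code{simulated_dataset} or a cohort \code{data.frame}.
#' @param wa A \code{weight_assignment}.
#' @param balance Optional \code{balance_report} to embed in the record.
#' @param replicate_index Replicate bookkeeping.
#' @return An object of class \code{estimate_record}: list with
#'   \code{method_label}, \code{replicate_index}, \code{estimate},
#'   \code{robust_se}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{n_used}, \code{converged}, \code{separation_flag},
#'   \code{fallback_family}, \code{balance}.
#' @export
estimate_effect <- function(data, wa, balance = NULL,
                            replicate_index = NA_integer_) {
  cohort <- if (inherits(data, "simulated_dataset")) data$cohort else data
  if (is.na(replicate_index) && inherits(data, "simulated_dataset")) {
    replicate_index <- data$replicate_index
  }
  inc <- wa$included
  d <- cohort[inc, , drop = FALSE]
  w <- wa$weights[inc]
  y <- d$outcome
  z <- d$exposure
  if (length(unique(z)) < 2L) {
    stop("estimation requires both exposure groups among included subjects",
         call. = FALSE)
  }
  if (sum(y) == 0) {
    stop("estimation requires at least one event among included subjects",
         call. = FALSE)
  }
  cl <- if (!is.null(d$source_id)) d$source_id else seq_along(y)

  est <- NA_real_; se <- NA_real_; converged <- FALSE
  fallback <- NA_character_
  # no finite MLE when either arm has zero weighted events
  ev1 <- sum(w[z == 1] * y[z == 1])
  ev0 <- sum(w[z == 0] * y[z == 0])
  if (ev1 > 0 && ev0 > 0) {
    X <- cbind(`(Intercept)` = 1, exposure = z)
    p_start <- min(max(sum(w * y) / sum(w), 1e-8), 1 - 1e-8)
    fit <- tryCatch(
      suppressWarnings(
        stats::glm.fit(X, y, weights = w,
                       family = stats::quasibinomial(link = "log"),
                       start = c(log(p_start), 0),
                       control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        !all(is.finite(fit$coefficients))) {
      # log-binomial can fail near the boundary; Poisson log-link with
      # robust SE is the standard fallback for relative risks
      fit <- tryCatch(
        suppressWarnings(
          stats::glm.fit(X, y, weights = w,
                         family = stats::quasipoisson(link = "log"),
                         control = stats::glm.control(maxit = 100))),
        error = function(e) NULL)
      if (!is.null(fit)) fallback <- "poisson"
    }
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      est <- unname(fit$coefficients["exposure"])
      V <- tryCatch(cluster_robust_vcov(fit, cl, X = X),
                    error = function(e) NULL)
      se <- if (is.null(V)) NA_real_ else sqrt(V["exposure", "exposure"])
      converged <- isTRUE(fit$converged)
    }
  }
  zcrit <- stats::qnorm(0.975)
  rec <- structure(list(method_label = wa$method_label,
                        replicate_index = replicate_index,
                        estimate = est,
                        robust_se = se,
                        ci_low = est - zcrit * se,
                        ci_high = est + zcrit * se,
                        p_value = if (is.finite(est) && is.finite(se) && se > 0)
                          2 * stats::pnorm(-abs(est / se)) else NA_real_,
                        n_used = wa$n_used,
                        converged = converged,
                        separation_flag = FALSE,
                        fallback_family = fallback,
                        balance = balance),
                   class = "estimate_record")
  rec$separation_flag <- detect_separation(rec, d, w)
  rec
}

#' Flag (quasi-)complete separation or unstable estimation
#'
#' TRUE when the fit failed to converge, \code{|estimate| > 10},
#' \code{robust_se > 50}, or any exposure-by-outcome margin cell among
#' the included subjects is empty.  Flagged replicates stay in primary
#' summaries; sensitivity summaries exclude them.
#'
#' @param record An \code{estimate_record}.
#' @param data Included-subject data (cohort rows) used for the margin
#'   check; a full cohort plus a \code{weight_assignment} also works.
#' @param wa Included-subject weights, or a \code{weight_assignment}.
#' @return Logical flag.
#' @export
detect_separation <- function(record, data, wa = NULL) {
  if (inherits(wa, "weight_assignment")) {
    data <- data[wa$included, , drop = FALSE]
  }
  margin_empty <- any(table(factor(data$exposure, levels = 0:1),
                            factor(data$outcome, levels = 0:1)) == 0)
  isTRUE(!record$converged ||
           is.na(record$estimate) ||
           abs(record$estimate) > 10 ||
           (is.finite(record$robust_se) && record$robust_se > 50) ||
           margin_empty)
}

#' @export
print.estimate_record <- function(x, ...) {
  cat("Estimate [", x$method_label, "]: ", format(x$estimate, digits = 4),
      " (robust SE ", format(x$robust_se, digits = 4), ")\n", sep = "")
  cat("  95% CI [", format(x$ci_low, digits = 4), ", ",
      format(x$ci_high, digits = 4), "], p = ",
      format(x$p_value, digits = 3), ", n used = ", x$n_used, "\n", sep = "")
  if (x$separation_flag) cat("  separation flagged\n")
  invisible(x)
}
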