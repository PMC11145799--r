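# Propensity-score estimation: maximum-likelihood logistic regression of
# exposure on all covariates (main effects only).  One indicator is
# dropped from each exhaustive block (race; the blind-disabled/adult
# eligibility pair) to keep the design full rank; the fitted score space
# is unchanged by the choice of reference level.

#' Fit a logistic propensity-score model
#'
#' @param cohort Cohort \code{data.frame} with an \code{exposure} column.
#' @param covariate_names Covariates to enter as main effects (default:
#'   all covariates recorded in the cohort metadata).
#' @param epsilon Convergence tolerance passed to
#'   \code{\link[stats]{glm.control}}; the tight default makes the score
#'   equations (and hence overlap-weight exact balance) hold to high
#'   precision.
#' @param maxit Iteration cap.
#' @return An object of class \code{ps_fit}: list with
#'   \code{coefficients} (named, including \code{(Intercept)}),
#'   \code{scores} (per-subject probabilities, clipped to
#'   \code{[1e-12, 1-1e-12]}, aligned with cohort rows and named by
#'   \code{subject_id}), \code{converged}, \code{n_iterations},
#'   \code{separation} (TRUE when fitted probabilities hit 0/1 or a
#'   coefficient diverged), and \code{design_columns}.
#' @export
fit_propensity <- function(cohort, covariate_names = NULL,
                           epsilon = 1e-12, maxit = 100L) {
  meta <- cohort_meta(cohort)
  covariate_names <- covariate_names %||% meta$covariate_names
  z <- cohort$exposure
  if (length(unique(z)) < 2L) {
    stop("cannot fit a propensity model: only one exposure group present",
         call. = FALSE)
  }
  drop_refs <- c(
    if (all(meta$race_block %in% covariate_names)) meta$race_block[1L],
    if (all(meta$elig_pair %in% covariate_names)) meta$elig_pair[2L]
  )
  keep <- setdiff(covariate_names, drop_refs)
  X <- cbind(`(Intercept)` = 1, as.matrix(cohort[, keep, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("propensity design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, z, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(fit$coefficients) > 15)) separation <- TRUE
  scores <- clip01(fit$fitted.values)
  names(scores) <- cohort$subject_id
  structure(list(coefficients = fit$coefficients,
                 scores = scores,
                 converged = fit$converged && !separation,
                 n_iterations = fit$iter,
                 separation = separation,
                 design_columns = colnames(X)),
            class = "ps_fit")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat("Propensity-score fit:", length(x$scores), "subjects,",
      length(x$coefficients), "coefficients\n")
  cat("  converged:", x$converged,
      " separation:", x$separation,
      " iterations:", x$n_iterations, "\n")
  cat("  score range: [", format(min(x$scores), digits = 4), ", ",
      format(max(x$scores), digits = 4), "]\n", sep = "")
  invisible(x)
}
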