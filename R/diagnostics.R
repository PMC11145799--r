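# Covariate-balance diagnostics: per-covariate standardized mean
# differences (reported x100) and the Mahalanobis balance distance
# between weighted group mean vectors.  Denominators (pooled SD, the
# covariance matrix) are UNWEIGHTED over the included sample, so
# weighting moves only the mean differences and crude/weighted values
# share one scale.

#' Weighted standardized mean difference for one covariate
#'
#' \code{100 * (weighted exposed mean - weighted unexposed mean) /
#' pooled unweighted SD} over the included sample, with the pooled SD
#' \code{sqrt((var_exposed + var_unexposed) / 2)}.  Sign convention:
#' exposed minus unexposed.
#'
#' @param cohort Cohort \code{data.frame}.
#' @param wa A \code{weight_assignment}.
#' @param covariate Covariate name.
#' @return A single numeric (SMD x100).
#' @export
weighted_smd <- function(cohort, wa, covariate) {
  inc <- wa$included
  x <- cohort[[covariate]][inc]
  z <- cohort$exposure[inc]
  w <- wa$weights[inc]
  if (sum(w[z == 1]) <= 0 || sum(w[z == 0]) <= 0) {
    stop("both groups need positive total weight among included subjects",
         call. = FALSE)
  }
  sdp <- pooled_sd(x, z)
  if (sdp == 0) {
    stop("SMD undefined: covariate '", covariate,
         "' is constant within groups on the included sample",
         call. = FALSE)
  }
  m1 <- stats::weighted.mean(x[z == 1], w[z == 1])
  m0 <- stats::weighted.mean(x[z == 0], w[z == 0])
  100 * (m1 - m0) / sdp
}

# columns entering the Mahalanobis quadratic form: one reference level
# dropped per exhaustive block so the covariance matrix stays invertible
#' @noRd
mb_columns <- function(meta) {
  drop_refs <- c(
    if (length(meta$race_block)) meta$race_block[1L],
    if (length(meta$elig_pair)) meta$elig_pair[2L]
  )
  setdiff(meta$covariate_names, drop_refs)
}

#' Mahalanobis balance distance
#'
#' \eqn{d' S^{-1} d} where \eqn{d} is the vector of weighted group mean
#' differences over the retained covariate columns (exhaustive indicator
#' blocks contribute their levels minus one) and \eqn{S} the unweighted
#' sample covariance matrix of those columns over the included sample.
#' Zero iff the weighted group mean vectors coincide.
#'
#' @param cohort Cohort \code{data.frame}.
#' @param wa A \code{weight_assignment}.
#' @return A single nonnegative numeric.
#' @export
mahalanobis_balance <- function(cohort, wa) {
  meta <- cohort_meta(cohort)
  cols <- mb_columns(meta)
  inc <- wa$included
  X <- as.matrix(cohort[inc, cols, drop = FALSE])
  z <- cohort$exposure[inc]
  w <- wa$weights[inc]
  if (sum(w[z == 1]) <= 0 || sum(w[z == 0]) <= 0) {
    stop("both groups need positive total weight among included subjects",
         call. = FALSE)
  }
  m1 <- colSums(X[z == 1, , drop = FALSE] * w[z == 1]) / sum(w[z == 1])
  m0 <- colSums(X[z == 0, , drop = FALSE] * w[z == 0]) / sum(w[z == 0])
  d <- m1 - m0
  S <- stats::cov(X)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("covariance matrix numerically singular; ",
            "using pseudo-inverse for the Mahalanobis balance",
            call. = FALSE)
    pseudo_inverse(S)
  })
  max(0, drop(d %*% Sinv %*% d))
}

#' Full balance report for one weight assignment
#'
#' @param cohort Cohort \code{data.frame}.
#' @param wa A \code{weight_assignment}.
#' @return An object of class \code{balance_report}: list with
#'   \code{smd_by_covariate} (named, x100 scale), \code{mb},
#'   \code{n_used}, \code{method_label}.
#' @export
balance_report <- function(cohort, wa) {
  meta <- cohort_meta(cohort)
  smd <- vapply(meta$covariate_names,
                function(nm) weighted_smd(cohort, wa, nm), numeric(1))
  structure(list(smd_by_covariate = smd,
                 mb = mahalanobis_balance(cohort, wa),
                 n_used = wa$n_used,
                 method_label = wa$method_label),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report [", x$method_label, "]\n", sep = "")
  cat("  max |SMD| (x100):",
      format(max(abs(x$smd_by_covariate)), digits = 4), "\n")
  cat("  MB:", format(x$mb, digits = 4), "  N used:", x$n_used, "\n")
  invisible(x)
}

#' Assemble balance reports into a Table-1-shaped data frame
#'
#' Covariate rows with one SMD column per method, plus \code{MB} and
#' \code{N_used} footer rows.
#'
#' @param reports A named list of \code{balance_report} objects (names
#'   become columns; falls back to each report's method label).
#' @return A \code{data.frame}.
#' @export
balance_table <- function(reports) {
  stopifnot(length(reports) > 0L)
  labels <- names(reports) %||% vapply(reports, `[[`, "", "method_label")
  if (is.null(names(reports))) names(reports) <- labels
  covs <- names(reports[[1L]]$smd_by_covariate)
  out <- data.frame(covariate = c(covs, "MB", "N_used"),
                    stringsAsFactors = FALSE)
  for (lab in names(reports)) {
    r <- reports[[lab]]
    out[[lab]] <- c(round(r$smd_by_covariate[covs], 4), round(r$mb, 6),
                    r$n_used)
  }
  out
}
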