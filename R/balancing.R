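# Balancing methods: crude (no weighting), overlap weighting, and
# propensity-score fine stratification with the two published ATE weight
# schemes, plus the cross-classification pruning that defines the
# reduced ("X") dataset.

#' @noRd
new_weight_assignment <- function(method_label, weights, included,
                                  stratum_id = NULL) {
  structure(list(method_label = method_label,
                 weights = weights,
                 included = included,
                 n_used = sum(included),
                 stratum_id = stratum_id),
            class = "weight_assignment")
}

#' @export
print.weight_assignment <- function(x, ...) {
  cat("Weight assignment [", x$method_label, "]: ", x$n_used, " of ",
      length(x$weights), " subjects included\n", sep = "")
  invisible(x)
}

#' Crude (unweighted) assignment
#'
#' All weights 1, nobody excluded: the raw-data reference method.
#'
#' @param cohort Cohort \code{data.frame}.
#' @param method_label Label stored on the assignment.
#' @return A \code{weight_assignment}.
#' @export
crude_weights <- function(cohort, method_label = "crude") {
  n <- nrow(cohort)
  new_weight_assignment(method_label, rep(1, n), rep(TRUE, n))
}

#' Overlap weights
#'
#' Exposed subjects receive \code{1 - PS}, unexposed subjects receive
#' \code{PS}; no subject is pruned.  With a converged maximum-likelihood
#' logistic propensity model these weights balance every covariate mean
#' exactly, and the two groups' total weights are identical.
#'
#' @param fit A converged \code{\link{fit_propensity}} result.
#' @param cohort The cohort the fit was computed on.
#' @param method_label Label stored on the assignment.
#' @return A \code{weight_assignment} with weights in (0, 1).
#' @export
overlap_weights <- function(fit, cohort, method_label = "OW") {
  if (!fit$converged) {
    warning("overlap weights computed from a non-converged propensity fit",
            call. = FALSE)
  }
  z <- cohort$exposure
  w <- ifelse(z == 1, 1 - fit$scores, fit$scores)
  new_weight_assignment(method_label, unname(w), rep(TRUE, nrow(cohort)))
}

#' Fine stratification of the propensity score
#'
#' Stratum boundaries are equal-frequency quantiles of the EXPOSED
#' subjects' scores (default 20 strata).  Unexposed subjects with scores
#' strictly outside the exposed score range are excluded as
#' non-overlap; strata left without at least one subject from each
#' group are dropped and their members excluded.  Subjects exactly at an
#' internal boundary go to the lower stratum (right-closed intervals).
#'
#' @param fit A \code{\link{fit_propensity}} result.
#' @param cohort The cohort the fit was computed on.
#' @param k_strata Number of strata (default 20).
#' @return An object of class \code{stratification}: list with
#'   \code{boundaries}, \code{stratum_id} (per subject, \code{NA} =
#'   excluded), per-stratum counts \code{n_total}, \code{n_exposed},
#'   \code{n_unexposed}, \code{retained}, and
#'   \code{excluded_nonoverlap}.
#' @export
fine_stratify <- function(fit, cohort, k_strata = 20L) {
  z <- cohort$exposure
  ps <- fit$scores
  ps_exp <- ps[z == 1]
  if (length(ps_exp) < k_strata) {
    stop("fewer exposed subjects (", length(ps_exp), ") than strata (",
         k_strata, "); reduce k_strata", call. = FALSE)
  }
  boundaries <- unname(stats::quantile(ps_exp,
                                       probs = seq(0, 1, length.out = k_strata + 1)))
  boundaries <- unique(boundaries)  # ties collapse strata
  nonoverlap <- z == 0 & (ps < boundaries[1] | ps > boundaries[length(boundaries)])
  stratum <- cut(ps, breaks = boundaries, labels = FALSE,
                 include.lowest = TRUE, right = TRUE)
  k <- length(boundaries) - 1L
  n_exposed <- tabulate(stratum[z == 1 & !is.na(stratum)], nbins = k)
  n_unexposed <- tabulate(stratum[z == 0 & !is.na(stratum)], nbins = k)
  retained <- n_exposed >= 1L & n_unexposed >= 1L
  stratum[!is.na(stratum) & !retained[stratum]] <- NA_integer_
  structure(list(boundaries = boundaries,
                 stratum_id = stratum,
                 n_total = n_exposed + n_unexposed,
                 n_exposed = n_exposed,
                 n_unexposed = n_unexposed,
                 retained = retained,
                 excluded_nonoverlap = sum(nonoverlap)),
            class = "stratification")
}

#' Fine-stratification ATE weights
#'
#' For retained stratum \eqn{i} with \eqn{N_i} subjects (\eqn{N_{1i}}
#' exposed, \eqn{N_{0i}} unexposed):
#' \itemize{
#'   \item \code{equ} (equal group totals): exposed weight
#'     \eqn{N_i / N_{1i}}, unexposed weight \eqn{N_i / N_{0i}}; each
#'     group's weights total the retained sample size.
#'   \item \code{unequ} (group totals equal to group sizes): exposed
#'     weight \eqn{(N_i/N)/(N_{1i}/N_1)}, unexposed weight
#'     \eqn{(N_i/N)/(N_{0i}/N_0)}, with \eqn{N}, \eqn{N_1}, \eqn{N_0}
#'     totals over the retained strata.
#' }
#' Excluded subjects carry weight 0.
#'
#' @param strat A \code{\link{fine_stratify}} result.
#' @param cohort The cohort that was stratified.
#' @param scheme \code{"equ"} or \code{"unequ"}.
#' @param method_label Label stored on the assignment.
#' @return A \code{weight_assignment} with per-subject
#'   \code{stratum_id}.
#' @export
fs_weights <- function(strat, cohort, scheme = c("equ", "unequ"),
                       method_label = NULL) {
  scheme <- match.arg(scheme)
  if (!any(strat$retained)) {
    stop("no retained strata; cannot compute fine-stratification weights",
         call. = FALSE)
  }
  method_label <- method_label %||% paste0("FS_", scheme)
  z <- cohort$exposure
  sid <- strat$stratum_id
  included <- !is.na(sid)
  Ni <- strat$n_total
  N1i <- strat$n_exposed
  N0i <- strat$n_unexposed
  w <- numeric(nrow(cohort))
  if (scheme == "equ") {
    w_exp <- Ni / N1i
    w_unexp <- Ni / N0i
  } else {
    N <- sum(Ni[strat$retained])
    N1 <- sum(N1i[strat$retained])
    N0 <- sum(N0i[strat$retained])
    w_exp <- (Ni / N) / (N1i / N1)
    w_unexp <- (Ni / N) / (N0i / N0)
  }
  w[included] <- ifelse(z[included] == 1, w_exp[sid[included]],
                        w_unexp[sid[included]])
  new_weight_assignment(method_label, w, included, stratum_id = sid)
}

#' Remove subjects unmatched on the binary-covariate cross-classification
#'
#' Forms the cell key from all listed binary covariates and removes
#' every subject whose cell is occupied by only one exposure group; the
#' result is the reduced ("X") dataset.  The operation is idempotent.
#'
#' @param cohort Cohort \code{data.frame}.
#' @param binary_names Binary covariates defining the cells (default:
#'   all 12 from the cohort metadata).
#' @return The reduced cohort, with attribute \code{"n_removed"}.
#' @export
prune_unmatched <- function(cohort, binary_names = NULL) {
  meta <- cohort_meta(cohort)
  binary_names <- binary_names %||% meta$binary_names
  for (nm in binary_names) {
    if (!nm %in% names(cohort)) {
      stop("binary covariate '", nm, "' not found", call. = FALSE)
    }
    assert_binary01(cohort[[nm]], nm)
  }
  key <- do.call(paste, c(cohort[binary_names], sep = "\r"))
  z <- cohort$exposure
  has_exp <- unique(key[z == 1])
  has_unexp <- unique(key[z == 0])
  matched <- key %in% intersect(has_exp, has_unexp)
  if (!any(matched)) {
    stop("pruning removed every subject: no cross-classification cell ",
         "contains both exposure groups", call. = FALSE)
  }
  out <- cohort_subset(cohort, matched)
  attr(out, "n_removed") <- sum(!matched)
  out
}
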