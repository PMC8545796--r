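## Multiple-testing correction, sex-difference testing, and the scale
## conversions used for reporting and for auditing printed results.

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validating wrapper over \code{stats::p.adjust(method = "BH")}: step-up
#' adjustment adj_i = min over j >= i of (m p_(j) / j), capped at 1 and
#' returned in input order.
#'
#' @param pvalues numeric vector in (0, 1].
#' @param labels optional test identifiers used to name the result.
#' @return adjusted p-values in input order.
#' @export
bhFDR <- function(pvalues, labels = names(pvalues)) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(labels)) names(adj) <- labels
  adj
}

#' Test for a sex (stratum) difference between two MR estimates
#'
#' z = (b1 - b2) / sqrt(SE1^2 + SE2^2) with a two-tailed normal p; both
#' estimates must be on the log-OR scale.
#'
#' @param est_a,est_b \code{MREstimate}s for the two strata.
#' @return list with \code{z} and \code{pvalue}.
#' @export
sexDifferenceTest <- function(est_a, est_b) {
  s1 <- causalSE(est_a); s2 <- causalSE(est_b)
  if (is.na(s1) || is.na(s2) || s1 <= 0 || s2 <= 0)
    stopf("both estimates need positive standard errors")
  z <- (causalEstimate(est_a) - causalEstimate(est_b)) / sqrt(s1^2 + s2^2)
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Odds ratio and 95\% CI from a log-OR estimate
#'
#' @param beta log-OR estimate.
#' @param se its standard error.
#' @return named numeric: \code{or}, \code{ci_low}, \code{ci_high}.
#' @export
orCiFromBeta <- function(beta, se) {
  c(or = exp(beta), ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se))
}

#' P-value recovered from a printed OR and 95\% CI
#'
#' Inverts the reporting convention: b = ln(OR),
#' SE = (ln hi - ln lo) / (2 * 1.96), p = 2 (1 - Phi(|b| / SE)). Used to
#' audit printed results.
#'
#' @param or odds ratio.
#' @param ci_low,ci_high 95\% confidence bounds, 0 < ci_low <= or <= ci_high.
#' @return the two-sided p-value.
#' @export
pFromOrCi <- function(or, ci_low, ci_high) {
  if (any(ci_low >= ci_high)) stopf("ci_low must be below ci_high")
  if (any(ci_low <= 0) || any(or < ci_low) || any(or > ci_high))
    stopf("need 0 < ci_low <= or <= ci_high")
  b <- log(or)
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  2 * stats::pnorm(-abs(b / se))
}

#' Build an MREstimate from a printed OR and 95\% CI
#'
#' Convenience for reconstruction work: recovers the log-OR and its SE from
#' printed values.
#'
#' @inheritParams pFromOrCi
#' @param method method tag for the resulting estimate, default "IVW_CORR".
#' @param k number of variants backing the printed estimate (bookkeeping).
#' @return an \code{\link{MREstimate}}.
#' @export
estimateFromOrCi <- function(or, ci_low, ci_high, method = "IVW_CORR", k = 0L) {
  if (ci_low >= ci_high) stopf("ci_low must be below ci_high")
  b <- log(or)
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  newMREstimate(method, b, se, k)
}
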