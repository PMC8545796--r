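## Canonical summary-statistic columns. A summary-statistic table is a plain
## data.frame with these columns; n_cases is optional (case-control outcomes).
.SUMSTAT_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

.DROP_REASONS <- c("MISSING_IN_OUTCOME", "PALINDROMIC_AMBIGUOUS",
                   "ALLELE_MISMATCH", "PROXY_SUBSTITUTED")

#' LDMatrix: signed pairwise correlations among instrument variants
#'
#' Square symmetric matrix of pairwise correlations (rho, not r-squared),
#' signed with respect to each variant's effect allele after harmonization.
#'
#' @slot variantIds character vector naming rows/columns, in order.
#' @slot rho numeric matrix of correlations in [-1, 1], unit diagonal.
#' @exportClass LDMatrix
setClass("LDMatrix",
         representation(variantIds = "character", rho = "matrix"))

setValidity("LDMatrix", function(object) {
  r <- object@rho
  ids <- object@variantIds
  msg <- character()
  if (nrow(r) != ncol(r)) msg <- c(msg, "rho must be square")
  if (length(ids) != nrow(r)) msg <- c(msg, "variantIds length must match rho")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate variant ids")
  if (nrow(r) > 0) {
    if (max(abs(r - t(r))) > 1e-12) msg <- c(msg, "rho must be symmetric within 1e-12")
    if (max(abs(diag(r) - 1)) > 1e-12) msg <- c(msg, "rho diagonal must be 1")
    if (any(abs(r) > 1 + 1e-12)) msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: aligned exposure/outcome association vectors
#'
#' Exposure and outcome effects for a shared, allele-aligned set of variants,
#' together with a drop log recording every variant that was excluded (and
#' any proxy substitutions) during harmonization.
#'
#' @slot variantIds character, retained variant ids in order.
#' @slot bx,sx numeric, exposure betas and SEs (SD units of the exposure).
#' @slot by,sy numeric, outcome betas and SEs (log-odds for case-control).
#' @slot dropLog data.frame with columns variant_id, reason.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
         representation(variantIds = "character",
                        bx = "numeric", sx = "numeric",
                        by = "numeric", sy = "numeric",
                        dropLog = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  k <- length(object@variantIds)
  msg <- character()
  if (!all(lengths(list(object@bx, object@sx, object@by, object@sy)) == k))
    msg <- c(msg, "bx, sx, by, sy must match variantIds in length")
  if (anyDuplicated(object@variantIds)) msg <- c(msg, "duplicate variant ids")
  if (k && (any(object@sx < 0) || any(object@sy <= 0)))
    msg <- c(msg, "outcome SEs must be positive and exposure SEs non-negative")
  dl <- object@dropLog
  if (!all(c("variant_id", "reason") %in% names(dl)))
    msg <- c(msg, "dropLog needs variant_id and reason columns")
  else if (nrow(dl) && !all(dl$reason %in% .DROP_REASONS))
    msg <- c(msg, "unknown drop reason code")
  if (length(msg)) msg else TRUE
})

#' MREstimate: a causal-effect estimate from one MR method
#'
#' Effects are kept on the log-OR-per-SD scale; exponentiation to an odds
#' ratio happens only at reporting (see \code{\link{orCiFromBeta}}).
#'
#' @slot method one of WALD, IVW_FE, IVW_MRE, IVW_CORR, EGGER, EGGER_SIMEX,
#'   WMEDIAN, WMODE, MVMR.
#' @slot beta,se numeric estimate and standard error.
#' @slot ciLow,ciHigh 95\% confidence bounds (beta +/- 1.96 se).
#' @slot pvalue two-sided p.
#' @slot kUsed number of variants contributing.
#' @slot intercept,interceptSE,interceptP Egger intercept fields (NA for
#'   non-Egger methods).
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", beta = "numeric", se = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        pvalue = "numeric", kUsed = "integer",
                        intercept = "numeric", interceptSE = "numeric",
                        interceptP = "numeric"))

setValidity("MREstimate", function(object) {
  ok_methods <- c("WALD", "IVW_FE", "IVW_MRE", "IVW_CORR", "EGGER",
                  "EGGER_SIMEX", "WMEDIAN", "WMODE", "MVMR")
  msg <- character()
  if (!object@method %in% ok_methods)
    msg <- c(msg, sprintf("unknown method '%s'", object@method))
  if (!is.na(object@se) && object@se < 0) msg <- c(msg, "se must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GeneRegion: a gene interval plus cis flank
#'
#' 1-based inclusive GRCh37 coordinates; the instrument window is
#' [start - flank, end + flank].
#'
#' @slot gene gene symbol.
#' @slot chromosome chromosome label.
#' @slot start,end numeric base-pair bounds, start <= end.
#' @slot flank numeric flank in bp (default 100 kb).
#' @exportClass GeneRegion
setClass("GeneRegion",
         representation(gene = "character", chromosome = "character",
                        start = "numeric", end = "numeric", flank = "numeric"))

setValidity("GeneRegion", function(object) {
  msg <- character()
  if (object@start > object@end) msg <- c(msg, "start must be <= end")
  if (object@flank < 0) msg <- c(msg, "flank must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Instrument: a selected variant set proxying one exposure
#'
#' @slot name instrument label (target gene or lipid trait).
#' @slot variants data.frame of exposure-scale summary statistics.
#' @slot ld an \code{LDMatrix} over the variants, or NULL when unknown.
#' @slot selection list recording p/r2/distance thresholds and whether the
#'   relaxed r-squared threshold was needed.
#' @exportClass Instrument
setClass("Instrument",
         representation(name = "character", variants = "data.frame",
                        ld = "ANY", selection = "list"))

setValidity("Instrument", function(object) {
  msg <- character()
  if (!is.null(object@ld) && !is(object@ld, "LDMatrix"))
    msg <- c(msg, "ld must be an LDMatrix or NULL")
  if (!"variant_id" %in% names(object@variants))
    msg <- c(msg, "variants must carry a variant_id column")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: knobs of the synthetic two-sample GWAS generator
#'
#' @slot k number of variants.
#' @slot nExposure,nOutcome sample sizes of the two studies.
#' @slot caseFraction case fraction K of the binary outcome.
#' @slot mafRange length-2 numeric in (0, 0.5].
#' @slot theta true causal effect (log-OR per SD of exposure).
#' @slot pleiotropyMean,pleiotropySD distribution of per-variant direct effects.
#' @slot invalidFraction share of variants carrying pleiotropy.
#' @slot ldRho AR(1) correlation parameter in [0, 1).
#' @slot palindromicFraction share of variants given A/T or G/C alleles.
#' @slot gammaSD scale of true SNP-exposure effects (SD units).
#' @slot seed integer seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(k = "integer", nExposure = "numeric",
                        nOutcome = "numeric", caseFraction = "numeric",
                        mafRange = "numeric", theta = "numeric",
                        pleiotropyMean = "numeric", pleiotropySD = "numeric",
                        invalidFraction = "numeric", ldRho = "numeric",
                        palindromicFraction = "numeric", gammaSD = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@k < 1) msg <- c(msg, "k must be >= 1")
  if (object@invalidFraction < 0 || object@invalidFraction > 1)
    msg <- c(msg, "invalidFraction must lie in [0, 1]")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must lie in [0, 1)")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be within (0, 0.5]")
  if (object@caseFraction <= 0 || object@caseFraction >= 1)
    msg <- c(msg, "caseFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
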