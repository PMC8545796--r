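## Instrument construction (cis gene-window and genome-wide clumping),
## instrument strength, and statistical power.

#' Construct a GeneRegion
#'
#' @param gene gene symbol.
#' @param chromosome chromosome label.
#' @param start,end 1-based inclusive GRCh37 bounds.
#' @param flank cis flank in bp (default 100 kb).
#' @return a \code{GeneRegion}.
#' @export
geneRegion <- function(gene, chromosome, start, end, flank = 1e5) {
  new("GeneRegion", gene = as.character(gene),
      chromosome = as.character(chromosome),
      start = as.numeric(start), end = as.numeric(end),
      flank = as.numeric(flank))
}

## Pairwise r^2 between two variants from a signed LD matrix; NA when either
## variant is absent (LD unknown).
.pairR2 <- function(ld, a, b) {
  if (is.null(ld)) return(NA_real_)
  ia <- match(a, ld@variantIds); ib <- match(b, ld@variantIds)
  if (is.na(ia) || is.na(ib)) return(NA_real_)
  ld@rho[ia, ib]^2
}

## Greedy p-value-ranked clumping. `rule` decides how the r^2 and distance
## conditions combine into a discard decision:
##   "and": discard only if correlated beyond threshold AND within distance
##   "or" : discard if either condition binds (cross-chromosome never clumps)
## Ties in p broken by ascending position then lexical variant id.
.greedyClump <- function(cand, ld, r2_threshold, distance_bp, rule) {
  ord <- order(cand$pvalue, cand$position, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  retained <- integer()
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    retained <- c(retained, i)
    if (i == nrow(cand)) break
    for (j in seq.int(i + 1L, nrow(cand))) {
      if (!alive[j]) next
      same_chr <- identical(cand$chromosome[i], cand$chromosome[j])
      near <- same_chr && abs(cand$position[i] - cand$position[j]) <= distance_bp
      r2 <- .pairR2(ld, cand$variant_id[i], cand$variant_id[j])
      correlated <- !is.na(r2) && r2 > r2_threshold
      discard <- if (rule == "and") near && correlated else near || correlated
      if (discard) alive[j] <- FALSE
    }
  }
  cand[retained, , drop = FALSE]
}

#' Select a cis (gene-window) drug-target instrument
#'
#' Candidates are variants inside \code{[start - flank, end + flank]} with
#' p below \code{p_threshold}, thinned by greedy p-value-ranked clumping: the
#' most significant candidate is retained and remaining candidates are
#' discarded when both correlated (pairwise r-squared above the threshold)
#' with and within \code{distance_bp} of a retained variant. When fewer than
#' \code{min_snps} survive, clumping is re-run at the relaxed r-squared
#' threshold and the instrument is flagged accordingly.
#'
#' @param sumstats exposure summary statistics (canonical layout with
#'   position and pvalue).
#' @param region a \code{\link{geneRegion}}.
#' @param ld an \code{LDMatrix} covering the candidates (pairs absent from it
#'   are treated as uncorrelated).
#' @param p_threshold genome-wide significance threshold, default 5e-8.
#' @param r2_primary primary clumping r-squared threshold, default 0.2.
#' @param distance_bp clumping distance, default 250 kb.
#' @param min_snps minimum instrument size before relaxation, default 3.
#' @param r2_relaxed relaxed r-squared threshold, default 0.40.
#' @return an \code{\link{Instrument}}.
#' @export
selectGeneWindow <- function(sumstats, region, ld = NULL,
                             p_threshold = 5e-8, r2_primary = 0.2,
                             distance_bp = 250000, min_snps = 3,
                             r2_relaxed = 0.40) {
  win_lo <- region@start - region@flank
  win_hi <- region@end + region@flank
  cand <- sumstats[!is.na(sumstats$position) &
                   sumstats$chromosome == region@chromosome &
                   sumstats$position >= win_lo & sumstats$position <= win_hi &
                   !is.na(sumstats$pvalue) & sumstats$pvalue < p_threshold, ,
                   drop = FALSE]
  if (nrow(cand) == 0L)
    stopf("no variant passes p < %g in region %s (chr%s:%d-%d +/- %d)",
          p_threshold, region@gene, region@chromosome,
          as.integer(region@start), as.integer(region@end),
          as.integer(region@flank))
  kept <- .greedyClump(cand, ld, r2_primary, distance_bp, rule = "and")
  relaxed <- FALSE
  if (nrow(kept) < min_snps) {
    kept <- .greedyClump(cand, ld, r2_relaxed, distance_bp, rule = "and")
    relaxed <- TRUE
  }
  rownames(kept) <- NULL
  sel <- list(p_threshold = p_threshold, r2_threshold = r2_primary,
              r2_relaxed = r2_relaxed, distance_bp = distance_bp,
              min_snps = min_snps, relaxed = relaxed, window = "gene")
  ld_out <- if (!is.null(ld) && all(kept$variant_id %in% ld@variantIds))
    alignLD(ld, kept$variant_id) else NULL
  new("Instrument", name = region@gene, variants = kept, ld = ld_out,
      selection = sel)
}

#' Select a genome-wide (molecule-specific) instrument
#'
#' As \code{\link{selectGeneWindow}} without the window restriction or the
#' relaxation step, under the independence-oriented clumping rule: a
#' candidate is discarded when it is within \code{distance_bp} of a retained
#' variant on the same chromosome or correlated with one beyond
#' \code{r2_threshold}.
#'
#' @inheritParams selectGeneWindow
#' @param name instrument label, default "genomewide".
#' @param r2_threshold clumping r-squared threshold, default 0.001.
#' @param distance_bp clumping distance, default 10 Mb.
#' @return an \code{\link{Instrument}}.
#' @export
selectGenomewide <- function(sumstats, p_threshold = 5e-8,
                             r2_threshold = 0.001, distance_bp = 1e7,
                             ld = NULL, name = "genomewide") {
  cand <- sumstats[!is.na(sumstats$pvalue) & sumstats$pvalue < p_threshold, ,
                   drop = FALSE]
  if (nrow(cand) == 0L)
    stopf("no variant passes p < %g genome-wide", p_threshold)
  kept <- .greedyClump(cand, ld, r2_threshold, distance_bp, rule = "or")
  rownames(kept) <- NULL
  sel <- list(p_threshold = p_threshold, r2_threshold = r2_threshold,
              distance_bp = distance_bp, relaxed = FALSE,
              window = "genomewide")
  ld_out <- if (!is.null(ld) && all(kept$variant_id %in% ld@variantIds))
    alignLD(ld, kept$variant_id) else NULL
  new("Instrument", name = name, variants = kept, ld = ld_out, selection = sel)
}

#' Per-variant variance explained (Shim et al. form)
#'
#' r2 = 2 beta^2 f (1 - f) / (2 beta^2 f (1 - f) + se^2 * 2 n f (1 - f)),
#' clipped to [0, 1).
#'
#' @param beta,se association estimate and standard error.
#' @param eaf effect-allele frequency; an error instructs the caller to
#'   exclude the variant from strength reporting when missing.
#' @param n exposure sample size.
#' @return the variance fraction.
#' @export
snpR2 <- function(beta, eaf, se, n) {
  if (any(is.na(eaf)))
    stopf("eaf missing: exclude this variant from strength reporting")
  if (any(se <= 0)) stopf("se must be positive")
  num <- 2 * beta^2 * eaf * (1 - eaf)
  den <- num + se^2 * 2 * n * eaf * (1 - eaf)
  pmin(pmax(num / den, 0), 1 - .Machine$double.eps)
}

#' Instrument F-statistic
#'
#' F = ((N - k - 1) / k) * (R2 / (1 - R2)).
#'
#' @param r2_total variance explained by the instrument, in [0, 1).
#' @param n exposure sample size; must exceed k + 1.
#' @param k number of variants.
#' @return the F value.
#' @export
fStatistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) stopf("r2_total must lie in [0, 1)")
  if (n <= k + 1) stopf("need n > k + 1 (n = %g, k = %g)", n, k)
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Instrument strength report
#'
#' Sums per-variant variance fractions (variants in weak LD treated as
#' independent) and evaluates the instrument F-statistic. Variants with
#' missing effect-allele frequency are excluded from both the sum and k for
#' strength reporting only.
#'
#' @param instrument an \code{\link{Instrument}}.
#' @param n exposure sample size; defaults to the maximum \code{n} column of
#'   the instrument's variants.
#' @return list with \code{r2_per_snp}, \code{r2_total}, \code{f_stat},
#'   \code{n}, \code{k}, and \code{excluded} (ids lacking EAF).
#' @export
instrumentStrength <- function(instrument, n = NULL) {
  v <- instrumentVariants(instrument)
  if (is.null(n)) {
    n <- suppressWarnings(max(v$n, na.rm = TRUE))
    if (!is.finite(n)) stopf("exposure sample size unavailable; pass n")
  }
  usable <- !is.na(v$eaf)
  if (!any(usable)) stopf("no variant with EAF; cannot report strength")
  r2 <- snpR2(v$beta[usable], v$eaf[usable], v$se[usable], n)
  r2_total <- min(sum(r2), 1 - .Machine$double.eps)
  k <- sum(usable)
  list(r2_per_snp = stats::setNames(r2, v$variant_id[usable]),
       r2_total = r2_total, f_stat = fStatistic(r2_total, n, k),
       n = n, k = k, excluded = v$variant_id[!usable])
}

#' Statistical power for a binary outcome
#'
#' Closed-form two-sided power of a two-sample MR test of a binary outcome:
#' power = Phi(|ln OR| sqrt(n r2 K (1 - K)) - z) +
#' Phi(-|ln OR| sqrt(n r2 K (1 - K)) - z), z the upper alpha/2 normal
#' quantile.
#'
#' @param n outcome sample size.
#' @param case_fraction case fraction K in (0, 1).
#' @param r2 variance in the exposure explained by the instrument.
#' @param or_alt odds ratio under the alternative.
#' @param alpha two-sided size, default 0.05.
#' @return power in [0, 1].
#' @export
powerBinary <- function(n, case_fraction, r2, or_alt, alpha = 0.05) {
  if (case_fraction <= 0 || case_fraction >= 1)
    stopf("case_fraction must lie in (0, 1)")
  if (r2 < 0 || r2 > 1) stopf("r2 must lie in [0, 1]")
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(or_alt)) * sqrt(n * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Write an instrument as TSV plus a JSON-like provenance sidecar
#'
#' @param instrument an \code{\link{Instrument}}.
#' @param path output TSV path; provenance goes to \code{<path>.selection.yaml}.
#' @export
writeInstrument <- function(instrument, path) {
  utils::write.table(instrumentVariants(instrument), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(selectionInfo(instrument),
                   paste0(path, ".selection.yaml"))
  invisible(path)
}
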