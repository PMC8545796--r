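## Bundled fixtures: the published drug-target instrument table (six LDL-C
## lowering targets, exposure GLGC LDL-C, N = 188,577) and the printed
## odds-ratio results used for reconstruction audits.

.GLGC_N <- 188577

#' Published drug-target instrument variants
#'
#' The bundled table of LDL-C-lowering variants within/near HMGCR, NPC1L1,
#' PCSK9, LDLR, CETP and APOB (exposure scale: SD of LDL-C; GLGC
#' N = 188,577). SEs are recovered from the printed 95\% CIs as
#' (upper - lower) / (2 * 1.96). The \code{rcc_available} column marks
#' variants present in the renal cell carcinoma outcome GWAS.
#'
#' @param gene optional gene symbol to subset to one instrument.
#' @return canonical summary-statistic data.frame with extra columns
#'   \code{gene} and \code{rcc_available}.
#' @export
table1Instruments <- function(gene = NULL) {
  path <- system.file("extdata", "table1_instruments.tsv",
                      package = "targetMR", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$se <- (tab$ci_high - tab$ci_low) / (2 * Z95)
  tab$n <- .GLGC_N
  tab$chromosome <- NA_character_
  tab$position <- NA_real_
  if (!is.null(gene)) {
    tab <- tab[tab$gene == gene, , drop = FALSE]
    if (nrow(tab) == 0L) stopf("no instrument for gene '%s'", gene)
    rownames(tab) <- NULL
  }
  tab
}

#' Published instrument as an Instrument object
#'
#' @param gene one of HMGCR, NPC1L1, PCSK9, LDLR, CETP, APOB.
#' @return an \code{\link{Instrument}} (selection provenance marks the set
#'   as taken from the published table; no LD matrix attached).
#' @export
table1Instrument <- function(gene) {
  v <- table1Instruments(gene)
  new("Instrument", name = gene, variants = v, ld = NULL,
      selection = list(p_threshold = 5e-8, r2_threshold = 0.2,
                       r2_relaxed = 0.40, distance_bp = 250000,
                       relaxed = NA, window = "gene",
                       source = "published table"))
}

#' Printed drug-target odds ratios and confidence intervals
#'
#' The published overall and sex-specific odds ratios (with 95\% CIs and
#' printed raw/FDR p-values) for the HMGCR, PCSK9 and CETP instruments,
#' bundled for reconstruction audits (\code{\link{auditPrintedResults}}).
#'
#' @return data.frame with columns target, stratum, or, ci_low, ci_high,
#'   p_printed, fdr_p_printed.
#' @export
printedResults <- function() {
  path <- system.file("extdata", "printed_results.tsv",
                      package = "targetMR", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
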