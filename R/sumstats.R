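## Summary-statistic I/O and exposure/outcome harmonization.

.MANDATORY_COLS <- c("variant_id", "effect_allele", "other_allele", "beta", "se")

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
  (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-separated table (gzip transparent) with a header row
#' into the canonical summary-statistic layout. Rows whose beta or SE cannot
#' be parsed, or whose SE is non-positive, are rejected; the rejected rows are
#' reported in a warning and attached as the \code{"rejected"} attribute
#' (columns row, variant_id, reason).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical column names
#'   (\code{variant_id}, \code{chromosome}, \code{position},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}, \code{pvalue}, \code{n}, \code{n_cases}) to the file's column
#'   names. Unmapped canonical names are looked up verbatim.
#' @return a data.frame of associations in file order, alleles upper-cased.
#' @export
readSumstats <- function(path, column_map = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stopf("empty summary-statistic file: %s", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "", "."),
                           colClasses = "character")
  if (nrow(raw) == 0L) stopf("summary-statistic file has no data rows: %s", path)

  want <- c(.SUMSTAT_COLS, "n_cases")
  src <- stats::setNames(want, want)
  src[names(column_map)] <- column_map
  missing_mandatory <- .MANDATORY_COLS[!src[.MANDATORY_COLS] %in% names(raw)]
  if (length(missing_mandatory))
    stopf("missing mandatory column(s): %s (file columns: %s)",
          paste(src[missing_mandatory], collapse = ", "),
          paste(names(raw), collapse = ", "))

  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    variant_id = raw[[src["variant_id"]]])
  pull <- function(col) if (src[col] %in% names(raw)) raw[[src[col]]] else NA
  out$chromosome <- as.character(pull("chromosome"))
  out$position <- suppressWarnings(as.numeric(pull("position")))
  out$effect_allele <- toupper(as.character(raw[[src["effect_allele"]]]))
  out$other_allele <- toupper(as.character(raw[[src["other_allele"]]]))
  out$eaf <- suppressWarnings(as.numeric(pull("eaf")))
  beta_raw <- raw[[src["beta"]]]
  se_raw <- raw[[src["se"]]]
  out$beta <- suppressWarnings(as.numeric(beta_raw))
  out$se <- suppressWarnings(as.numeric(se_raw))
  out$pvalue <- suppressWarnings(as.numeric(pull("pvalue")))
  out$n <- suppressWarnings(as.numeric(pull("n")))
  if (src["n_cases"] %in% names(raw))
    out$n_cases <- suppressWarnings(as.numeric(raw[[src["n_cases"]]]))

  reason <- rep(NA_character_, nrow(out))
  reason[!is.na(beta_raw) & is.na(out$beta)] <- "unparseable beta"
  reason[is.na(beta_raw)] <- "missing beta"
  reason[is.na(reason) & !is.na(se_raw) & is.na(out$se)] <- "unparseable SE"
  reason[is.na(reason) & is.na(se_raw)] <- "missing SE"
  reason[is.na(reason) & out$se <= 0] <- "non-positive SE"
  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad), variant_id = out$variant_id[bad],
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("rejected %d row(s): %s", nrow(rejected),
                    paste(sprintf("%s (%s)", rejected$variant_id,
                                  rejected$reason), collapse = "; ")),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejected") <- rejected
  out
}

#' Construct an LDMatrix
#'
#' @param rho square symmetric numeric matrix of signed correlations.
#' @param variant_ids variant ids in matrix order; taken from dimnames when
#'   omitted.
#' @return an \code{LDMatrix}.
#' @export
ldMatrix <- function(rho, variant_ids = rownames(rho)) {
  rho <- as.matrix(rho)
  if (is.null(variant_ids)) stopf("variant ids required (or set dimnames)")
  new("LDMatrix", variantIds = as.character(variant_ids), rho = unname(rho))
}

#' Read / write a plain-text LD correlation matrix
#'
#' Square matrix with variant ids as the first row and first column, values
#' signed correlations in [-1, 1].
#'
#' @param path file path.
#' @return \code{readLDMatrix}: an \code{LDMatrix}.
#' @export
readLDMatrix <- function(path) {
  m <- utils::read.table(path, header = TRUE, check.names = FALSE,
                         row.names = 1)
  m <- as.matrix(m)
  if (!identical(rownames(m), colnames(m)))
    stopf("LD matrix row and column ids disagree")
  ldMatrix(m)
}

#' @rdname readLDMatrix
#' @param ld an \code{LDMatrix}.
#' @export
writeLDMatrix <- function(ld, path) {
  m <- ldRho(ld)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Subset and reorder an LDMatrix to a variant set
#'
#' @param ld an \code{LDMatrix}.
#' @param variant_ids ids to keep, in the desired order (e.g.
#'   \code{variantIds(h)} of a \code{HarmonizedSet}).
#' @return an \code{LDMatrix} aligned to \code{variant_ids}.
#' @export
alignLD <- function(ld, variant_ids) {
  idx <- match(variant_ids, ld@variantIds)
  if (anyNA(idx))
    stopf("LD matrix lacks variant(s): %s",
          paste(variant_ids[is.na(idx)], collapse = ", "))
  new("LDMatrix", variantIds = as.character(variant_ids),
      rho = ld@rho[idx, idx, drop = FALSE])
}

## Align one outcome record to a reference (effect, other) allele pair.
## Returns list(ok, by, sy, eaf, flipped_strand) or NULL if irreconcilable.
## Palindromic pairs are handled by the caller (frequency orientation).
.alignAlleles <- function(ea_ref, oa_ref, rec) {
  ea <- rec$effect_allele; oa <- rec$other_allele
  res <- list(by = rec$beta, sy = rec$se, eaf = rec$eaf)
  if (ea == ea_ref && oa == oa_ref) return(res)
  if (ea == oa_ref && oa == ea_ref) {
    res$by <- -res$by
    res$eaf <- if (is.na(res$eaf)) NA_real_ else 1 - res$eaf
    return(res)
  }
  eac <- .complement[ea]; oac <- .complement[oa]
  if (!is.na(eac) && !is.na(oac)) {
    if (eac == ea_ref && oac == oa_ref) return(res)
    if (eac == oa_ref && oac == ea_ref) {
      res$by <- -res$by
      res$eaf <- if (is.na(res$eaf)) NA_real_ else 1 - res$eaf
      return(res)
    }
  }
  NULL
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect-allele orientation.
#' Variants absent from the outcome are replaced by a user-supplied proxy
#' when available (logged \code{PROXY_SUBSTITUTED}) and otherwise logged
#' \code{MISSING_IN_OUTCOME}. Swapped alleles flip the outcome beta and
#' complement its frequency; strand flips are resolved by base
#' complementation. Palindromic (A/T, G/C) variants with minor-allele
#' frequency inside the ambiguity window are dropped
#' \code{PALINDROMIC_AMBIGUOUS}; outside the window they are oriented by
#' frequency agreement between the studies (dropped when either frequency is
#' missing). Irreconcilable alleles are dropped \code{ALLELE_MISMATCH}.
#'
#' The ambiguity window is applied to the minor-allele frequency as an
#' interval open at the low end and closed at 0.5, using the outcome
#' frequency when present and the exposure frequency otherwise.
#'
#' @param exposure,outcome data.frames in the canonical summary-statistic
#'   layout (see \code{\link{readSumstats}}); exposure variant ids must be
#'   unique.
#' @param palindromic_maf_window length-2 numeric, default \code{c(0.4, 0.5)}.
#' @param proxy_table optional data.frame with columns \code{index_id},
#'   \code{proxy_id} and optionally \code{effect_allele}, \code{other_allele}
#'   giving the proxy's alleles corresponding to the index variant's exposure
#'   effect/other alleles.
#' @return a \code{\link{HarmonizedSet}}. Proxy-substituted variants are
#'   retained under the index variant's id and additionally recorded in the
#'   drop log as provenance.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_maf_window = c(0.4, 0.5),
                      proxy_table = NULL) {
  if (anyDuplicated(exposure$variant_id))
    stopf("duplicate variant_id in exposure: %s",
          paste(unique(exposure$variant_id[duplicated(exposure$variant_id)]),
                collapse = ", "))
  lo <- palindromic_maf_window[1]; hi <- palindromic_maf_window[2]
  out_idx <- function(id) match(id, outcome$variant_id)

  keep <- list(); drops <- list()
  dropIt <- function(id, reason)
    drops[[length(drops) + 1L]] <<- data.frame(variant_id = id, reason = reason,
                                               stringsAsFactors = FALSE)

  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    id <- ex$variant_id
    j <- out_idx(id)
    ref_ea <- ex$effect_allele; ref_oa <- ex$other_allele
    via_proxy <- FALSE
    if (is.na(j) && !is.null(proxy_table)) {
      p <- proxy_table[proxy_table$index_id == id, , drop = FALSE]
      if (nrow(p)) {
        j <- out_idx(p$proxy_id[1])
        if (!is.na(j)) {
          via_proxy <- TRUE
          if (all(c("effect_allele", "other_allele") %in% names(p)) &&
              !is.na(p$effect_allele[1])) {
            ref_ea <- toupper(p$effect_allele[1])
            ref_oa <- toupper(p$other_allele[1])
          }
        }
      }
    }
    if (is.na(j)) { dropIt(id, "MISSING_IN_OUTCOME"); next }
    rec <- outcome[j, ]
    pal <- .isPalindromic(ref_ea, ref_oa)
    if (pal) {
      ## allele set must match (complement is a no-op for palindromic pairs)
      set_ok <- all(sort(c(rec$effect_allele, rec$other_allele)) ==
                      sort(c(ref_ea, ref_oa)))
      if (!set_ok) { dropIt(id, "ALLELE_MISMATCH"); next }
      by <- rec$beta; sy <- rec$se; eaf_out <- rec$eaf
      if (rec$effect_allele != ref_ea) {    # label swap first
        by <- -by
        eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
      }
      freq <- if (!is.na(eaf_out)) eaf_out else ex$eaf
      if (is.na(freq)) { dropIt(id, "PALINDROMIC_AMBIGUOUS"); next }
      maf <- min(freq, 1 - freq)
      if (maf > lo && maf <= hi) { dropIt(id, "PALINDROMIC_AMBIGUOUS"); next }
      ## orient by frequency agreement; needs both studies' frequencies
      if (is.na(ex$eaf) || is.na(eaf_out)) {
        dropIt(id, "PALINDROMIC_AMBIGUOUS"); next
      }
      if (abs(ex$eaf - eaf_out) > abs(ex$eaf - (1 - eaf_out))) by <- -by
      keep[[length(keep) + 1L]] <- data.frame(
        variant_id = id, bx = ex$beta, sx = ex$se, by = by, sy = sy,
        stringsAsFactors = FALSE)
      if (via_proxy) dropIt(id, "PROXY_SUBSTITUTED")
      next
    }
    al <- .alignAlleles(ref_ea, ref_oa, rec)
    if (is.null(al)) { dropIt(id, "ALLELE_MISMATCH"); next }
    keep[[length(keep) + 1L]] <- data.frame(
      variant_id = id, bx = ex$beta, sx = ex$se, by = al$by, sy = al$sy,
      stringsAsFactors = FALSE)
    if (via_proxy) dropIt(id, "PROXY_SUBSTITUTED")
  }

  kept <- if (length(keep)) do.call(rbind, keep) else
    data.frame(variant_id = character(), bx = numeric(), sx = numeric(),
               by = numeric(), sy = numeric(), stringsAsFactors = FALSE)
  dl <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  new("HarmonizedSet", variantIds = kept$variant_id,
      bx = kept$bx, sx = kept$sx, by = kept$by, sy = kept$sy, dropLog = dl)
}

#' Build a HarmonizedSet directly from aligned vectors
#'
#' For simulated or already-aligned inputs where no allele bookkeeping is
#' needed.
#'
#' @param variant_ids,bx,sx,by,sy parallel vectors.
#' @param drop_log optional drop-log data.frame.
#' @return a \code{HarmonizedSet}.
#' @export
harmonizedSet <- function(variant_ids, bx, sx, by, sy,
                          drop_log = data.frame(variant_id = character(),
                                                reason = character(),
                                                stringsAsFactors = FALSE)) {
  new("HarmonizedSet", variantIds = as.character(variant_ids),
      bx = as.numeric(bx), sx = as.numeric(sx),
      by = as.numeric(by), sy = as.numeric(sy), dropLog = drop_log)
}

#' Write a harmonization drop log as TSV
#'
#' @param h a \code{HarmonizedSet}.
#' @param path output path.
#' @export
writeDropLog <- function(h, path) {
  utils::write.table(dropLog(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Variants dropped outright (proxy substitution is provenance, not a drop).
.droppedIds <- function(h) {
  dl <- dropLog(h)
  dl$variant_id[dl$reason != "PROXY_SUBSTITUTED"]
}
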