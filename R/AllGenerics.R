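#' Accessors for targetMR classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a targetMR object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))
#' @rdname accessors
#' @export
setGeneric("exposureBeta", function(x) standardGeneric("exposureBeta"))
#' @rdname accessors
#' @export
setGeneric("exposureSE", function(x) standardGeneric("exposureSE"))
#' @rdname accessors
#' @export
setGeneric("outcomeBeta", function(x) standardGeneric("outcomeBeta"))
#' @rdname accessors
#' @export
setGeneric("outcomeSE", function(x) standardGeneric("outcomeSE"))
#' @rdname accessors
#' @export
setGeneric("ldRho", function(x) standardGeneric("ldRho"))
#' @rdname accessors
#' @export
setGeneric("causalEstimate", function(x) standardGeneric("causalEstimate"))
#' @rdname accessors
#' @export
setGeneric("causalSE", function(x) standardGeneric("causalSE"))
#' @rdname accessors
#' @export
setGeneric("causalP", function(x) standardGeneric("causalP"))
#' @rdname accessors
#' @export
setGeneric("confidenceInterval", function(x) standardGeneric("confidenceInterval"))
#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname accessors
#' @export
setGeneric("kUsed", function(x) standardGeneric("kUsed"))
#' @rdname accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))
#' @rdname accessors
#' @export
setGeneric("instrumentVariants", function(x) standardGeneric("instrumentVariants"))
#' @rdname accessors
#' @export
setGeneric("selectionInfo", function(x) standardGeneric("selectionInfo"))

setMethod("variantIds", "HarmonizedSet", function(x) x@variantIds)
setMethod("variantIds", "LDMatrix", function(x) x@variantIds)
setMethod("variantIds", "Instrument", function(x) x@variants$variant_id)
setMethod("nVariants", "HarmonizedSet", function(x) length(x@variantIds))
setMethod("nVariants", "LDMatrix", function(x) length(x@variantIds))
setMethod("nVariants", "Instrument", function(x) nrow(x@variants))
setMethod("dropLog", "HarmonizedSet", function(x) x@dropLog)
setMethod("exposureBeta", "HarmonizedSet", function(x) x@bx)
setMethod("exposureSE", "HarmonizedSet", function(x) x@sx)
setMethod("outcomeBeta", "HarmonizedSet", function(x) x@by)
setMethod("outcomeSE", "HarmonizedSet", function(x) x@sy)
setMethod("ldRho", "LDMatrix", function(x) {
  r <- x@rho
  dimnames(r) <- list(x@variantIds, x@variantIds)
  r
})
setMethod("causalEstimate", "MREstimate", function(x) x@beta)
setMethod("causalSE", "MREstimate", function(x) x@se)
setMethod("causalP", "MREstimate", function(x) x@pvalue)
setMethod("confidenceInterval", "MREstimate",
          function(x) c(low = x@ciLow, high = x@ciHigh))
setMethod("mrMethod", "MREstimate", function(x) x@method)
setMethod("kUsed", "MREstimate", function(x) x@kUsed)
setMethod("eggerIntercept", "MREstimate", function(x)
  c(intercept = x@intercept, se = x@interceptSE, pvalue = x@interceptP))
setMethod("instrumentVariants", "Instrument", function(x) x@variants)
setMethod("selectionInfo", "Instrument", function(x) x@selection)

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet with", nVariants(object), "retained variants\n")
  dl <- dropLog(object)
  if (nrow(dl)) {
    tab <- table(dl$reason)
    cat("drop log:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  } else cat("drop log: empty\n")
  invisible(object)
})

setMethod("show", "MREstimate", function(object) {
  or <- orCiFromBeta(object@beta, object@se)
  cat(sprintf("MREstimate [%s] k = %d\n", object@method, object@kUsed))
  cat(sprintf("  beta = %.4f (SE %.4f), OR = %.3f [95%% CI %.3f-%.3f], p = %.3g\n",
              object@beta, object@se, or["or"], or["ci_low"], or["ci_high"],
              object@pvalue))
  if (!is.na(object@intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                object@intercept, object@interceptSE, object@interceptP))
  invisible(object)
})

setMethod("show", "Instrument", function(object) {
  sel <- object@selection
  cat(sprintf("Instrument '%s': %d variants%s\n", object@name,
              nVariants(object),
              if (isTRUE(sel$relaxed)) " (relaxed r2 threshold)" else ""))
  invisible(object)
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix over %d variants\n", nVariants(object)))
  invisible(object)
})

setMethod("show", "GeneRegion", function(object) {
  cat(sprintf("GeneRegion %s: chr%s:%d-%d (+/- %d bp)\n", object@gene,
              object@chromosome, as.integer(object@start),
              as.integer(object@end), as.integer(object@flank)))
  invisible(object)
})
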