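## Config-driven orchestration: drug-target MR (targets x outcome strata),
## molecule-specific (trait) MR, and the printed-results audit. Failures are
## isolated per analysis cell.

#' Read gene regions from a BED-like TSV
#'
#' Columns chromosome, start, end, gene (header required); coordinates are
#' 1-based inclusive GRCh37.
#'
#' @param path file path.
#' @param flank cis flank applied to every region, default 100 kb.
#' @return named list of \code{\link{geneRegion}} objects.
#' @export
readGeneRegions <- function(path, flank = 1e5) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "gene")
  if (!all(need %in% names(tab)))
    stopf("gene-region file needs columns: %s", paste(need, collapse = ", "))
  regions <- lapply(seq_len(nrow(tab)), function(i)
    geneRegion(tab$gene[i], tab$chromosome[i], tab$start[i], tab$end[i],
               flank))
  stats::setNames(regions, tab$gene)
}

#' Assemble an analysis configuration
#'
#' @param exposures list of exposure descriptors:
#'   \code{list(name =, sumstats = <data.frame or path>, type =
#'   "gene_target"|"trait", region = <GeneRegion, gene targets only>,
#'   ld = <LDMatrix or path, optional>)}.
#' @param outcomes list of outcome descriptors: \code{list(name =,
#'   sumstats =, n =, n_cases =, stratum =)}.
#' @param estimator settings: \code{model}
#'   ("multiplicative_random"/"fixed"), \code{ld_correction} (combine the LD
#'   correction with the random-effects model; on by default), \code{ridge}.
#' @param palindromic_maf_window passed to \code{\link{harmonize}}.
#' @param proxy_table passed to \code{\link{harmonize}}.
#' @param fdr_family optional character vector of "exposure|outcome" labels
#'   defining the multiple-testing family; default all cells.
#' @param sex_strata length-2 stratum labels paired in the sex-difference
#'   test, default \code{c("men", "women")}.
#' @param seed master seed for seeded diagnostics.
#' @return validated config (class \code{"targetMRConfig"} list).
#' @export
analysisConfig <- function(exposures, outcomes,
                           estimator = list(model = "multiplicative_random",
                                            ld_correction = TRUE,
                                            ridge = FALSE),
                           palindromic_maf_window = c(0.4, 0.5),
                           proxy_table = NULL, fdr_family = NULL,
                           sex_strata = c("men", "women"), seed = 1L) {
  for (ex in exposures) {
    if (is.null(ex$name) || is.null(ex$sumstats) || is.null(ex$type))
      stopf("each exposure needs name, sumstats, type")
    if (ex$type == "gene_target" && is.null(ex$region))
      stopf("gene_target exposure '%s' needs a region", ex$name)
    if (!ex$type %in% c("gene_target", "trait"))
      stopf("exposure type must be gene_target or trait")
  }
  for (oc in outcomes) {
    if (is.null(oc$name) || is.null(oc$sumstats))
      stopf("each outcome needs name and sumstats")
    if (!is.null(oc$n_cases) && !is.null(oc$n) && oc$n_cases > oc$n)
      stopf("outcome '%s': n_cases exceeds n", oc$name)
  }
  structure(list(exposures = exposures, outcomes = outcomes,
                 estimator = estimator,
                 palindromic_maf_window = palindromic_maf_window,
                 proxy_table = proxy_table, fdr_family = fdr_family,
                 sex_strata = sex_strata, seed = as.integer(seed)),
            class = "targetMRConfig")
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror \code{\link{analysisConfig}}; sumstats, region and LD entries
#' are file paths resolved relative to the YAML file.
#'
#' @param path YAML path.
#' @return a config as from \code{\link{analysisConfig}}.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  exposures <- lapply(y$exposures, function(ex) {
    if (!is.null(ex$region) && is.character(ex$region))
      ex$region <- readGeneRegions(rel(ex$region))[[ex$name]]
    if (!is.null(ex$region) && is.list(ex$region))
      ex$region <- geneRegion(ex$name, ex$region$chromosome, ex$region$start,
                              ex$region$end, ex$region$flank %||% 1e5)
    if (is.character(ex$sumstats)) ex$sumstats <- rel(ex$sumstats)
    if (!is.null(ex$ld) && is.character(ex$ld)) ex$ld <- rel(ex$ld)
    ex
  })
  outcomes <- lapply(y$outcomes, function(oc) {
    if (is.character(oc$sumstats)) oc$sumstats <- rel(oc$sumstats)
    oc
  })
  analysisConfig(exposures, outcomes,
                 estimator = y$estimator %||%
                   list(model = "multiplicative_random", ld_correction = TRUE,
                        ridge = FALSE),
                 seed = y$seed %||% 1L)
}

.loadSumstats <- function(x) if (is.character(x)) readSumstats(x) else x
.loadLD <- function(x) {
  if (is.null(x)) NULL
  else if (is.character(x)) readLDMatrix(x)
  else x
}

.emptyResultRow <- function(exposure, outcome, stratum) {
  data.frame(exposure = exposure, outcome = outcome, stratum = stratum,
             method = NA_character_, k = NA_integer_, beta = NA_real_,
             se = NA_real_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pvalue = NA_real_, fdr_pvalue = NA_real_,
             error = NA_character_, stringsAsFactors = FALSE)
}

## One (instrument, outcome) analysis cell: harmonize, estimate, diagnose.
.runCell <- function(instrument, oc, config, cell_seed) {
  v <- instrumentVariants(instrument)
  h <- harmonize(v, .loadSumstats(oc$sumstats),
                 palindromic_maf_window = config$palindromic_maf_window,
                 proxy_table = config$proxy_table)
  k <- nVariants(h)
  accounted <- length(unique(c(variantIds(h), .droppedIds(h))))
  if (accounted != nrow(v))
    stopf("conservation audit failed: %d of %d variants unaccounted",
          nrow(v) - accounted, nrow(v))
  if (k == 0L) stopf("no variant survived harmonization")
  ld_h <- instrument@ld
  use_ld <- isTRUE(config$estimator$ld_correction) && !is.null(ld_h) &&
    all(variantIds(h) %in% variantIds(ld_h))
  if (use_ld) ld_h <- alignLD(ld_h, variantIds(h))
  model <- config$estimator$model %||% "multiplicative_random"
  est <- if (k < 3L) mrWaldRatio(h)
  else if (use_ld) mrIVWCorrelated(h, ld_h, model = model,
                                   ridge = isTRUE(config$estimator$ridge))
  else mrIVW(h, model = model)

  diag_list <- list(
    q_ivw = if (k >= 2) cochranQ(h) else NULL,
    egger_intercept = if (k >= 3) eggerInterceptTest(
      h, if (use_ld) ld_h else NULL) else NULL,
    i2_gx = if (k >= 2) i2GX(h) else NULL,
    presso = if (k >= 4) mrPresso(h, n_sim = 1000, seed = cell_seed) else NULL,
    loo = if (k >= 2) leaveOneOut(
      h, estimator = if (use_ld) "ivw_correlated" else "ivw",
      ld = if (use_ld) ld_h else NULL) else NULL,
    sensitivity = if (k >= 3) list(
      egger = mrEgger(h, if (use_ld) ld_h else NULL),
      wmedian = mrWeightedMedian(h, seed = cell_seed + 1L),
      wmode = mrWeightedMode(h, seed = cell_seed + 2L)) else NULL)
  list(h = h, estimate = est, diagnostics = diag_list)
}

.collectResults <- function(config, selectFun) {
  cells <- expand.grid(e = seq_along(config$exposures),
                       o = seq_along(config$outcomes))
  seeds <- childSeeds(config$seed, nrow(cells) * 4L)
  rows <- list(); diagnostics <- list(); drop_logs <- list()
  instruments <- list()
  for (ex in config$exposures)
    instruments[[ex$name]] <- tryCatch(selectFun(ex), error = identity)
  for (ci in seq_len(nrow(cells))) {
    ex <- config$exposures[[cells$e[ci]]]
    oc <- config$outcomes[[cells$o[ci]]]
    row <- .emptyResultRow(ex$name, oc$name, oc$stratum %||% "overall")
    label <- paste(ex$name, oc$name, sep = "|")
    instr <- instruments[[ex$name]]
    res <- if (inherits(instr, "error")) instr else
      tryCatch(.runCell(instr, oc, config, seeds[ci]), error = identity)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      est <- res$estimate
      or <- orCiFromBeta(causalEstimate(est), causalSE(est))
      row$method <- mrMethod(est); row$k <- kUsed(est)
      row$beta <- causalEstimate(est); row$se <- causalSE(est)
      row$or <- or["or"]; row$ci_low <- or["ci_low"]
      row$ci_high <- or["ci_high"]; row$pvalue <- causalP(est)
      diagnostics[[label]] <- res$diagnostics
      drop_logs[[label]] <- dropLog(res$h)
    }
    rows[[label]] <- row
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ## FDR across the configured family
  lab <- paste(results$exposure, results$outcome, sep = "|")
  fam <- config$fdr_family %||% lab
  in_fam <- lab %in% fam & !is.na(results$pvalue)
  if (any(in_fam))
    results$fdr_pvalue[in_fam] <- bhFDR(results$pvalue[in_fam])
  ## sex-difference tests for paired strata per exposure
  sd_rows <- list()
  st <- config$sex_strata
  for (exn in unique(results$exposure)) {
    a <- results[results$exposure == exn & results$stratum == st[1] &
                   !is.na(results$beta), , drop = FALSE]
    b <- results[results$exposure == exn & results$stratum == st[2] &
                   !is.na(results$beta), , drop = FALSE]
    if (nrow(a) == 1L && nrow(b) == 1L) {
      sd_ <- sexDifferenceTest(
        newMREstimate(a$method, a$beta, a$se, a$k),
        newMREstimate(b$method, b$beta, b$se, b$k))
      sd_rows[[exn]] <- data.frame(exposure = exn, z = sd_$z,
                                   pvalue = sd_$pvalue,
                                   stringsAsFactors = FALSE)
    }
  }
  sex_difference <- if (length(sd_rows)) do.call(rbind, sd_rows) else
    data.frame(exposure = character(), z = numeric(), pvalue = numeric(),
               stringsAsFactors = FALSE)
  rownames(sex_difference) <- NULL
  list(results = results, diagnostics = diagnostics, drop_logs = drop_logs,
       sex_difference = sex_difference, instruments = instruments,
       config = config)
}

#' Run the drug-target (cis instrument) MR analysis grid
#'
#' For every (gene target, outcome) cell: gene-window instrument selection,
#' harmonization, LD-adjusted multiplicative random-effects IVW (Wald ratio
#' below three variants), the sensitivity battery (Egger, weighted
#' median/mode, MR-PRESSO, leave-one-out, Q, I2_GX), BH-FDR across the
#' configured family, and sex-difference tests for paired strata. A failing
#' cell records its error without aborting the rest of the grid.
#'
#' @param config from \code{\link{analysisConfig}}; exposures must be of
#'   type \code{gene_target}.
#' @return list with \code{results} (tidy data.frame), \code{diagnostics},
#'   \code{drop_logs}, \code{sex_difference}, \code{instruments},
#'   \code{config}.
#' @export
runDrugTargetMR <- function(config) {
  .collectResults(config, function(ex) {
    if (ex$type != "gene_target")
      stopf("exposure '%s' is not a gene target", ex$name)
    selectGeneWindow(.loadSumstats(ex$sumstats), ex$region,
                     ld = .loadLD(ex$ld))
  })
}

#' Run the molecule-specific (trait) MR analysis grid
#'
#' As \code{\link{runDrugTargetMR}} with genome-wide instrument selection
#' and uncorrected IVW (variants are quasi-independent by construction).
#'
#' @param config from \code{\link{analysisConfig}}; exposures of type
#'   \code{trait}.
#' @return as \code{\link{runDrugTargetMR}}.
#' @export
runTraitMR <- function(config) {
  config$estimator$ld_correction <- FALSE
  .collectResults(config, function(ex) {
    if (ex$type != "trait") stopf("exposure '%s' is not a trait", ex$name)
    selectGenomewide(.loadSumstats(ex$sumstats), ld = .loadLD(ex$ld),
                     name = ex$name)
  })
}

#' Audit published drug-target results from their printed ORs and CIs
#'
#' Recomputes, from the bundled table of printed odds ratios and confidence
#' intervals, each cell's two-sided p-value and each target's
#' men-versus-women difference p-value.
#'
#' @param printed optional data.frame overriding the bundled fixture; needs
#'   columns target, stratum, or, ci_low, ci_high.
#' @return list with \code{cells} (target, stratum, recomputed p) and
#'   \code{sex_difference} (target, z, p).
#' @export
auditPrintedResults <- function(printed = NULL) {
  if (is.null(printed)) printed <- printedResults()
  printed$p_recomputed <- pFromOrCi(printed$or, printed$ci_low,
                                    printed$ci_high)
  sd_rows <- list()
  for (tg in unique(printed$target)) {
    m <- printed[printed$target == tg & printed$stratum == "men", ]
    w <- printed[printed$target == tg & printed$stratum == "women", ]
    if (nrow(m) == 1L && nrow(w) == 1L) {
      sd_ <- sexDifferenceTest(
        estimateFromOrCi(m$or, m$ci_low, m$ci_high),
        estimateFromOrCi(w$or, w$ci_low, w$ci_high))
      sd_rows[[tg]] <- data.frame(target = tg, z = sd_$z,
                                  pvalue = sd_$pvalue,
                                  stringsAsFactors = FALSE)
    }
  }
  sex_difference <- do.call(rbind, sd_rows)
  rownames(sex_difference) <- NULL
  list(cells = printed, sex_difference = sex_difference)
}
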