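## Synthetic two-sample GWAS generator with known ground truth. Emulates the
## statistical structure the estimators assume: SNP-exposure effects in SD
## units with sampling error, case-control outcome effects on the log-OR
## scale built as theta * gamma + pleiotropy + noise, optional AR(1) LD, and
## palindromic alleles.

#' Configuration of the synthetic two-sample generator
#'
#' Defaults mirror the calibration conditions the package is validated
#' under: 50 instrument variants from an exposure GWAS of 100,000, a binary
#' outcome study of 20,000 with 30\% cases, true causal effect 0.5 on the
#' log-OR-per-SD scale, no pleiotropy, no LD.
#'
#' @param k number of variants.
#' @param n_exp,n_out exposure and outcome sample sizes.
#' @param case_fraction outcome case fraction K in (0, 1).
#' @param maf_range uniform range of minor-allele frequencies, within
#'   (0, 0.5].
#' @param theta true causal effect (log-OR per SD of exposure).
#' @param pleiotropy mean and SD of per-variant direct effects, length 2.
#' @param invalid_fraction share of variants carrying pleiotropy.
#' @param ld_rho AR(1) correlation between adjacent variants, in [0, 1).
#' @param palindromic_fraction share of variants given A/T or G/C alleles.
#' @param gamma_sd scale of true SNP-exposure effects (SD units).
#' @param seed integer seed.
#' @return a \code{SimulationConfig}.
#' @export
simulationConfig <- function(k = 50, n_exp = 1e5, n_out = 2e4,
                             case_fraction = 0.3, maf_range = c(0.05, 0.5),
                             theta = 0.5, pleiotropy = c(0, 0),
                             invalid_fraction = 0, ld_rho = 0,
                             palindromic_fraction = 0, gamma_sd = 0.02,
                             seed = 1L) {
  new("SimulationConfig", k = as.integer(k), nExposure = n_exp,
      nOutcome = n_out, caseFraction = case_fraction,
      mafRange = as.numeric(maf_range), theta = theta,
      pleiotropyMean = pleiotropy[1], pleiotropySD = pleiotropy[2],
      invalidFraction = invalid_fraction, ldRho = ld_rho,
      palindromicFraction = palindromic_fraction, gammaSD = gamma_sd,
      seed = as.integer(seed))
}

.Z_GW <- NULL  # genome-wide z threshold, computed lazily
.zGenomewide <- function() stats::qnorm(1 - 2.5e-8)

.NONPAL_PAIRS <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                       c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a two-sample summary-statistic pair with known truth
#'
#' True SNP-exposure effects gamma are drawn from normal(0, gamma_sd^2) and
#' rejection-sampled to pass genome-wide significance at the exposure sample
#' size (conditioning on the true effect, so the instruments are free of
#' winner's curse); observed exposure betas add sampling noise with SE
#' 1/sqrt(2 n f (1 - f)) and AR(1) correlation; outcome betas are
#' theta * gamma + alpha + noise with case-control SE
#' 1/sqrt(2 n K (1 - K) f (1 - f)), alpha the direct (pleiotropic) effect of
#' the invalid subset.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{exposure} and \code{outcome} summary-statistic
#'   data.frames (canonical layout, allele-aligned), \code{ld} (the true
#'   \code{LDMatrix}), and \code{truth} (gamma, alpha, theta, invalid ids).
#' @export
simulateTwoSample <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  k <- cfg@k
  withSeed(cfg@seed, {
    f <- stats::runif(k, cfg@mafRange[1], cfg@mafRange[2])
    sx <- 1 / sqrt(2 * cfg@nExposure * f * (1 - f))
    zgw <- .zGenomewide()
    gamma <- vapply(seq_len(k), function(i) {
      for (attempt in seq_len(10000)) {
        g <- stats::rnorm(1, 0, cfg@gammaSD)
        if (abs(g) / sx[i] > zgw) return(g)
      }
      stopf(paste0("could not draw a genome-wide-significant effect for ",
                   "variant %d; increase gamma_sd or n_exp"), i)
    }, numeric(1))

    rho <- cfg@ldRho^abs(outer(seq_len(k), seq_len(k), "-"))
    chol_rho <- chol(rho)
    mvn <- function(sd) drop(stats::rnorm(k) %*% chol_rho) * sd
    bx <- gamma + mvn(sx)

    n_invalid <- round(cfg@invalidFraction * k)
    invalid <- if (n_invalid > 0) sort(sample.int(k, n_invalid)) else integer()
    alpha <- numeric(k)
    if (n_invalid > 0)
      alpha[invalid] <- stats::rnorm(n_invalid, cfg@pleiotropyMean,
                                     cfg@pleiotropySD)

    K <- cfg@caseFraction
    sy <- 1 / sqrt(2 * cfg@nOutcome * K * (1 - K) * f * (1 - f))
    by <- cfg@theta * gamma + alpha + mvn(sy)

    n_pal <- round(cfg@palindromicFraction * k)
    pal <- if (n_pal > 0) sample.int(k, n_pal) else integer()
    alleles <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), k, TRUE), ,
                             drop = FALSE]
    if (n_pal > 0)
      alleles[pal, ] <- .PAL_PAIRS[sample.int(nrow(.PAL_PAIRS), n_pal, TRUE), ,
                                   drop = FALSE]

    ids <- sprintf("rs%07d", seq_len(k))
    pos <- 1e6 + (seq_len(k) - 1L) * 5e4
    exposure <- data.frame(
      variant_id = ids, chromosome = "1", position = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = f, beta = bx, se = sx, pvalue = zPvalue(bx, sx),
      n = cfg@nExposure, stringsAsFactors = FALSE)
    outcome <- data.frame(
      variant_id = ids, chromosome = "1", position = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = f, beta = by, se = sy, pvalue = zPvalue(by, sy),
      n = cfg@nOutcome, n_cases = round(K * cfg@nOutcome),
      stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         ld = ldMatrix(rho, ids),
         truth = list(gamma = gamma, alpha = alpha, theta = cfg@theta,
                      invalid = ids[invalid], config = cfg))
  })
}

#' HarmonizedSet straight from a simulation
#'
#' The generator writes exposure and outcome already allele-aligned, so a
#' harmonized set can be formed directly; equivalent to running
#' \code{\link{harmonize}} when no palindromic variants were requested.
#'
#' @param sim output of \code{\link{simulateTwoSample}}.
#' @return a \code{HarmonizedSet}.
#' @export
simulatedHarmonizedSet <- function(sim) {
  harmonizedSet(sim$exposure$variant_id, sim$exposure$beta, sim$exposure$se,
                sim$outcome$beta, sim$outcome$se)
}

#' Simulate a dense cis region with planted LD blocks
#'
#' Builds regional exposure summary statistics in which correlated blocks
#' (constant within-block correlation) and isolated significant variants sit
#' at known positions, so the expected output of gene-window clumping is
#' known by construction: the most significant member of each block plus the
#' isolated variants. P-values decrease with the order of construction
#' (block members first, then isolated variants), making the greedy order
#' deterministic.
#'
#' @param blocks list of \code{list(size =, rho =)} giving block sizes and
#'   within-block correlations (pairwise r-squared = rho^2).
#' @param n_isolated number of uncorrelated significant variants.
#' @param between_rho correlation between variants of different blocks (and
#'   between blocks and isolated variants), default 0.
#' @param region a \code{\link{geneRegion}}; variants are laid inside its
#'   flanked window.
#' @param n_exp exposure sample size, default 188577.
#' @param spacing_bp distance between consecutive variants, default 5 kb.
#' @param id_prefix prefix of the generated variant ids (keep distinct when
#'   combining several regions into one table).
#' @param seed integer seed.
#' @return list with \code{sumstats}, \code{ld}, \code{region},
#'   \code{block_ids} (list of id vectors per block), \code{isolated_ids}.
#' @export
simulateDrugTargetRegion <- function(blocks = list(), n_isolated = 3,
                                     between_rho = 0,
                                     region = geneRegion("SYNTH1", "1",
                                                         5e6, 5.05e6),
                                     n_exp = 188577, spacing_bp = 5000,
                                     id_prefix = "rs9", seed = 1L) {
  sizes <- vapply(blocks, function(b) as.integer(b$size), integer(1))
  k <- sum(sizes) + n_isolated
  if (k < 1) stopf("empty region requested")
  rho <- diag(k)
  if (between_rho != 0) rho[rho == 0] <- between_rho
  at <- 0L
  membership <- rep(0L, k)
  for (b in seq_along(blocks)) {
    idx <- at + seq_len(sizes[b])
    rho[idx, idx] <- blocks[[b]]$rho
    diag(rho)[idx] <- 1
    membership[idx] <- b
    at <- at + sizes[b]
  }
  withSeed(seed, {
    ids <- sprintf("%s%06d", id_prefix, seq_len(k))
    pos <- (region@start - region@flank) + 1000 + (seq_len(k) - 1L) * spacing_bp
    se <- 0.005
    beta <- -(0.10 - 0.0005 * (seq_len(k) - 1L))   # p increases with index
    f <- stats::runif(k, 0.1, 0.5)
    alleles <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), k, TRUE), ,
                             drop = FALSE]
    sumstats <- data.frame(
      variant_id = ids, chromosome = region@chromosome, position = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = f, beta = beta, se = se, pvalue = zPvalue(beta, se), n = n_exp,
      stringsAsFactors = FALSE)
    list(sumstats = sumstats, ld = ldMatrix(rho, ids), region = region,
         block_ids = split(ids[membership > 0], membership[membership > 0]),
         isolated_ids = ids[membership == 0])
  })
}

#' Write summary statistics in the canonical TSV layout
#'
#' @param sumstats a canonical summary-statistic data.frame.
#' @param path output path (\code{.gz} suffix writes gzip).
#' @export
writeSumstats <- function(sumstats, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(sumstats, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
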