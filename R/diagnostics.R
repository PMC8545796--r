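## Heterogeneity, pleiotropy, dilution (NOME), outlier and influence
## diagnostics.

#' Cochran's Q heterogeneity test
#'
#' In the IVW framework, Q = sum_i (bx_i/sy_i)^2 (by_i/bx_i - beta)^2 about
#' the supplied (or freshly computed) IVW estimate, df = k - 1. In the Egger
#' framework, the weighted residual sum of squares about the fitted Egger
#' line, df = k - 2. The per-variant terms are returned for audit.
#'
#' @param h a \code{HarmonizedSet}.
#' @param framework \code{"IVW"} (default) or \code{"EGGER"}.
#' @param estimate optional \code{MREstimate} the IVW Q is taken about;
#'   computed from \code{h} when omitted.
#' @return list with \code{q}, \code{df}, \code{pvalue}, \code{framework},
#'   \code{terms} (per-variant contributions, IVW framework).
#' @export
cochranQ <- function(h, framework = c("IVW", "EGGER"), estimate = NULL) {
  framework <- match.arg(framework)
  k <- nVariants(h)
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  if (framework == "IVW") {
    if (k < 2L) stopf("Q (IVW) needs at least 2 variants")
    beta <- if (is.null(estimate)) {
      w <- 1 / sy^2
      sum(w * bx * by) / sum(w * bx^2)
    } else causalEstimate(estimate)
    terms <- (bx / sy)^2 * (by / bx - beta)^2
    names(terms) <- variantIds(h)
    q <- sum(terms)
    df <- k - 1
  } else {
    if (k < 3L) stopf("Q (Egger) needs at least 3 variants")
    fit <- .eggerFit(h)
    q <- fit$q
    df <- fit$df
    terms <- NULL
  }
  list(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE),
       framework = framework, terms = terms)
}

#' MR-Egger intercept (pleiotropy) test
#'
#' @param h a \code{HarmonizedSet} with at least 3 variants.
#' @param ld optional aligned \code{LDMatrix}.
#' @return list with \code{intercept}, \code{se}, \code{pvalue}.
#' @export
eggerInterceptTest <- function(h, ld = NULL) {
  est <- mrEgger(h, ld)
  ic <- eggerIntercept(est)
  list(intercept = unname(ic["intercept"]), se = unname(ic["se"]),
       pvalue = unname(ic["pvalue"]))
}

#' I2_GX statistic for the NOME assumption
#'
#' Quantifies regression dilution of the Egger slope from measurement error
#' in the exposure betas: with weights 1/sx^2 on |bx| (the Egger
#' orientation), Q_GX = sum_i (|bx_i| - bbar)^2 / sx_i^2 about the weighted
#' mean bbar, and I2_GX = max(0, (Q_GX - (k - 1)) / Q_GX). Values near 1 mean
#' negligible dilution; below ~0.9 a SIMEX correction is advisable.
#'
#' @param h a \code{HarmonizedSet} with at least 2 variants.
#' @return the I2_GX fraction.
#' @export
i2GX <- function(h) {
  k <- nVariants(h)
  if (k < 2L) stopf("I2_GX undefined for fewer than 2 variants")
  b <- abs(exposureBeta(h))
  w <- 1 / exposureSE(h)^2
  bbar <- sum(w * b) / sum(w)
  q <- sum(w * (b - bbar)^2)
  if (q == 0) return(0)
  max(0, (q - (k - 1)) / q)
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation extrapolation against exposure measurement error: for each
#' lambda > 0, \code{b_reps} pseudo-datasets add noise of variance
#' lambda * sx^2 to the exposure betas; the mean Egger slope per lambda is
#' fitted by a quadratic in lambda and extrapolated to lambda = -1 (the
#' no-measurement-error limit). The SE is a jackknife over replicates. With
#' error-free exposure betas the plain Egger fit is returned unchanged.
#'
#' @param h a \code{HarmonizedSet} with at least 3 variants.
#' @param lambdas added-noise multiples; must contain at least 3 distinct
#'   values for the quadratic fit. Default \code{c(0, 0.5, 1, 1.5, 2)}.
#' @param b_reps pseudo-datasets per lambda, default 1000.
#' @param extrapolation only \code{"quadratic"} is supported.
#' @param seed integer seed.
#' @param ld optional aligned \code{LDMatrix} passed to the Egger fits.
#' @return an \code{\link{MREstimate}} with method \code{EGGER_SIMEX}.
#' @export
simexEgger <- function(h, lambdas = c(0, 0.5, 1.0, 1.5, 2.0), b_reps = 1000,
                       extrapolation = "quadratic", seed, ld = NULL) {
  .checkK(h, 3L, "SIMEX Egger")
  if (!identical(extrapolation, "quadratic"))
    stopf("only quadratic extrapolation is supported")
  lambdas <- sort(unique(lambdas))
  if (length(lambdas) < 3L)
    stopf("degenerate quadratic fit: need at least 3 distinct lambdas")
  base <- mrEgger(h, ld)
  sx <- exposureSE(h)
  if (all(sx == 0)) {
    return(newMREstimate("EGGER_SIMEX", causalEstimate(base), causalSE(base),
                         nVariants(h)))
  }
  k <- nVariants(h)
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  pos <- lambdas[lambdas > 0]
  ## antithetic noise pairs (+e, -e) halve the Monte-Carlo variance of the
  ## per-lambda mean slopes that feed the extrapolation
  slopes <- withSeed(seed, {
    vapply(pos, function(lam) {
      vapply(seq_len(b_reps), function(b) {
        e <- stats::rnorm(k, 0, sqrt(lam) * sx)
        mean(vapply(list(e, -e), function(ei) {
          hb <- harmonizedSet(variantIds(h), bx + ei, sx, by, sy)
          unname(.eggerFit(hb, ld)$coef["slope"])
        }, numeric(1)))
      }, numeric(1))
    }, numeric(b_reps))
  })  # b_reps x length(pos)
  has0 <- any(lambdas == 0)
  lam_all <- c(if (has0) 0, pos)
  mean_all <- c(if (has0) causalEstimate(base), colMeans(slopes))
  ## extrapolation at lambda = -1 is linear in the per-lambda means:
  ## theta = g' mean_all with g from the quadratic least-squares projector
  A <- cbind(1, lam_all, lam_all^2)
  g <- drop(c(1, -1, 1) %*% solve(crossprod(A), t(A)))
  est <- sum(g * mean_all)
  ## jackknife over replicates (replicate i removed jointly from every lambda)
  gpos <- g[(length(g) - length(pos) + 1):length(g)]
  jk <- vapply(seq_len(b_reps), function(i) {
    mpos_i <- (colSums(slopes) - slopes[i, ]) / (b_reps - 1)
    base_part <- if (has0) g[1] * causalEstimate(base) else 0
    base_part + sum(gpos * mpos_i)
  }, numeric(1))
  se_sim <- sqrt((b_reps - 1) / b_reps * sum((jk - mean(jk))^2))
  ## simulation noise alone understates uncertainty; combine with the
  ## sampling SE of the underlying Egger slope
  se <- sqrt(causalSE(base)^2 + se_sim^2)
  newMREstimate("EGGER_SIMEX", est, se, k)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Global test: the observed residual sum of squares of each outcome beta
#' about its leave-one-out IVW prediction, compared with a parametric null in
#' which outcome betas are redrawn from normal(fitted, sy) and the
#' leave-one-out procedure re-run per simulation. Per-variant contributions
#' give empirical outlier p-values ((r+1)/(n+1) convention), flagged at the
#' Bonferroni-adjusted level. When outliers are flagged the estimate is
#' recomputed without them and the shift is compared against the shift from
#' removing equally many random variants (distortion test).
#'
#' @param h a \code{HarmonizedSet} with at least 4 variants.
#' @param n_sim simulations, default 1000.
#' @param outlier_alpha per-family outlier level before Bonferroni, default
#'   0.05.
#' @param seed integer seed.
#' @return list with \code{global_rss}, \code{global_p}, \code{outlier_p}
#'   (named), \code{outliers}, \code{distortion_p}, \code{corrected}
#'   (\code{MREstimate} after outlier removal), \code{n_sim}, \code{seed}.
#' @export
mrPresso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed) {
  k <- nVariants(h)
  if (k < 4L) stopf("MR-PRESSO needs at least 4 variants (got %d)", k)
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  ids <- variantIds(h)
  w <- 1 / sy^2
  S1 <- sum(w * bx * by); S2 <- sum(w * bx^2)
  loo_beta <- (S1 - w * bx * by) / (S2 - w * bx^2)
  fitted <- loo_beta * bx
  d_obs <- (by - fitted)^2
  rss_obs <- sum(d_obs)

  sim <- withSeed(seed, {
    BY <- matrix(stats::rnorm(n_sim * k, mean = rep(fitted, each = n_sim),
                              sd = rep(sy, each = n_sim)), n_sim, k)
    S1s <- BY %*% (w * bx)                       # n_sim x 1
    num <- sweep(-BY * rep(w * bx, each = n_sim), 1, S1s, "+")
    loo_s <- sweep(num, 2, S2 - w * bx^2, "/")   # per-sim LOO betas
    D <- (BY - loo_s * rep(bx, each = n_sim))^2
    list(rss = rowSums(D), D = D)
  })
  global_p <- (sum(sim$rss >= rss_obs) + 1) / (n_sim + 1)
  outlier_p <- vapply(seq_len(k), function(i)
    (sum(sim$D[, i] >= d_obs[i]) + 1) / (n_sim + 1), numeric(1))
  names(outlier_p) <- ids
  flagged <- outlier_p < outlier_alpha / k

  full <- mrIVW(h)
  if (any(flagged) && sum(!flagged) >= 1L) {
    keepIdx <- which(!flagged)
    h2 <- harmonizedSet(ids[keepIdx], bx[keepIdx], exposureSE(h)[keepIdx],
                        by[keepIdx], sy[keepIdx])
    corrected <- mrIVW(h2)
    delta_obs <- causalEstimate(corrected) - causalEstimate(full)
    n_out <- sum(flagged)
    deltas <- withSeed(seed + 1L, vapply(seq_len(n_sim), function(s) {
      drop_i <- sample.int(k, n_out)
      wk <- w[-drop_i]; bxk <- bx[-drop_i]; byk <- by[-drop_i]
      sum(wk * bxk * byk) / sum(wk * bxk^2) - causalEstimate(full)
    }, numeric(1)))
    distortion_p <- (sum(abs(deltas) >= abs(delta_obs)) + 1) / (n_sim + 1)
  } else {
    corrected <- full
    distortion_p <- NA_real_
  }
  list(global_rss = rss_obs, global_p = global_p, outlier_p = outlier_p,
       outliers = ids[flagged], distortion_p = distortion_p,
       corrected = corrected, n_sim = n_sim, seed = seed)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the causal effect k times, each omitting one variant, plus
#' the all-variant estimate for reference.
#'
#' @param h a \code{HarmonizedSet}.
#' @param estimator \code{"ivw"} (default), \code{"ivw_correlated"} or
#'   \code{"wald"}; LD-adjusted IVW is the natural choice when an LD matrix
#'   backs the headline estimate.
#' @param ld aligned \code{LDMatrix}, required for
#'   \code{"ivw_correlated"}.
#' @return list with \code{perVariant} (data.frame: dropped id, beta, se,
#'   ci bounds, p) and \code{full} (\code{MREstimate}).
#' @export
leaveOneOut <- function(h, estimator = c("ivw", "ivw_correlated", "wald"),
                        ld = NULL) {
  estimator <- match.arg(estimator)
  if (estimator == "ivw_correlated" && is.null(ld))
    stopf("ivw_correlated needs an LD matrix")
  k <- nVariants(h)
  ids <- variantIds(h)
  fit <- function(hh, ldd) switch(estimator,
    ivw = mrIVW(hh),
    ivw_correlated = mrIVWCorrelated(hh, ldd),
    wald = mrWaldRatio(hh))
  subsetH <- function(keepIdx)
    harmonizedSet(ids[keepIdx], exposureBeta(h)[keepIdx],
                  exposureSE(h)[keepIdx], outcomeBeta(h)[keepIdx],
                  outcomeSE(h)[keepIdx])
  full <- fit(h, ld)
  rows <- lapply(seq_len(k), function(i) {
    keepIdx <- setdiff(seq_len(k), i)
    ldd <- if (is.null(ld)) NULL else alignLD(ld, ids[keepIdx])
    e <- fit(subsetH(keepIdx), ldd)
    data.frame(dropped = ids[i], beta = causalEstimate(e), se = causalSE(e),
               ci_low = confidenceInterval(e)["low"],
               ci_high = confidenceInterval(e)["high"],
               pvalue = causalP(e), stringsAsFactors = FALSE)
  })
  perVariant <- do.call(rbind, rows)
  rownames(perVariant) <- NULL
  list(perVariant = perVariant, full = full)
}
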