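## Causal-effect estimators. All effects stay on the log-OR-per-SD scale;
## odds ratios appear only at reporting (orCiFromBeta).

newMREstimate <- function(method, beta, se, k,
                          intercept = NA_real_, interceptSE = NA_real_,
                          interceptP = NA_real_, pvalue = NULL) {
  beta <- unname(beta); se <- unname(se)
  intercept <- unname(intercept); interceptSE <- unname(interceptSE)
  interceptP <- unname(interceptP)
  if (is.null(pvalue)) pvalue <- zPvalue(beta, se)
  pvalue <- unname(pvalue)
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - Z95 * se, ciHigh = beta + Z95 * se,
      pvalue = pvalue, kUsed = as.integer(k),
      intercept = intercept, interceptSE = interceptSE,
      interceptP = interceptP)
}

.checkK <- function(h, kmin, what) {
  if (nVariants(h) < kmin)
    stopf("%s needs at least %d variants (got %d)", what, kmin, nVariants(h))
}

#' Wald ratio estimate (one or two variants)
#'
#' Per-variant ratio by/bx with first-order SE sy/|bx|; with two variants,
#' the fixed-effect inverse-variance average of the two ratios.
#'
#' @param h a \code{HarmonizedSet} with 1 or 2 variants.
#' @return an \code{\link{MREstimate}} with method \code{WALD}.
#' @export
mrWaldRatio <- function(h) {
  k <- nVariants(h)
  if (k < 1 || k > 2) stopf("Wald ratio applies to 1 or 2 variants (got %d)", k)
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  if (any(bx == 0)) stopf("degenerate instrument: exposure beta is zero")
  ratio <- by / bx
  se <- sy / abs(bx)
  if (k == 1L) return(newMREstimate("WALD", ratio, se, 1L))
  w <- 1 / se^2
  newMREstimate("WALD", sum(w * ratio) / sum(w), sqrt(1 / sum(w)), 2L)
}

## Multiplicative random-effects inflation, floored at 1 so heterogeneity
## never deflates the SE.
.mreFactor <- function(q, df) sqrt(max(1, q / df))

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome on exposure betas through the origin with
#' weights 1/sy^2. The multiplicative random-effects model inflates the
#' fixed-effect SE by sqrt(max(1, Q/(k-1))) with Q Cochran's heterogeneity
#' statistic about the estimate. With fewer than three variants the Wald
#' ratio is used.
#'
#' @param h a \code{HarmonizedSet}.
#' @param model \code{"multiplicative_random"} (default) or \code{"fixed"}.
#' @return an \code{\link{MREstimate}}.
#' @export
mrIVW <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  k <- nVariants(h)
  if (k < 3L) return(mrWaldRatio(h))
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  if (all(bx == 0)) stopf("degenerate instrument: all exposure betas zero")
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  if (model == "multiplicative_random") {
    q <- sum((bx / sy)^2 * (by / bx - beta)^2)
    se <- se * .mreFactor(q, k - 1)
    return(newMREstimate("IVW_MRE", beta, se, k))
  }
  newMREstimate("IVW_FE", beta, se, k)
}

## Cholesky of the outcome covariance Omega = diag(sy) rho diag(sy),
## optionally ridge-regularized on rho.
.omegaChol <- function(sy, rho, ridge) {
  if (ridge) rho <- rho + diag(1e-6, nrow(rho))
  omega <- outer(sy, sy) * rho
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch))
    stopf(paste0("LD-adjusted covariance is not positive definite; ",
                 "inspect the LD matrix or set ridge = TRUE"))
  ch
}

#' IVW estimate under correlated variants (LD correction)
#'
#' Generalized weighted least squares through the origin with outcome
#' covariance Omega = diag(sy) rho diag(sy), rho the signed LD correlation
#' matrix aligned to the harmonized set:
#' beta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by. The multiplicative
#' random-effects model inflates the SE with the GLS analogue of Cochran's Q.
#'
#' @param h a \code{HarmonizedSet}.
#' @param ld an \code{LDMatrix} aligned to \code{h} (see \code{\link{alignLD}}).
#' @param model as in \code{\link{mrIVW}}.
#' @param ridge add 1e-6 to the LD diagonal when rho is numerically singular;
#'   off by default so data problems surface.
#' @return an \code{\link{MREstimate}} with method \code{IVW_CORR}.
#' @export
mrIVWCorrelated <- function(h, ld,
                            model = c("multiplicative_random", "fixed"),
                            ridge = FALSE) {
  model <- match.arg(model)
  k <- nVariants(h)
  .checkK(h, 1L, "LD-adjusted IVW")
  if (!identical(variantIds(h), variantIds(ld)))
    stopf("LD matrix is not aligned to the harmonized set; use alignLD()")
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  if (all(bx == 0)) stopf("degenerate instrument: all exposure betas zero")
  ch <- .omegaChol(sy, ld@rho, ridge)
  xs <- backsolve(ch, bx, transpose = TRUE)   # L^-1 bx with Omega = L'L
  ys <- backsolve(ch, by, transpose = TRUE)
  xtx <- sum(xs^2)
  beta <- sum(xs * ys) / xtx
  se <- sqrt(1 / xtx)
  if (model == "multiplicative_random" && k >= 2) {
    q <- sum((ys - beta * xs)^2)
    se <- se * .mreFactor(q, k - 1)
  }
  newMREstimate("IVW_CORR", beta, se, k)
}

## Shared WLS/GLS fit of by on [1, bx] after orienting bx >= 0 (joint sign
## flips of bx, by and, when LD is supplied, of the corresponding LD rows).
.eggerFit <- function(h, ld = NULL, ridge = FALSE) {
  k <- nVariants(h)
  bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
  s <- ifelse(bx < 0, -1, 1)
  bx <- s * bx; by <- s * by
  if (stats::var(bx) == 0)
    stopf("exposure betas are constant after orientation; Egger fit undefined")
  if (is.null(ld)) {
    ch <- diag(sy, nrow = k)      # chol of diag(sy^2)
  } else {
    if (!identical(variantIds(h), variantIds(ld)))
      stopf("LD matrix is not aligned to the harmonized set; use alignLD()")
    rho <- outer(s, s) * ld@rho
    ch <- .omegaChol(sy, rho, ridge)
  }
  X <- cbind(intercept = 1, slope = bx)
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, by, transpose = TRUE)
  XtX <- crossprod(Xs)
  coef <- drop(solve(XtX, crossprod(Xs, ys)))
  names(coef) <- colnames(X)
  resid <- ys - Xs %*% coef
  phi <- max(1, sum(resid^2) / (k - 2))
  covb <- solve(XtX) * phi
  se <- sqrt(diag(covb))
  names(se) <- colnames(X)
  list(coef = coef, se = se, k = k, q = sum(resid^2), df = k - 2)
}

#' MR-Egger regression
#'
#' Weighted (or, with an LD matrix, generalized least squares) regression of
#' outcome on exposure betas with an intercept, each variant oriented so its
#' exposure beta is non-negative. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy. SEs carry the
#' multiplicative random-effects inflation floored at 1.
#'
#' @param h a \code{HarmonizedSet} with at least 3 variants.
#' @param ld optional aligned \code{LDMatrix}.
#' @param ridge as in \code{\link{mrIVWCorrelated}}.
#' @return an \code{\link{MREstimate}} with method \code{EGGER} and intercept
#'   fields set.
#' @export
mrEgger <- function(h, ld = NULL, ridge = FALSE) {
  .checkK(h, 3L, "MR-Egger")
  fit <- .eggerFit(h, ld, ridge)
  newMREstimate("EGGER", fit$coef["slope"], fit$se["slope"], fit$k,
                intercept = unname(fit$coef["intercept"]),
                interceptSE = unname(fit$se["intercept"]),
                interceptP = zPvalue(fit$coef["intercept"],
                                     fit$se["intercept"]))
}

## Weighted 50th percentile by the cumulative-weight interpolation
## p_i = (sum_{j<=i} w_j) - w_i / 2 on ordered ratios.
.weightedMedian <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  n <- length(r)
  if (0.5 >= p[n]) return(r[n])
  j <- max(which(p < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

.ratioWeights <- function(bx, sy) (bx / sy)^2

#' Weighted median estimate
#'
#' Weighted 50th percentile of the per-variant ratios with inverse-variance
#' weights (bx/sy)^2; SE from a parametric bootstrap resampling bx and by
#' from their sampling distributions.
#'
#' @param h a \code{HarmonizedSet} with at least 3 variants.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed (mandatory: bootstrap SEs must be reproducible).
#' @return an \code{\link{MREstimate}} with method \code{WMEDIAN}.
#' @export
mrWeightedMedian <- function(h, n_boot = 1000, seed) {
  .checkK(h, 3L, "weighted median")
  bx <- exposureBeta(h); sx <- exposureSE(h)
  by <- outcomeBeta(h); sy <- outcomeSE(h)
  est <- .weightedMedian(by / bx, .ratioWeights(bx, sy))
  boots <- withSeed(seed, vapply(seq_len(n_boot), function(b) {
    bxs <- stats::rnorm(length(bx), bx, sx)
    bys <- stats::rnorm(length(by), by, sy)
    .weightedMedian(bys / bxs, .ratioWeights(bxs, sy))
  }, numeric(1)))
  newMREstimate("WMEDIAN", est, stats::sd(boots), nVariants(h))
}

## Modified Silverman bandwidth on the ratio scale; 0 when ratios identical.
.modeBandwidth <- function(ratios, factor) {
  s <- stats::sd(ratios)
  m <- stats::mad(ratios)
  spread <- if (m > 0) min(s, m) else s
  factor * 0.9 * spread * length(ratios)^(-1 / 5)
}

.weightedModeEstimate <- function(ratios, w, bw) {
  w <- w / sum(w)
  f <- function(x) vapply(x, function(xi)
    sum(w * stats::dnorm(xi, ratios, bw)), numeric(1))
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, length.out = 512)
  dens <- f(grid)
  i <- which.max(dens)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  stats::optimize(f, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode estimate
#'
#' Maximizer of a Gaussian-kernel weighted density of the per-variant ratios,
#' weights as in \code{\link{mrWeightedMedian}} and bandwidth a
#' modified-Silverman rule scaled by \code{bandwidth_factor}; SE by
#' parametric bootstrap. When all ratios coincide (zero bandwidth) the common
#' ratio is returned with the bootstrap SE.
#'
#' @inheritParams mrWeightedMedian
#' @param bandwidth_factor multiplier on the bandwidth rule, default 1.
#' @return an \code{\link{MREstimate}} with method \code{WMODE}.
#' @export
mrWeightedMode <- function(h, bandwidth_factor = 1.0, n_boot = 1000, seed) {
  .checkK(h, 3L, "weighted mode")
  bx <- exposureBeta(h); sx <- exposureSE(h)
  by <- outcomeBeta(h); sy <- outcomeSE(h)
  one <- function(bx_, by_) {
    r <- by_ / bx_
    bw <- .modeBandwidth(r, bandwidth_factor)
    if (bw <= 0) return(r[1])
    .weightedModeEstimate(r, .ratioWeights(bx_, sy), bw)
  }
  est <- one(bx, by)
  boots <- withSeed(seed, vapply(seq_len(n_boot), function(b)
    one(stats::rnorm(length(bx), bx, sx), stats::rnorm(length(by), by, sy)),
    numeric(1)))
  newMREstimate("WMODE", est, stats::sd(boots), nVariants(h))
}

#' Multivariable MR
#'
#' Weighted multiple regression of the outcome betas on the matrix of
#' exposure betas without intercept, weights 1/sy^2; returns each exposure's
#' conditional estimate. SEs carry the multiplicative random-effects
#' inflation floored at 1.
#'
#' @param h_list named list of \code{HarmonizedSet}s, one per exposure, on a
#'   shared variant set with identical outcome columns.
#' @return named list of \code{\link{MREstimate}}s (method \code{MVMR}).
#' @export
mrMVMR <- function(h_list) {
  p <- length(h_list)
  if (p < 2L) stopf("multivariable MR needs at least 2 exposures")
  ids <- variantIds(h_list[[1]])
  for (h in h_list[-1])
    if (!identical(variantIds(h), ids))
      stopf("exposures must share one variant set in the same order")
  k <- length(ids)
  if (k < p + 1L) stopf("need at least %d shared variants for %d exposures",
                        p + 1L, p)
  by <- outcomeBeta(h_list[[1]]); sy <- outcomeSE(h_list[[1]])
  X <- vapply(h_list, exposureBeta, numeric(k))
  nm <- names(h_list) %||% paste0("exposure", seq_len(p))
  ## exposures with no genetic signal at these variants contribute nothing to
  ## the fit; drop them (NA estimate) rather than fail on a zero column
  active <- colSums(X != 0) > 0
  Xa <- X[, active, drop = FALSE]
  pa <- ncol(Xa)
  sw <- 1 / sy
  Xs <- Xa * sw; ys <- by * sw
  qr_ <- qr(Xs)
  if (qr_$rank < pa) {
    dropped <- setdiff(seq_len(pa), qr_$pivot[seq_len(qr_$rank)])
    stopf("collinear exposure(s): %s",
          paste(nm[active][dropped], collapse = ", "))
  }
  XtX <- crossprod(Xs)
  coef <- drop(solve(XtX, crossprod(Xs, ys)))
  resid <- ys - Xs %*% coef
  phi <- max(1, sum(resid^2) / (k - pa))
  ses <- sqrt(diag(solve(XtX)) * phi)
  out <- vector("list", p)
  ia <- 0L
  for (j in seq_len(p)) {
    if (active[j]) {
      ia <- ia + 1L
      out[[j]] <- newMREstimate("MVMR", coef[ia], ses[ia], k)
    } else {
      out[[j]] <- newMREstimate("MVMR", NA_real_, NA_real_, k,
                                pvalue = NA_real_)
    }
  }
  stats::setNames(out, nm)
}

#' Pre-whiten a harmonized set by the Cholesky inverse of its LD matrix
#'
#' Transforms bx and by by L^-1 where diag(sy) rho diag(sy) = L' L, so that
#' the transformed outcome errors are independent with unit SE. Intended for
#' running the weighted median/mode estimators on correlated variants; off
#' the default analysis path.
#'
#' @param h a \code{HarmonizedSet}.
#' @param ld an aligned \code{LDMatrix}.
#' @return a transformed \code{HarmonizedSet} (sy all 1; sx propagated
#'   through the transform).
#' @export
prewhitenSet <- function(h, ld) {
  if (!identical(variantIds(h), variantIds(ld)))
    stopf("LD matrix is not aligned to the harmonized set; use alignLD()")
  sy <- outcomeSE(h); sx <- exposureSE(h)
  ch <- .omegaChol(sy, ld@rho, ridge = FALSE)
  Linv <- backsolve(ch, diag(nVariants(h)), transpose = TRUE)
  covx <- Linv %*% (outer(sx, sx) * ld@rho) %*% t(Linv)
  harmonizedSet(variantIds(h),
                drop(Linv %*% exposureBeta(h)), sqrt(diag(covx)),
                drop(Linv %*% outcomeBeta(h)), rep(1, nVariants(h)),
                dropLog(h))
}
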