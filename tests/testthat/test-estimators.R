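test_that("Wald ratio matches hand computation and pools two variants", {
  h <- harmonizedSet("rs1", 0.1, 0.005, 0.05, 0.01)
  e <- mrWaldRatio(h)
  expect_equal(causalEstimate(e), 0.5)
  expect_equal(causalSE(e), 0.1)
  ## null outcome effect
  e0 <- mrWaldRatio(harmonizedSet("rs1", 0.1, 0.005, 0, 0.01))
  expect_equal(causalEstimate(e0), 0)
  ## two variants with equal ratios and equal ratio SEs: same ratio,
  ## SE reduced by sqrt(2)
  h2 <- harmonizedSet(c("a", "b"), c(0.1, 0.1), c(0.005, 0.005),
                      c(0.05, 0.05), c(0.01, 0.01))
  e2 <- mrWaldRatio(h2)
  expect_equal(causalEstimate(e2), 0.5)
  expect_equal(causalSE(e2), 0.1 / sqrt(2))
  expect_error(mrWaldRatio(harmonizedSet("rs1", 0, 0.005, 0.01, 0.01)),
               "degenerate")
})

test_that("IVW recovers exact proportionality and delegates below k = 3", {
  h <- harmonizedSet(c("a", "b", "c"), c(0.1, 0.2, 0.3), rep(0.005, 3),
                     c(0.05, 0.10, 0.15), rep(0.01, 3))
  fe <- mrIVW(h, model = "fixed")
  mre <- mrIVW(h)
  expect_equal(causalEstimate(fe), 0.5)
  expect_equal(causalEstimate(mre), 0.5)
  ## homogeneous data: Q = 0, both models give the same SE
  expect_equal(causalSE(fe), causalSE(mre))
  expect_equal(mrMethod(mre), "IVW_MRE")
  ## k < 3 delegates to the Wald ratio
  h1 <- harmonizedSet("a", 0.1, 0.005, 0.05, 0.01)
  expect_equal(causalEstimate(mrIVW(h1)), causalEstimate(mrWaldRatio(h1)))
  expect_equal(mrMethod(mrIVW(h1)), "WALD")
})

test_that("IVW and Egger match independent WLS oracles on random sets", {
  for (seed in 1:15) {
    k <- sample(3:6, 1)
    h <- randomSet(k, seed)
    bx <- exposureBeta(h); by <- outcomeBeta(h); sy <- outcomeSE(h)
    ## IVW: weighted regression through the origin
    o <- wlsOracle(matrix(bx), by, 1 / sy^2)
    fe <- mrIVW(h, model = "fixed")
    expect_equal(causalEstimate(fe), o$coef, tolerance = 1e-10)
    mre <- mrIVW(h)
    q <- sum((bx / sy)^2 * (by / bx - o$coef)^2)
    expect_equal(causalSE(mre),
                 sqrt(1 / sum(bx^2 / sy^2)) * sqrt(max(1, q / (k - 1))),
                 tolerance = 1e-10)
    ## Egger: weighted regression with intercept after bx >= 0 orientation
    s <- ifelse(bx < 0, -1, 1)
    oe <- wlsOracle(cbind(1, s * bx), s * by, 1 / sy^2)
    eg <- mrEgger(h)
    expect_equal(causalEstimate(eg), oe$coef[2], tolerance = 1e-10)
    expect_equal(unname(eggerIntercept(eg)["intercept"]), oe$coef[1],
                 tolerance = 1e-10)
    expect_equal(causalSE(eg), oe$se[2], tolerance = 1e-10)
  }
})

test_that("LD-adjusted IVW reduces to IVW, collapses duplicates, matches GLS", {
  h <- randomSet(5, 42)
  ldI <- ldMatrix(diag(5), variantIds(h))
  expect_equal(causalEstimate(mrIVWCorrelated(h, ldI)),
               causalEstimate(mrIVW(h)), tolerance = 1e-12)
  expect_equal(causalSE(mrIVWCorrelated(h, ldI)), causalSE(mrIVW(h)),
               tolerance = 1e-12)

  ## duplicating a variant at rho = 1 (ridge-regularized inversion) leaves
  ## the fixed-effect estimate of the original set unchanged
  ids <- c(variantIds(h), "dup")
  bx <- c(exposureBeta(h), exposureBeta(h)[5])
  sx <- c(exposureSE(h), exposureSE(h)[5])
  by <- c(outcomeBeta(h), outcomeBeta(h)[5])
  sy <- c(outcomeSE(h), outcomeSE(h)[5])
  rho6 <- diag(6); rho6[5, 6] <- rho6[6, 5] <- 1
  hdup <- harmonizedSet(ids, bx, sx, by, sy)
  expect_error(mrIVWCorrelated(hdup, ldMatrix(rho6, ids)), "ridge")
  edup <- mrIVWCorrelated(hdup, ldMatrix(rho6, ids), model = "fixed",
                          ridge = TRUE)
  e5 <- mrIVWCorrelated(h, ldI, model = "fixed")
  expect_equal(causalEstimate(edup), causalEstimate(e5), tolerance = 1e-4)

  ## random well-conditioned rho: explicit-inversion GLS oracle
  for (seed in 1:10) {
    k <- sample(3:5, 1)
    h2 <- randomSet(k, 200 + seed)
    rho <- randomRho(k, 300 + seed)
    sy2 <- outcomeSE(h2)
    omega <- outer(sy2, sy2) * rho
    o <- glsOracle(matrix(exposureBeta(h2)), outcomeBeta(h2), omega)
    fe <- mrIVWCorrelated(h2, ldMatrix(rho, variantIds(h2)), model = "fixed")
    expect_equal(causalEstimate(fe), o$coef, tolerance = 1e-8)
    expect_equal(causalSE(fe), o$se_fixed, tolerance = 1e-8)
    mre <- mrIVWCorrelated(h2, ldMatrix(rho, variantIds(h2)))
    expect_equal(causalSE(mre), o$se, tolerance = 1e-8)
  }
})

test_that("Egger recovers noiseless slopes, offsets, and sign invariance", {
  bx <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  h <- harmonizedSet(paste0("rs", 1:5), bx, rep(0.005, 5), 0.3 * bx,
                     rep(0.01, 5))
  e <- mrEgger(h)
  expect_equal(causalEstimate(e), 0.3, tolerance = 1e-12)
  expect_equal(unname(eggerIntercept(e)["intercept"]), 0, tolerance = 1e-12)
  ## constant directional pleiotropy moves the intercept, not the slope
  h2 <- harmonizedSet(paste0("rs", 1:5), bx, rep(0.005, 5),
                      0.3 * bx + 0.05, rep(0.01, 5))
  e2 <- mrEgger(h2)
  expect_equal(causalEstimate(e2), 0.3, tolerance = 1e-12)
  expect_equal(unname(eggerIntercept(e2)["intercept"]), 0.05,
               tolerance = 1e-12)
  ## joint sign flips of (bx, by) do not change the fit
  h3 <- randomSet(5, 77)
  flip <- c(-1, 1, -1, 1, -1)
  h3f <- harmonizedSet(variantIds(h3), flip * exposureBeta(h3),
                       exposureSE(h3), flip * outcomeBeta(h3), outcomeSE(h3))
  expect_equal(causalEstimate(mrEgger(h3f)), causalEstimate(mrEgger(h3)),
               tolerance = 1e-12)
  expect_error(mrEgger(randomSet(2, 1)), "at least 3")
})

test_that("weighted median follows the interpolation rule and oracle", {
  ## equal weights, three ratios: plain median
  h <- harmonizedSet(paste0("rs", 1:3), c(0.1, 0.1, 0.1), rep(0.005, 3),
                     c(0.01, 0.05, 0.09), rep(0.01, 3))
  e <- mrWeightedMedian(h, n_boot = 200, seed = 1)
  expect_equal(causalEstimate(e), 0.5)
  ## random sets against the direct-definition oracle
  for (seed in 1:10) {
    h2 <- randomSet(sample(3:6, 1), 400 + seed)
    e2 <- mrWeightedMedian(h2, n_boot = 50, seed = 2)
    expect_equal(causalEstimate(e2),
                 weightedMedianOracle(outcomeBeta(h2) / exposureBeta(h2),
                                      (exposureBeta(h2) / outcomeSE(h2))^2),
                 tolerance = 1e-12)
  }
  ## a variant holding > 50% of the weight pins the estimate near its ratio
  h3 <- harmonizedSet(paste0("rs", 1:4), c(0.5, 0.05, 0.05, 0.05),
                      rep(0.005, 4), c(0.25, 0.01, 0.02, 0.03),
                      rep(0.01, 4))
  e3 <- mrWeightedMedian(h3, n_boot = 50, seed = 3)
  r <- sort(c(0.5, 0.2, 0.4, 0.6))
  expect_lt(abs(causalEstimate(e3) - 0.5), max(diff(r)))
  ## bootstrap SE reproducible bit-for-bit under a fixed seed
  a <- mrWeightedMedian(h3, n_boot = 100, seed = 9)
  b <- mrWeightedMedian(h3, n_boot = 100, seed = 9)
  expect_identical(causalSE(a), causalSE(b))
})

test_that("weighted mode finds the dominant cluster, not the mean", {
  ## identical ratios: the common ratio is returned
  h <- proportionalSet(rate = 0.4, k = 4)
  e <- mrWeightedMode(h, n_boot = 50, seed = 1)
  expect_equal(causalEstimate(e), 0.4)
  ## 60% of the weight near ratio 0.2, the rest at 1.0
  set.seed(5)
  r_lo <- rnorm(9, 0.2, 0.01); r_hi <- rnorm(6, 1.0, 0.01)
  bx <- rep(0.1, 15)
  h2 <- harmonizedSet(paste0("rs", 1:15), bx, rep(0.005, 15),
                      bx * c(r_lo, r_hi), rep(0.01, 15))
  e2 <- mrWeightedMode(h2, n_boot = 50, seed = 2)
  expect_lt(abs(causalEstimate(e2) - 0.2), 0.05)
  ## and matches a dense grid search of the weighted density
  ratios <- c(r_lo, r_hi)
  w <- (bx / rep(0.01, 15))^2
  bw <- 0.9 * min(sd(ratios), mad(ratios)) * 15^(-1 / 5)
  expect_equal(causalEstimate(e2), modeGridOracle(ratios, w, bw),
               tolerance = 1e-3)
  ## determinism under fixed seed
  expect_identical(causalSE(mrWeightedMode(h2, n_boot = 80, seed = 4)),
                   causalSE(mrWeightedMode(h2, n_boot = 80, seed = 4)))
})

test_that("multivariable MR reduces, recovers truth, and matches its oracle", {
  ## an exposure with no signal leaves the other's estimate at univariable IVW
  h1 <- randomSet(8, 501)
  h0 <- harmonizedSet(variantIds(h1), rep(0, 8), exposureSE(h1),
                      outcomeBeta(h1), outcomeSE(h1))
  mv <- mrMVMR(list(x1 = h1, x2 = h0))
  expect_equal(causalEstimate(mv$x1), causalEstimate(mrIVW(h1, "fixed")),
               tolerance = 1e-12)
  expect_true(is.na(causalEstimate(mv$x2)))

  ## known conditional effects (0.4, -0.2) recovered within 2 SE
  set.seed(71)
  k <- 40
  g1 <- rnorm(k, 0, 0.05); g2 <- rnorm(k, 0, 0.05)
  sy <- rep(0.02, k)
  by <- 0.4 * g1 - 0.2 * g2 + rnorm(k, 0, sy)
  ha <- harmonizedSet(paste0("rs", 1:k), g1, rep(0.001, k), by, sy)
  hb <- harmonizedSet(paste0("rs", 1:k), g2, rep(0.001, k), by, sy)
  mv2 <- mrMVMR(list(a = ha, b = hb))
  expect_lt(abs(causalEstimate(mv2$a) - 0.4), 2 * causalSE(mv2$a))
  expect_lt(abs(causalEstimate(mv2$b) + 0.2), 2 * causalSE(mv2$b))

  ## small instances match the multiple-WLS normal-equations oracle
  o <- wlsOracle(cbind(g1, g2), by, 1 / sy^2)
  expect_equal(c(causalEstimate(mv2$a), causalEstimate(mv2$b)),
               unname(o$coef), tolerance = 1e-10)
  expect_equal(c(causalSE(mv2$a), causalSE(mv2$b)), unname(o$se),
               tolerance = 1e-10)

  ## collinear exposures are named
  expect_error(mrMVMR(list(p = ha, q = ha)), "collinear")
  expect_error(mrMVMR(list(one = ha)), "at least 2")
})

test_that("weighted median resists 40% large directional pleiotropy", {
  set.seed(99)
  k <- 30
  n_bad <- 12
  gamma <- runif(k, 0.03, 0.1)
  sx <- rep(0.002, k); sy <- rep(0.015, k)
  alpha <- c(rep(0.08, n_bad), rep(0, k - n_bad))
  bx <- gamma + rnorm(k, 0, sx)
  by <- 0.5 * gamma + alpha + rnorm(k, 0, sy)
  h <- harmonizedSet(paste0("rs", 1:k), bx, sx, by, sy)
  e <- mrWeightedMedian(h, n_boot = 500, seed = 12)
  expect_lt(abs(causalEstimate(e) - 0.5), 2 * causalSE(e))
})

test_that("pre-whitening makes correlated-variant IVW equal plain IVW", {
  h <- randomSet(5, 61)
  rho <- randomRho(5, 62)
  ld <- ldMatrix(rho, variantIds(h))
  hw <- prewhitenSet(h, ld)
  ## on the whitened scale, ordinary IVW reproduces the GLS estimate
  expect_equal(causalEstimate(mrIVW(hw, model = "fixed")),
               causalEstimate(mrIVWCorrelated(h, ld, model = "fixed")),
               tolerance = 1e-10)
})
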