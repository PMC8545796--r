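## Independent brute-force oracles. Deliberately written as literal
## transcriptions of the defining formulas, sharing no code with the package.

## Weighted least squares by explicit normal equations (X may include an
## intercept column).
wlsOracle <- function(X, y, w) {
  W <- diag(w, nrow = length(w))
  XtWX <- t(X) %*% W %*% X
  coef <- solve(XtWX) %*% t(X) %*% W %*% y
  resid <- y - X %*% coef
  df <- length(y) - ncol(X)
  phi <- max(1, drop(t(resid) %*% W %*% resid) / df)
  list(coef = drop(coef), se = sqrt(diag(solve(XtWX)) * phi))
}

## Generalized least squares by explicit inversion of Omega.
glsOracle <- function(X, y, omega) {
  Oi <- solve(omega)
  XtOX <- t(X) %*% Oi %*% X
  coef <- solve(XtOX) %*% t(X) %*% Oi %*% y
  resid <- y - X %*% coef
  df <- length(y) - ncol(X)
  q <- drop(t(resid) %*% Oi %*% resid)
  phi <- if (df > 0) max(1, q / df) else 1
  list(coef = drop(coef), se = sqrt(diag(solve(XtOX)) * phi),
       se_fixed = sqrt(diag(solve(XtOX))))
}

## Weighted 50th percentile by the interpolation definition.
weightedMedianOracle <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  n <- length(r)
  if (0.5 >= p[n]) return(r[n])
  for (j in seq_len(n - 1)) {
    if (p[j] < 0.5 && 0.5 <= p[j + 1]) {
      return(r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j]))
    }
  }
}

## Dense grid search over the weighted kernel density.
modeGridOracle <- function(ratios, w, bw, n_grid = 20000) {
  w <- w / sum(w)
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw,
              length.out = n_grid)
  dens <- sapply(grid, function(x) sum(w * dnorm(x, ratios, bw)))
  grid[which.max(dens)]
}

## BH step-up by its definition: sort ascending, adj_i = min_{j >= i}
## m p_(j) / j, cap at 1, return in input order.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## Greedy p-ranked clumping, re-implemented independently. r2 looked up from
## a signed correlation matrix with dimnames; missing pairs count as
## uncorrelated.
bruteClumpOracle <- function(cand, rho, r2_thr, dist_bp, rule) {
  cand <- cand[order(cand$pvalue, cand$position, cand$variant_id), ]
  retained <- character()
  pool <- cand
  while (nrow(pool) > 0) {
    top <- pool[1, ]
    retained <- c(retained, top$variant_id)
    keep <- rep(TRUE, nrow(pool))
    for (i in seq_len(nrow(pool))[-1]) {
      row <- pool[i, ]
      near <- identical(row$chromosome, top$chromosome) &&
        abs(row$position - top$position) <= dist_bp
      r2 <- NA_real_
      if (!is.null(rho) && top$variant_id %in% rownames(rho) &&
          row$variant_id %in% rownames(rho))
        r2 <- rho[top$variant_id, row$variant_id]^2
      corr <- !is.na(r2) && r2 > r2_thr
      drop_it <- if (rule == "and") near && corr else near || corr
      if (drop_it) keep[i] <- FALSE
    }
    pool <- pool[keep, ][-1, , drop = FALSE]
  }
  retained
}

## Power for a binary outcome via the closed normal form, written directly.
powerOracle <- function(n, K, r2, or_alt, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  d <- abs(log(or_alt)) * sqrt(n * r2 * K * (1 - K))
  pnorm(d - z) + pnorm(-d - z)
}
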