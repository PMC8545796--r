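## Shared in-code fixtures.

## A small exactly-proportional harmonized set (ratio = rate for every SNP).
proportionalSet <- function(rate = 0.5, k = 3) {
  bx <- seq(0.1, by = 0.1, length.out = k)
  harmonizedSet(paste0("rs", seq_len(k)), bx, rep(0.005, k),
                rate * bx, rep(0.01, k))
}

## Random harmonized set of size k for oracle-equivalence loops.
randomSet <- function(k, seed) {
  set.seed(seed)
  bx <- rnorm(k, 0.08, 0.04)
  bx[abs(bx) < 0.01] <- 0.02
  harmonizedSet(paste0("rs", seq_len(k)), bx, runif(k, 0.002, 0.01),
                0.4 * bx + rnorm(k, 0, 0.02), runif(k, 0.01, 0.05))
}

## Random well-conditioned signed correlation matrix.
randomRho <- function(k, seed, scale = 0.3) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  S <- crossprod(A) + diag(k) * k * (1 - scale)
  D <- diag(1 / sqrt(diag(S)))
  D %*% S %*% D
}

## Canonical sumstats row constructor.
ssRow <- function(id, ea, oa, beta, se = 0.01, eaf = 0.3, chr = "1",
                  pos = 1e6, p = 1e-10, n = 1e5) {
  data.frame(variant_id = id, chromosome = chr, position = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pvalue = p, n = n, stringsAsFactors = FALSE)
}
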