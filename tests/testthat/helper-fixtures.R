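## Shared fixtures (memoized: the planted co-expression fixture is reused
## by several files) and independent brute-force oracles.

.cache <- new.env(parent = emptyenv())

## Standard planted fixture at a given residual noise: simulated FPKM,
## TOM, detected partition, eigengenes and sample metadata.
plantedFixture <- function(noise = 0.5, seed = 7) {
  key <- sprintf("fx_%d_%g", seed, noise)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  cfg <- simConfig(seed = seed, factorNoiseSD = noise)
  sim <- simulateExpression(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
  fm <- SummarizedExperiment::assay(filterExpressed(sim$se), "fpkm")
  at <- adjacencyTom(fm, 14)
  part <- detectModules(at$tom)
  eig <- moduleEigengenes(fm, part)
  fx <- list(cfg = cfg, sim = sim, cd = cd, fm = fm, tom = at$tom,
             adjacency = at$adjacency, part = part, eig = eig,
             truth = moduleLabels(sim$partition)[rownames(fm)])
  .cache[[key]] <- fx
  fx
}

## Independent triple-loop evaluation of the TOM formula.
tomOracle <- function(a) {
  n <- nrow(a)
  a0 <- a; diag(a0) <- 0
  k <- rowSums(a0)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
    tom[i, j] <- (l + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j])
  }
  tom
}

## O(m^2) evaluation of the BH step-up definition.
bhOracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(vapply(cand, function(j) m * p[j] / sum(p <= p[j]), 1)))
  }, 1)
}

## Exact small-p-values binomial test (Poisson-conditional limit).
binomOracle <- function(s1, s, prob) {
  probs <- dbinom(0:s, s, prob)
  sum(probs[probs <= probs[s1 + 1] * (1 + 1e-8)])
}

## Straight-line TMM re-derivation: explicit sort-based double trim and
## inverse-variance weighting, coded independently of the package path.
tmmOracle <- function(m, ref) {
  lib <- colSums(m)
  f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    obs <- m[, s]; r <- m[, ref]
    keep <- obs > 0 & r > 0
    obs <- obs[keep]; r <- r[keep]
    M <- log2((obs / lib[s]) / (r / lib[ref]))
    A <- 0.5 * log2((obs / lib[s]) * (r / lib[ref]))
    w <- (lib[s] - obs) / (lib[s] * obs) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    okM <- rank(M) >= floor(0.3 * n) + 1 & rank(M) <= n - floor(0.3 * n)
    okA <- rank(A) >= floor(0.05 * n) + 1 & rank(A) <= n - floor(0.05 * n)
    sel <- okM & okA
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }, 1)
  f / exp(mean(log(f)))
}

## Columns with an exactly prescribed correlation structure: returns a
## matrix whose columns are centered, unit-norm and mutually orthogonal.
orthoBasis <- function(n, k, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (k + 1)), n, k + 1)
  X <- sweep(X, 2, colMeans(X))
  Q <- qr.Q(qr(X))[, seq_len(k), drop = FALSE]
  Q <- sweep(Q, 2, colMeans(Q))          # re-center (qr can shift)
  sweep(Q, 2, sqrt(colSums(Q^2)), "/")
}
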