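## Internal helpers shared across modules.

## Derive an independent sub-seed for one output table from a master seed,
## so adding a table never perturbs the draws of another.
.streamSeed <- function(seed, stream) {
  (as.integer(seed) * 97L + as.integer(stream) * 1009L) %% 2147483647L
}

.withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(.streamSeed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

## Accept a SummarizedExperiment (named assay) or a plain matrix.
.asMatrix <- function(x, assayName = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!is.null(assayName) &&
        assayName %in% SummarizedExperiment::assayNames(x))
      return(as.matrix(SummarizedExperiment::assay(x, assayName)))
    return(as.matrix(SummarizedExperiment::assay(x)))
  }
  if (is.data.frame(x)) return(as.matrix(x))
  if (!is.matrix(x)) stop("expected a matrix or SummarizedExperiment")
  x
}

## Adjusted Rand index between two label vectors (Hubert & Arabie form).
.adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

## Truncated-at-zero normal draws (resampling; calibration bias negligible
## when mean is several SDs above zero, as for all Table-1-scale traits).
.rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad)) x[bad] <- mean * 1e-3
  x
}

## Two-sided p for a Pearson correlation via the t transform.
.corP <- function(r, n) {
  df <- n - 2
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(t, df, lower.tail = FALSE)
}
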