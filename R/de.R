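## Negative-binomial differential expression in the classic exact-test
## style: TMM normalization factors, pseudo-count equalization to a common
## effective library, a conditioned NB exact test with a method-of-moments
## common dispersion, BH adjustment, threshold DEG calling, cross-contrast
## intersections and the WGCNA-intersect-DEG core-gene screen.

#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample: per gene,
#' M = log2 relative abundance ratio and A = average log abundance;
#' genes with zero count in either sample are removed, the 30\% most
#' extreme M and 5\% most extreme A values are trimmed (each tail), and
#' the remaining M values are averaged with inverse-asymptotic-variance
#' weights.  Factors are rescaled so their geometric mean is 1.
#'
#' @param counts integer matrix (genes x samples) or SummarizedExperiment
#'   with a \code{"counts"} assay.
#' @param reference column name/index of the reference sample, or
#'   \code{"auto"}: the sample whose upper-quartile relative abundance is
#'   closest to the mean of all samples.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @examples
#' m <- matrix(rpois(40, 50), 20, 2,
#'             dimnames = list(paste0("g", 1:20), c("a", "b")))
#' tmmFactors(cbind(m, b2 = m[, 2] * 2L))
#' @export
tmmFactors <- function(counts, reference = "auto") {
  m <- .asMatrix(counts, "counts")
  if (ncol(m) < 2) stop("need >= 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(m)[lib == 0], collapse = ", "))
  if (identical(reference, "auto")) {
    q75 <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(q75 - mean(q75)))
  } else {
    ref <- if (is.character(reference)) match(reference, colnames(m))
           else as.integer(reference)
    if (is.na(ref) || ref < 1 || ref > ncol(m))
      stop("unknown reference sample")
  }
  f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    .tmmPair(m[, s], m[, ref], lib[s], lib[ref])
  }, 1)
  f / exp(mean(log(f)))
}

## One TMM factor: sample `obs` vs reference, doubly trimmed weighted mean.
.tmmPair <- function(obs, ref, nO, nR, logratioTrim = 0.3, sumTrim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("sample shares no expressed genes with the reference")
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1)     # pure depth difference
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM &
    rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

## Method-of-moments common dispersion pooled across genes, computed on
## library-equalized pseudo counts: phi solves var = mu + phi mu^2 with
## within-group means and pooled within-group variances.
.commonDispersion <- function(pseudo, group, floor = 1e-4) {
  g <- unique(group)
  num <- 0; den <- 0
  for (gg in g) {
    sub <- pseudo[, group == gg, drop = FALSE]
    n <- ncol(sub)
    if (n < 2) next
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    num <- num + sum((n - 1) * (v - mu))
    den <- den + sum((n - 1) * mu^2)
  }
  if (den <= 0) return(floor)
  max(num / den, floor)
}

## Conditional NB exact p for one gene: group sums (s1, s2) given the
## total, both groups NB with common dispersion phi; p = total probability
## of outcomes as or more extreme (no more probable) than the observed.
.nbExactP <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  size1 <- n1 / phi; size2 <- n2 / phi
  mu1 <- s * n1 / (n1 + n2); mu2 <- s * n2 / (n1 + n2)
  norm <- dnbinom(s, size = size1 + size2, mu = mu1 + mu2)
  if (!is.finite(norm) || norm <= 0) return(1)
  if (s <= 20000) {
    kr <- 0:s
  } else {
    lo <- stats::qnbinom(1e-14, size = size1, mu = mu1)
    hi <- stats::qnbinom(1e-14, size = size1, mu = mu1,
                         lower.tail = FALSE)
    kr <- max(0, lo):min(s, hi)
    if (!(s1 %in% kr)) kr <- sort(unique(c(kr, s1)))
  }
  probs <- dnbinom(kr, size = size1, mu = mu1) *
    dnbinom(s - kr, size = size2, mu = mu2) / norm
  pobs <- probs[match(s1, kr)]
  p <- sum(probs[probs <= pobs * (1 + 1e-8)])
  p <- p + max(0, 1 - sum(probs))       # untabulated tail mass is extreme
  min(p, 1)
}

#' Negative-binomial exact test between two groups
#'
#' Counts are scaled to a common effective library (TMM-adjusted
#' pseudo-counts); per gene, the rounded group sums are tested by
#' conditioning on their total under a common-dispersion NB model, summing
#' the probabilities of all outcomes no more probable than the observed
#' one.  Log2 fold changes come from the normalized group means with a
#' prior count for stability at zeros.
#'
#' @param counts integer matrix or SummarizedExperiment (assay
#'   \code{"counts"}).
#' @param group character/factor of length n samples with exactly two
#'   levels; the FIRST level in order of appearance is the reference, and
#'   log2fc is second vs first.
#' @param dispersion \code{"auto"} (pooled method-of-moments common
#'   dispersion, floored at 1e-4) or a positive number.
#' @param priorCount prior added to each group mean for log2fc
#'   (default 0.125).
#' @return data.frame: gene, log2fc, p, fdr (BH), mean_expression
#'   (counts-per-million scale).
#' @examples
#' sim <- simulateCounts(simConfig(seed = 1, nGenes = 100,
#'                                 deFraction = 0.1),
#'                       nPerGroup = c(4, 4))
#' res <- nbExactTest(sim$se, SummarizedExperiment::colData(sim$se)$group)
#' head(res)
#' @export
nbExactTest <- function(counts, group, dispersion = "auto",
                        priorCount = 0.125) {
  m <- .asMatrix(counts, "counts")
  group <- as.character(group)
  if (length(group) != ncol(m)) stop("one group label per sample required")
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly 2 groups required")
  n1 <- sum(group == lev[1]); n2 <- sum(group == lev[2])
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop("group with all-zero library")
  eff <- lib * tmmFactors(m)
  common <- exp(mean(log(eff)))
  pseudo <- sweep(m, 2, common / eff, "*")
  phi <- if (identical(dispersion, "auto"))
    .commonDispersion(pseudo, group) else {
      if (!is.numeric(dispersion) || dispersion <= 0)
        stop("dispersion must be positive or 'auto'")
      dispersion
    }
  i1 <- group == lev[1]; i2 <- group == lev[2]
  s1 <- round(rowSums(pseudo[, i1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, i2, drop = FALSE]))
  p <- vapply(seq_len(nrow(m)), function(g)
    .nbExactP(s1[g], s2[g], n1, n2, phi), 1)
  m1 <- rowMeans(pseudo[, i1, drop = FALSE])
  m2 <- rowMeans(pseudo[, i2, drop = FALSE])
  log2fc <- log2((m2 + priorCount) / (m1 + priorCount))
  data.frame(gene = rownames(m), log2fc = log2fc, p = p,
             fdr = bhAdjust(p),
             mean_expression = (m1 * n1 + m2 * n2) / (n1 + n2) /
               common * 1e6,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps \code{stats::p.adjust(method = "BH")});
#' order-preserving against the input order.
#'
#' @param p p-values in [0,1].
#' @return adjusted values in [0,1], monotone in p-rank.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds: up = log2fc > lfcThreshold and fdr < fdrThreshold;
#' down = log2fc < -lfcThreshold and fdr < fdrThreshold.
#'
#' @param results data.frame from \code{\link{nbExactTest}}.
#' @param lfcThreshold log2 fold-change threshold (default 1, strict).
#' @param fdrThreshold FDR threshold (default 0.05, strict).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
callDegs <- function(results, lfcThreshold = 1, fdrThreshold = 0.05) {
  stopifnot(all(c("gene", "log2fc", "fdr") %in% colnames(results)))
  list(up = results$gene[results$log2fc > lfcThreshold &
                           results$fdr < fdrThreshold],
       down = results$gene[results$log2fc < -lfcThreshold &
                             results$fdr < fdrThreshold])
}

#' Common DEGs across contrasts
#'
#' Per-direction set intersection across all contrasts (all contrasts must
#' share the same reference-group orientation).
#'
#' @param degList list of per-contrast results from \code{\link{callDegs}}
#'   (each a list with \code{up} and \code{down}).
#' @return list with \code{common_up} and \code{common_down}.
#' @examples
#' commonDegs(list(list(up = c("a", "b", "c"), down = "z"),
#'                 list(up = c("b", "c"), down = "z")))
#' @export
commonDegs <- function(degList) {
  if (length(degList) < 2) stop("need >= 2 contrasts")
  ok <- vapply(degList, function(d)
    is.list(d) && all(c("up", "down") %in% names(d)), TRUE)
  if (!all(ok))
    stop("every contrast needs 'up' and 'down' sets ",
         "(mismatched direction conventions?)")
  list(common_up = sort(Reduce(intersect, lapply(degList, `[[`, "up"))),
       common_down = sort(Reduce(intersect,
                                 lapply(degList, `[[`, "down"))))
}

#' Core-gene screen: WGCNA hubs intersected with common DEGs
#'
#' core = hub AND (common_up OR common_down).  The provenance table
#' records, per core gene, the module / kME / GS (when a hub table is
#' given) and the DEG direction.
#'
#' @param hub hub genes: either the data.frame from
#'   \code{\link{hubGeneScreen}} (rows with \code{hub == TRUE} are used)
#'   or a character vector of gene ids.
#' @param commonUp,commonDown character vectors from
#'   \code{\link{commonDegs}}.
#' @return A \linkS4class{ScreeningResult} with sets \code{hub},
#'   \code{common_up}, \code{common_down}, \code{core}.
#' @examples
#' geneSets(coreGeneScreen(c("a", "b", "c"), "b", c("c", "d")))$core
#' @export
coreGeneScreen <- function(hub, commonUp, commonDown) {
  hubTab <- NULL
  if (is.data.frame(hub)) {
    hubTab <- hub
    hub <- hub$gene[hub$hub]
  }
  hub <- as.character(hub)
  deg <- union(commonUp, commonDown)
  core <- sort(intersect(hub, deg))
  if (length(hub) && length(deg) && !length(core))
    warning("hub set and DEG sets share no gene ids")
  prov <- data.frame(gene = core,
                     direction = ifelse(core %in% commonUp, "up", "down"),
                     stringsAsFactors = FALSE)
  if (!is.null(hubTab) && nrow(prov)) {
    idx <- match(core, hubTab$gene)
    prov$module <- hubTab$module[idx]
    prov$kME <- hubTab$kME[idx]
    prov$GS <- hubTab$GS[idx]
  }
  new("ScreeningResult",
      sets = list(hub = sort(hub), common_up = sort(commonUp),
                  common_down = sort(commonDown), core = core),
      provenance = prov)
}
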