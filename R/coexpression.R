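## Weighted co-expression analysis, implemented from first principles:
## expression filtering, soft-threshold diagnostics, unsigned adjacency and
## topological overlap, average-linkage module detection with a static
## height cut, module eigengenes, dual-depth salinity screening of modules,
## and kME/GS hub-gene screening.

#' Filter expressed genes
#'
#' Removes genes whose FPKM is below \code{floor} in every sample (a gene
#' is kept as soon as one sample reaches the floor).  The sample set is
#' preserved.
#'
#' @param x FPKM matrix (genes x samples) or SummarizedExperiment with an
#'   \code{"fpkm"} assay.
#' @param floor FPKM floor (default 20).
#' @return filtered object of the same class as the input.
#' @examples
#' m <- rbind(low = rep(5, 4), hi = c(0, 0, 25, 0))
#' colnames(m) <- paste0("s", 1:4)
#' rownames(filterExpressed(m, 20))  # "hi"
#' @export
filterExpressed <- function(x, floor = 20) {
  if (floor < 0) stop("floor must be >= 0")
  m <- .asMatrix(x, "fpkm")
  keep <- apply(m, 1, max) >= floor
  if (!any(keep)) stop("no genes reach FPKM >= ", floor, " in any sample")
  if (methods::is(x, "SummarizedExperiment")) x[keep, ] else
    m[keep, , drop = FALSE]
}

.absCor <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene profile(s), correlation undefined: ",
         paste(head(rownames(m)[sds == 0], 5), collapse = ", "))
  abs(cor(t(m)))
}

#' Soft-threshold diagnostics
#'
#' For each candidate power beta: unsigned adjacency |r|^beta, per-gene
#' connectivity k, the scale-free topology fit R^2 (log-log regression of
#' binned connectivity frequency on connectivity) and the mean
#' connectivity.
#'
#' @param x FPKM matrix or SummarizedExperiment (>= 4 samples).
#' @param powers candidate powers (default 1..10, 12, 14, 16).
#' @param nBins connectivity histogram bins for the fit (default 10).
#' @return data.frame with columns power, fitR2, meanK.
#' @export
softThresholdDiagnostic <- function(x, powers = c(1:10, 12L, 14L, 16L),
                                    nBins = 10L) {
  m <- .asMatrix(x, "fpkm")
  if (ncol(m) < 4) stop("need >= 4 samples")
  r <- .absCor(m)
  diag(r) <- 0
  out <- lapply(powers, function(beta) {
    a <- r^beta
    k <- rowSums(a)
    data.frame(power = beta, fitR2 = .scaleFreeFit(k, nBins),
               meanK = mean(k))
  })
  do.call(rbind, out)
}

## R^2 of log10(freq) ~ log10(mean k) over connectivity bins.
.scaleFreeFit <- function(k, nBins = 10L) {
  if (stats::sd(k) == 0) return(NA_real_)
  bins <- cut(k, breaks = nBins)
  kmean <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length)
  ok <- !is.na(kmean) & kmean > 0
  if (sum(ok) < 3) return(NA_real_)
  lx <- log10(kmean[ok]); ly <- log10(freq[ok] / length(k))
  summary(stats::lm(ly ~ lx))$r.squared
}

#' Unsigned adjacency and topological overlap
#'
#' Adjacency a_ij = |cor(x_i, x_j)|^beta with unit diagonal, and the
#' topological overlap similarity
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' TOM_ii = 1, where k_i is the connectivity excluding the diagonal and the
#' numerator sum runs over u != i, j.
#'
#' @param x FPKM matrix or SummarizedExperiment (>= 4 samples).
#' @param beta soft-threshold power (default 14).
#' @return list with symmetric matrices \code{adjacency} and \code{tom},
#'   entries in [0,1].
#' @export
adjacencyTom <- function(x, beta = 14) {
  m <- .asMatrix(x, "fpkm")
  if (ncol(m) < 4) stop("need >= 4 samples")
  if (beta < 1) stop("beta must be >= 1")
  a <- .absCor(m)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a                    # diag(a)=0, so u = i, j drop out
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  diag(a) <- 1
  list(adjacency = a, tom = tom)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM), cut statically at the absolute dissimilarity height
#' \code{cutHeight}.  The TOM dissimilarity scale is absolute —
#' unrelated genes sit at essentially 1 under soft thresholding while
#' co-module genes merge well below it — so a fixed cut just under 1
#' separates modules from background deterministically.  Clusters smaller
#' than \code{minModuleSize} become
#' \code{"unassigned"}.  Module labels are deterministic: ordered by
#' decreasing size, ties by the lexicographically smallest member gene id.
#'
#' @param tom TOM similarity matrix (from \code{\link{adjacencyTom}}).
#' @param minModuleSize minimum module size (default 30).
#' @param cutHeight absolute dissimilarity cut in (0,1), default 0.99.
#' @return A \linkS4class{ModulePartition}.
#' @export
detectModules <- function(tom, minModuleSize = 30, cutHeight = 0.99) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  if (cutHeight <= 0 || cutHeight >= 1)
    stop("cutHeight must lie in (0,1)")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  d <- 1 - tom
  tree <- hclust(as.dist(d), method = "average")
  cl <- cutree(tree, h = cutHeight)
  tab <- table(cl)
  big <- names(tab)[tab >= minModuleSize]
  labels <- rep("unassigned", length(cl))
  if (length(big)) {
    first_gene <- vapply(big, function(b) min(genes[cl == b]), "")
    ord <- big[order(-tab[big], first_gene)]
    for (i in seq_along(ord))
      labels[cl == ord[i]] <- paste0("M", i)
  }
  names(labels) <- genes
  modulePartition(labels)
}

#' Module eigengenes
#'
#' Per module, the first principal component of the gene-standardized
#' module submatrix across samples, scaled to unit variance and sign-
#' oriented to correlate nonnegatively with the module's mean standardized
#' expression.  A size-1 module's eigengene is that gene's standardized
#' profile.  Background (\code{"unassigned"}) genes are skipped.
#'
#' @param x FPKM matrix or SummarizedExperiment.
#' @param partition a \linkS4class{ModulePartition} over the matrix genes.
#' @return matrix, modules x samples; each row has unit variance.
#' @export
moduleEigengenes <- function(x, partition) {
  m <- .asMatrix(x, "fpkm")
  labels <- moduleLabels(partition)
  if (!all(names(labels) %in% rownames(m)))
    stop("partition contains genes absent from the matrix")
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) stop("partition has no modules")
  ## keep deterministic M1, M2, ... ordering where labels follow that form
  num <- suppressWarnings(as.integer(sub("^M", "", mods)))
  mods <- if (!anyNA(num)) mods[order(num)] else sort(mods)
  eig <- matrix(NA_real_, length(mods), ncol(m),
                dimnames = list(mods, colnames(m)))
  for (mod in mods) {
    sub <- m[names(labels)[labels == mod], , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    sub <- sub[sds > 0, , drop = FALSE]
    if (!nrow(sub))
      stop("module ", mod, " has only constant profiles")
    z <- t(scale(t(sub)))
    if (nrow(z) == 1) {
      e <- z[1, ]
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    e <- e / stats::sd(e)
    if (cor(e, colMeans(z)) < 0) e <- -e
    eig[mod, ] <- e
  }
  eig
}

#' Screen modules against soil salinity at both depths
#'
#' Pearson correlation of each module eigengene with the per-sample soil
#' salinity of the 0-10 cm and 10-20 cm layers.  A module is selected when
#' |r| exceeds the threshold at BOTH depths (absolute value: a strongly
#' negatively salt-correlated module is salt-relevant too).
#'
#' @param eigengenes modules x samples matrix from
#'   \code{\link{moduleEigengenes}}.
#' @param salinity data.frame or matrix with per-sample columns
#'   \code{salinity_d1}, \code{salinity_d2} (rows follow the eigengene
#'   sample order), e.g. the colData of \code{\link{simulateExpression}}.
#' @param threshold correlation threshold (default 0.5, strict).
#' @return list: \code{selected} (module labels), \code{table}
#'   (module, depth, r, p).
#' @export
moduleTraitScreen <- function(eigengenes, salinity, threshold = 0.5) {
  sal <- as.data.frame(salinity)
  need <- c("salinity_d1", "salinity_d2")
  if (!all(need %in% colnames(sal)))
    stop("salinity needs columns salinity_d1 and salinity_d2")
  if (anyNA(sal[, need]))
    stop("missing salinity for sample(s): ",
         paste(head(rownames(sal)[!complete.cases(sal[, need])], 5),
               collapse = ", "))
  if (nrow(sal) != ncol(eigengenes))
    stop("salinity rows must match eigengene samples")
  n <- nrow(sal)
  tab <- do.call(rbind, lapply(rownames(eigengenes), function(mod) {
    r1 <- cor(eigengenes[mod, ], sal$salinity_d1)
    r2 <- cor(eigengenes[mod, ], sal$salinity_d2)
    data.frame(module = mod, depth = c("0-10 cm", "10-20 cm"),
               r = c(r1, r2), p = .corP(c(r1, r2), n),
               stringsAsFactors = FALSE)
  }))
  byMod <- split(tab$r, tab$module)
  selected <- names(byMod)[vapply(byMod,
                                  function(r) all(abs(r) > threshold),
                                  TRUE)]
  num <- suppressWarnings(as.integer(sub("^M", "", selected)))
  selected <- if (!anyNA(num) && length(num)) selected[order(num)] else
    sort(selected)
  list(selected = selected, table = tab)
}

#' Hub-gene screen by module membership and gene significance
#'
#' For every gene of the given (typically salinity-selected) modules,
#' computes kME = cor(gene, own-module eigengene) and GS = cor(gene,
#' trait), and flags hubs by |kME| > kmeThreshold AND |GS| > gsThreshold
#' (both strict).  Genes labelled \code{"unassigned"} are excluded and
#' counted in the attribute \code{"nExcluded"}.
#'
#' @param x FPKM matrix or SummarizedExperiment.
#' @param eigengenes modules x samples eigengene matrix.
#' @param partition a \linkS4class{ModulePartition}.
#' @param trait per-sample numeric covariate (defaults should be the
#'   0-10 cm soil salinity).
#' @param modules module labels to screen (default: all modules in the
#'   eigengene matrix).
#' @param kmeThreshold,gsThreshold strict thresholds (defaults 0.8, 0.5).
#' @return data.frame (gene, module, kME, GS, hub) with attribute
#'   \code{"nExcluded"}; hubs are \code{hub == TRUE}.
#' @export
hubGeneScreen <- function(x, eigengenes, partition, trait,
                          modules = rownames(eigengenes),
                          kmeThreshold = 0.8, gsThreshold = 0.5) {
  m <- .asMatrix(x, "fpkm")
  if (length(trait) != ncol(m))
    stop("trait must be defined for every sample")
  labels <- moduleLabels(partition)
  nExcluded <- sum(labels == "unassigned")
  keep <- names(labels)[labels %in% setdiff(modules, "unassigned")]
  keep <- intersect(keep, rownames(m))
  if (!length(keep)) {
    out <- data.frame(gene = character(), module = character(),
                      kME = numeric(), GS = numeric(), hub = logical())
    attr(out, "nExcluded") <- nExcluded
    return(out)
  }
  kme <- vapply(keep, function(g)
    cor(m[g, ], eigengenes[labels[[g]], ]), 1)
  gs <- vapply(keep, function(g) cor(m[g, ], trait), 1)
  out <- data.frame(gene = keep, module = unname(labels[keep]),
                    kME = unname(kme), GS = unname(gs),
                    hub = abs(kme) > kmeThreshold & abs(gs) > gsThreshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "nExcluded") <- nExcluded
  out
}
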