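## Pearson correlation gene networks with degree-based hub identification,
## and singular enrichment analysis (SEA) by the one-sided Fisher /
## hypergeometric test against a user-supplied annotation map.

#' Build a Pearson correlation gene network
#'
#' All-pairs Pearson correlation within a gene set; a pair becomes an
#' (undirected) edge when |r| >= rThreshold AND its BH-adjusted two-sided
#' p-value is below fdrThreshold.  Edge signs are recorded.  Constant
#' genes are excluded with a message.
#'
#' @param x FPKM matrix or SummarizedExperiment (>= 4 samples).
#' @param geneSet character vector of genes (subset of the matrix rows);
#'   default all genes.
#' @param rThreshold minimum |r| for an edge (default 0.8).
#' @param fdrThreshold BH FDR threshold (default 0.05).
#' @param nodeFlags optional data.frame of node attributes (column
#'   \code{gene} plus flags), merged onto the node table.
#' @return A \linkS4class{GeneNetwork}.
#' @export
buildCorrelationNetwork <- function(x, geneSet = NULL, rThreshold = 0.8,
                                    fdrThreshold = 0.05,
                                    nodeFlags = NULL) {
  m <- .asMatrix(x, "fpkm")
  if (ncol(m) < 4) stop("need >= 4 samples")
  if (is.null(geneSet)) geneSet <- rownames(m)
  missing_g <- setdiff(geneSet, rownames(m))
  if (length(missing_g))
    stop("gene(s) absent from matrix: ",
         paste(head(missing_g, 5), collapse = ", "))
  sub <- m[geneSet, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    message("excluding constant gene(s): ",
            paste(head(geneSet[sds == 0], 5), collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
  }
  genes <- rownames(sub)
  edges <- data.frame(gene1 = character(), gene2 = character(),
                      r = numeric(), sign = character(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  if (length(genes) >= 2) {
    r <- cor(t(sub))
    ut <- which(upper.tri(r), arr.ind = TRUE)
    rv <- r[ut]
    pv <- .corP(rv, ncol(sub))
    fdr <- bhAdjust(pv)
    keep <- abs(rv) >= rThreshold & fdr < fdrThreshold
    if (any(keep))
      edges <- data.frame(gene1 = genes[ut[keep, 1]],
                          gene2 = genes[ut[keep, 2]],
                          r = rv[keep],
                          sign = ifelse(rv[keep] >= 0, "positive",
                                        "negative"),
                          p = pv[keep], fdr = fdr[keep],
                          stringsAsFactors = FALSE)
  }
  nodes <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!is.null(nodeFlags))
    nodes <- merge(nodes, nodeFlags, by = "gene", all.x = TRUE,
                   sort = FALSE)
  new("GeneNetwork", nodes = nodes, edges = edges,
      rThreshold = rThreshold, fdrThreshold = fdrThreshold)
}

#' Node degree and weighted degree
#'
#' Degree = number of incident edges; weighted degree = sum of |r| over
#' incident edges.  Nodes are ranked by decreasing degree, ties broken by
#' gene id.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @return data.frame (gene, degree, weightedDegree, rank), ranked.
#' @export
networkCentrality <- function(network) {
  nodes <- networkNodes(network)$gene
  e <- networkEdges(network)
  deg <- setNames(integer(length(nodes)), nodes)
  wdeg <- setNames(numeric(length(nodes)), nodes)
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      deg[e$gene1[i]] <- deg[e$gene1[i]] + 1L
      deg[e$gene2[i]] <- deg[e$gene2[i]] + 1L
      wdeg[e$gene1[i]] <- wdeg[e$gene1[i]] + abs(e$r[i])
      wdeg[e$gene2[i]] <- wdeg[e$gene2[i]] + abs(e$r[i])
    }
  }
  out <- data.frame(gene = nodes, degree = unname(deg),
                    weightedDegree = unname(wdeg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Singular enrichment analysis (Fisher exact test)
#'
#' One-sided over-representation test per annotation term: with universe
#' size N, term size K (after intersecting the term with the universe),
#' query size n and overlap k, p = P(X >= k) for X ~ Hypergeometric(N, K,
#' n); BH adjustment across terms.
#'
#' @param query character vector of genes (must lie in the universe).
#' @param annotation named list: term id -> character vector of genes.
#' @param universe character vector of background genes (e.g. all genes
#'   surviving the expression filter).
#' @return data.frame: term, k, n, K, N, p, fdr; ordered by p.
#' @examples
#' ann <- list(t1 = paste0("g", 1:20))
#' seaEnrichment(paste0("g", c(1:5, 90:94)), ann, paste0("g", 1:100))
#' @export
seaEnrichment <- function(query, annotation, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  if (is.null(names(annotation)) || any(names(annotation) == ""))
    stop("annotation terms must be named")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(annotation[[term]], universe)
    K <- length(tg)
    if (!K) return(NULL)
    k <- length(intersect(tg, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no annotation term overlaps the universe")
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
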