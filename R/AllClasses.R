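## S4 containers for the pipeline's results.  Expression and count data
## travel as SummarizedExperiment objects (assay "fpkm" or "counts", sample
## metadata in colData); the classes below hold derived results that have no
## canonical Bioconductor container.

#' Gene-to-module partition
#'
#' Assignment of every gene to exactly one co-expression module, with the
#' reserved label \code{"unassigned"} for background genes that fall below
#' the minimum module size.
#'
#' @slot labels Named character vector, one entry per gene; names are gene
#'   ids, values module labels.
#' @export
setClass("ModulePartition", representation(labels = "character"))

setValidity("ModulePartition", function(object) {
  lab <- object@labels
  if (is.null(names(lab)) || any(names(lab) == ""))
    return("every gene must be named")
  if (anyDuplicated(names(lab)))
    return("duplicate gene ids in partition")
  if (any(is.na(lab)))
    return("NA module labels not allowed")
  TRUE
})

#' Construct a ModulePartition
#'
#' @param labels named character vector mapping gene id to module label;
#'   use \code{"unassigned"} for background genes.
#' @return A \linkS4class{ModulePartition}.
#' @examples
#' modulePartition(c(g1 = "M1", g2 = "M1", g3 = "unassigned"))
#' @export
modulePartition <- function(labels) {
  new("ModulePartition", labels = labels)
}

#' @describeIn modulePartition gene-to-module label vector
#' @param object,x a \code{ModulePartition}
#' @export
moduleLabels <- function(object) object@labels

#' @describeIn modulePartition module sizes (excluding none; includes
#'   "unassigned" if present), decreasing
#' @export
moduleSizes <- function(object) {
  sort(table(object@labels), decreasing = TRUE)
}

#' @rdname modulePartition
#' @export
setMethod("length", "ModulePartition", function(x) length(x@labels))

setMethod("show", "ModulePartition", function(object) {
  tab <- moduleSizes(object)
  n_mod <- sum(names(tab) != "unassigned")
  cat("ModulePartition:", length(object@labels), "genes in", n_mod,
      "modules")
  if ("unassigned" %in% names(tab))
    cat(" (+", tab[["unassigned"]], "unassigned)")
  cat("\n")
  print(head(tab, 10))
})

#' Fuzzy comprehensive salt-tolerance evaluation
#'
#' Result of the membership-function / PCA evaluation: per-unit comprehensive
#' indices (retained principal-component scores), their variance
#' contributions and weights, component-score memberships, the integrated
#' tolerance score D and the per-unit rank (1 = most tolerant).
#'
#' @slot indices numeric matrix, units x retained components (scores).
#' @slot contributions numeric, percent variance per retained component.
#' @slot weights numeric, contribution-rate weights; sums to 1.
#' @slot memberships numeric matrix, units x retained components, in [0,1].
#' @slot D numeric, per-unit score in [0,1].
#' @slot rank integer, permutation of 1..n_units, 1 = highest D.
#' @export
setClass("ToleranceEvaluation",
         representation(indices = "matrix", contributions = "numeric",
                        weights = "numeric", memberships = "matrix",
                        D = "numeric", rank = "integer"))

setValidity("ToleranceEvaluation", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must sum to 1")
  if (any(object@memberships < -1e-12 | object@memberships > 1 + 1e-12))
    return("memberships must lie in [0,1]")
  if (any(object@D < -1e-12 | object@D > 1 + 1e-12))
    return("D must lie in [0,1]")
  if (!setequal(object@rank, seq_along(object@D)))
    return("rank must be a permutation of 1..n_units")
  TRUE
})

setMethod("show", "ToleranceEvaluation", function(object) {
  cat("ToleranceEvaluation:", length(object@D), "units,",
      length(object@weights), "retained component(s)\n")
  cat("weights:", paste(signif(object@weights, 4), collapse = ", "), "\n")
  df <- toleranceTable(object)
  print(df[order(df$rank), ], digits = 4)
})

#' @describeIn toleranceScore integrated D score per unit
#' @export
toleranceD <- function(object) object@D

#' @describeIn toleranceScore Table-shaped summary (unit, scores,
#'   memberships, D, rank)
#' @export
toleranceTable <- function(object) {
  k <- ncol(object@indices)
  df <- data.frame(unit = names(object@D),
                   object@indices,
                   object@memberships,
                   D = object@D, rank = object@rank,
                   check.names = FALSE, row.names = NULL)
  colnames(df)[seq_len(k) + 1L] <- paste0("X", seq_len(k))
  colnames(df)[k + seq_len(k) + 1L] <- paste0("mu_X", seq_len(k))
  df
}

#' Named gene sets with screening provenance
#'
#' Holds the gene sets produced by the screening chain (per-contrast DEGs,
#' cross-contrast intersections, WGCNA hub genes, core set) together with a
#' record of the filters each set passed.
#'
#' @slot sets named list of character vectors (gene ids).
#' @slot provenance data.frame describing, per core gene, the filters passed.
#' @export
setClass("ScreeningResult",
         representation(sets = "list", provenance = "data.frame"))

setValidity("ScreeningResult", function(object) {
  if (is.null(names(object@sets)) || any(names(object@sets) == ""))
    return("all gene sets must be named")
  if (!all(vapply(object@sets, is.character, TRUE)))
    return("gene sets must be character vectors")
  TRUE
})

#' @describeIn coreGeneScreen named list of gene sets
#' @param object a \code{ScreeningResult}
#' @export
geneSets <- function(object) object@sets

#' @describeIn coreGeneScreen per-core-gene filter provenance
#' @export
screenProvenance <- function(object) object@provenance

setMethod("show", "ScreeningResult", function(object) {
  cat("ScreeningResult with", length(object@sets), "gene set(s):\n")
  for (nm in names(object@sets))
    cat("  ", nm, ": ", length(object@sets[[nm]]), " genes\n", sep = "")
})

#' Pearson correlation gene network
#'
#' Undirected network over a gene set: one edge per gene pair whose
#' correlation passes the |r| and FDR thresholds.
#'
#' @slot nodes data.frame with columns \code{gene} and attribute flags.
#' @slot edges data.frame with columns \code{gene1, gene2, r, sign, p, fdr}.
#' @slot rThreshold,fdrThreshold numeric thresholds used to build the edges.
#' @export
setClass("GeneNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        rThreshold = "numeric", fdrThreshold = "numeric"))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  need <- c("gene1", "gene2", "r", "sign", "p", "fdr")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (nrow(e) && any(e$gene1 == e$gene2))
    return("self-edges not allowed")
  if (nrow(e) && any(abs(e$r) < object@rThreshold - 1e-12))
    return("edge below |r| threshold")
  TRUE
})

#' @describeIn buildCorrelationNetwork edge table of the network
#' @param object a \code{GeneNetwork}
#' @export
networkEdges <- function(object) object@edges

#' @describeIn buildCorrelationNetwork node table of the network
#' @export
networkNodes <- function(object) object@nodes

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges (|r| >=", object@rThreshold, ", FDR <",
      object@fdrThreshold, ")\n")
})
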