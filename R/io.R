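## Readers/writers for the pipeline's plain-text table formats, and the
## end-to-end run-directory orchestrator.  Tab-separated is canonical;
## comma-separated files are accepted on read (by extension).

.sepFor <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a gene x sample matrix
#'
#' First column = gene id, header = sample ids.  Validates shape and
#' content: ragged rows, duplicate gene or sample ids, and (for counts)
#' non-integer or negative values are rejected with line-numbered
#' messages.
#'
#' @param path TSV (or .csv) file.
#' @param kind \code{"fpkm"} (nonnegative numeric) or \code{"counts"}
#'   (nonnegative integer).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readMatrix <- function(path, kind = c("fpkm", "counts")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sepFor(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1)
    stop("ragged rows at line(s): ",
         paste(head(which(nf != nf[1]), 5), collapse = ", "))
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("need a gene-id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate gene id '", ids[dup[1]], "' at line ", dup[1] + 1L)
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id: ",
         samples[duplicated(samples)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix")
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("missing/invalid value at line ", bad + 1L)
  }
  neg <- which(rowSums(m < 0) > 0)
  if (length(neg))
    stop("negative value at line ", neg[1] + 1L)
  if (kind == "counts") {
    nonint <- which(rowSums(m != round(m)) > 0)
    if (length(nonint))
      stop("non-integer count at line ", nonint[1] + 1L)
    storage.mode(m) <- "integer"
  }
  rownames(m) <- ids
  m
}

#' Write a gene x sample matrix
#'
#' Inverse of \code{\link{readMatrix}}: gene ids in the first column
#' (header \code{gene}), tab-separated.
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = .sepFor(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an annotation map
#'
#' Two-column (term, gene) TSV, a minimal GO-annotation-like dialect.
#'
#' @param path TSV file with a header row.
#' @return named list: term -> character vector of gene ids.
#' @export
readAnnotationMap <- function(path) {
  df <- read.delim(path, sep = .sepFor(path), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation map needs term and gene columns")
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname readAnnotationMap
#' @param annotation named list (term -> genes)
#' @export
writeAnnotationMap <- function(annotation, path) {
  df <- data.frame(term = rep(names(annotation),
                              lengths(annotation)),
                   gene = unlist(annotation, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write gene sets (one id per line)
#'
#' @param genes character vector of gene ids.
#' @param path file path.
#' @return \code{readGeneSet}: character vector; writers return the path.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname writeGeneSet
#' @export
readGeneSet <- function(path) readLines(path)

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis chain into a run directory
#'
#' Executes, in order: expression filter, soft-threshold report,
#' adjacency/TOM, module detection, eigengenes, dual-depth module-salinity
#' screen, hub-gene screen, per-contrast NB differential expression
#' against the reference group, cross-contrast DEG intersections, the
#' core-gene screen, the correlation network over the core genes,
#' enrichment of the core set, shoot trait summaries, and the fuzzy
#' tolerance D table.  Every artifact is written as plain text and listed
#' in \code{manifest.json} (with md5 hashes and the seed); a resolved
#' \code{config.json} sits next to the outputs.  Inputs are the
#' synthetic-data generator's tables for the given config, so a rerun with
#' the same config is fully reproducible.
#'
#' @param outdir output directory (created if needed).
#' @param config a \code{\link{simConfig}}; its seed drives every draw.
#' @param beta soft-threshold power for the network (default 14).
#' @param minModuleSize,cutHeight module detection parameters.
#' @param moduleTraitThreshold dual-depth salinity screen threshold (0.5).
#' @param kmeThreshold,gsThreshold hub screen thresholds (0.8, 0.5).
#' @param lfcThreshold,fdrThreshold DEG thresholds (1, 0.05).
#' @param networkR,networkFdr correlation-network edge thresholds
#'   (0.8, 0.05).
#' @param expressionFloor FPKM filter floor (20).
#' @return (invisibly) a list with the principal in-memory results:
#'   partition, eigengenes, screen, hub table, DEG sets, screening result,
#'   network, enrichment, trait summary, tolerance evaluation, and the
#'   manifest.
#' @export
runPipeline <- function(outdir, config = simConfig(), beta = 14,
                        minModuleSize = 30, cutHeight = 0.99,
                        moduleTraitThreshold = 0.5, kmeThreshold = 0.8,
                        gsThreshold = 0.5, lfcThreshold = 1,
                        fdrThreshold = 0.05, networkR = 0.8,
                        networkFdr = 0.05, expressionFloor = 20) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  put <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    artifacts[[length(artifacts) + 1L]] <<- name
    path
  }

  sim <- .stage("simulate", simulateExpression(config))
  cd <- as.data.frame(SummarizedExperiment::colData(sim$se))

  filt <- .stage("filter", filterExpressed(sim$se, expressionFloor))
  fm <- .asMatrix(filt, "fpkm")

  soft <- .stage("soft-threshold",
                 softThresholdDiagnostic(fm, powers = c(1, 2, 4, 6, 8,
                                                        10, 12, 14)))
  put("soft_threshold.tsv", function(p) .writeTSV(soft, p))

  at <- .stage("adjacency-tom", adjacencyTom(fm, beta))
  partition <- .stage("modules",
                      detectModules(at$tom, minModuleSize, cutHeight))
  put("module_partition.tsv", function(p)
    .writeTSV(data.frame(gene = names(moduleLabels(partition)),
                         module = unname(moduleLabels(partition))), p))

  eig <- .stage("eigengenes", moduleEigengenes(fm, partition))
  put("eigengenes.tsv", function(p)
    .writeTSV(data.frame(module = rownames(eig), eig,
                         check.names = FALSE), p))

  screen <- .stage("module-trait",
                   moduleTraitScreen(eig, cd, moduleTraitThreshold))
  put("module_trait_screen.tsv", function(p)
    .writeTSV(screen$table, p))

  hub <- .stage("hub-screen",
                hubGeneScreen(fm, eig, partition, cd$salinity_d1,
                              modules = screen$selected,
                              kmeThreshold = kmeThreshold,
                              gsThreshold = gsThreshold))
  put("hub_genes.tsv", function(p) .writeTSV(hub, p))

  ## planted DE set shared across contrasts: drawn once from the config
  ## seed, half inside the salinity modules, half background
  deGenes <- .withStream(config$seed, 6L, {
    part0 <- moduleLabels(sim$partition)
    salLabels <- paste0("M", config$salinityModules)
    n_de <- round(config$deFraction * config$nGenes)
    inMod <- names(part0)[part0 %in% salLabels]
    outMod <- setdiff(names(part0), inMod)
    nIn <- min(length(inMod), ceiling(n_de / 2))
    g <- c(sample(inMod, nIn), sample(outMod, n_de - nIn))
    list(genes = g, signs = sample(c(-1, 1), n_de, replace = TRUE))
  })

  refGroup <- config$groups[1]
  others <- setdiff(config$groups, refGroup)
  deTabs <- list(); degSets <- list(); truths <- list()
  for (i in seq_along(others)) {
    g <- others[i]
    cfg_i <- config
    cfg_i$seed <- .streamSeed(config$seed, 100L + i)
    simc <- .stage(paste0("counts-", g),
                   simulateCounts(cfg_i, contrast = c(refGroup, g),
                                  deGenes = deGenes$genes,
                                  deSigns = deGenes$signs))
    res <- .stage(paste0("de-", g),
                  nbExactTest(simc$se,
                              SummarizedExperiment::colData(simc$se)$group))
    res$contrast <- paste0(g, "_vs_", refGroup)
    deTabs[[g]] <- res
    degSets[[g]] <- callDegs(res, lfcThreshold, fdrThreshold)
    truths[[g]] <- simc$truth
  }
  put("de_results.tsv", function(p)
    .writeTSV(do.call(rbind, c(deTabs, list(make.row.names = FALSE))), p))

  common <- .stage("intersect", commonDegs(degSets))
  put("common_up.txt", function(p) writeGeneSet(common$common_up, p))
  put("common_down.txt", function(p) writeGeneSet(common$common_down, p))

  core <- .stage("core-screen",
                 suppressWarnings(
                   coreGeneScreen(hub, common$common_up,
                                  common$common_down)))
  put("core_genes.tsv", function(p) {
    prov <- screenProvenance(core)
    if (!nrow(prov)) prov <- data.frame(gene = character(),
                                        direction = character())
    .writeTSV(prov, p)
  })

  netGenes <- geneSets(core)$core
  if (length(netGenes) < 2) netGenes <- geneSets(core)$hub
  net <- .stage("network",
                buildCorrelationNetwork(fm, intersect(netGenes,
                                                      rownames(fm)),
                                        networkR, networkFdr))
  put("network_edges.tsv", function(p) .writeTSV(networkEdges(net), p))

  ann <- .stage("annotation", simulateAnnotation(config))
  query <- geneSets(core)$core
  if (!length(query)) query <- geneSets(core)$hub
  enr <- .stage("enrichment",
                seaEnrichment(intersect(query, rownames(fm)), ann,
                              rownames(fm)))
  put("enrichment.tsv", function(p) .writeTSV(enr, p))

  traits <- .stage("traits",
                   deriveShootMetrics(simulateTraitSurvey(config)))
  traitCols <- c("height", "basal_diameter", "fresh_weight",
                 "dry_weight", "spad", "sla", "ldmc")
  summ <- do.call(rbind, lapply(traitCols, function(tr) {
    s <- groupSummary(traits, tr)
    s$trait <- tr
    a <- anovaFromSummary(s$mean, s$sd, s$n)
    s$F <- a$F; s$p_anova <- a$p
    s
  }))
  put("trait_summary.tsv", function(p) .writeTSV(summ, p))

  tol <- .stage("fuzzy", {
    traits$unit <- ifelse(traits$site == "L", traits$patch, traits$site)
    ind <- aggregate(traits[, c("fresh_weight", "dry_weight", "height",
                                "basal_diameter", "ldmc", "sla",
                                "spad")],
                     by = list(unit = traits$unit), FUN = mean)
    rn <- ind$unit
    ind <- as.matrix(ind[, -1])
    rownames(ind) <- rn
    fuzzyToleranceEvaluation(ind)
  })
  put("tolerance_D.tsv", function(p) .writeTSV(toleranceTable(tol), p))

  resolved <- config
  resolved$traitCalibration <- NULL
  resolved$salinityProfile <- NULL
  jsonlite::write_json(c(resolved,
                         list(beta = beta, minModuleSize = minModuleSize,
                              cutHeight = cutHeight,
                              moduleTraitThreshold = moduleTraitThreshold,
                              kmeThreshold = kmeThreshold,
                              gsThreshold = gsThreshold,
                              lfcThreshold = lfcThreshold,
                              fdrThreshold = fdrThreshold,
                              networkR = networkR,
                              networkFdr = networkFdr,
                              expressionFloor = expressionFloor)),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("phragnet")),
                   artifacts = artifacts,
                   md5 = as.list(tools::md5sum(file.path(outdir,
                                                         artifacts))))
  names(manifest$md5) <- artifacts
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(partition = partition, eigengenes = eig,
                 screen = screen, hub = hub, degSets = degSets,
                 common = common, core = core, network = net,
                 enrichment = enr, traitSummary = summ, tolerance = tol,
                 truths = truths, truePartition = sim$partition,
                 deGenes = deGenes, manifest = manifest))
}
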