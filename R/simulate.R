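## Synthetic-data generator: trait survey, soil profiles, FPKM matrix with
## planted co-expression modules, and NB counts with planted DE genes.
## Every table draws from its own RNG stream derived from the master seed,
## so generating one table never perturbs another.

.defaultTraitCalibration <- function() {
  ## Per-group mean/SD calibration for the six directly simulated shoot
  ## traits (leaf area and leaf dry weight are generated jointly via SLA).
  groups <- c("L", "IN", "M", "H")
  data.frame(
    trait = rep(c("height", "basal_diameter", "fresh_weight", "dry_weight",
                  "spad", "sla"), each = 4),
    group = rep(groups, times = 6),
    mean = c(108.93, 115.20, 145.32, 199.56,
             6.09, 4.99, 5.73, 7.41,
             33.19, 26.57, 35.47, 65.54,
             17.94, 16.22, 20.68, 34.33,
             44.12, 43.87, 43.29, 40.95,
             120.48, 131.77, 110.20, 110.76),
    sd = c(40.16, 17.27, 34.51, 54.33,
           1.34, 1.20, 1.39, 1.98,
           13.69, 9.47, 13.27, 33.78,
           6.95, 5.35, 7.03, 15.31,
           4.11, 3.89, 5.44, 2.10,
           24.60, 21.84, 19.93, 73.45),
    stringsAsFactors = FALSE)
}

.defaultSalinityProfile <- function() {
  ## Site-group mean salinity (g/kg) at the two sampled depths; the low
  ## tidal flat is the saltiest habitat, middle intermediate, high lowest.
  data.frame(group = c("L", "IN", "M", "H"),
             depth1 = c(12.0, 5.0, 6.5, 4.5),
             depth2 = c(11.0, 5.0, 6.0, 4.0),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  Defaults
#' reproduce the study design: four tidal-flat groups (L, IN, M, H) with
#' 15/5/10/10 quadrats of 5 shoots each (200 shoots), 39 retained RNA
#' samples, 2000 genes with 8 planted co-expression modules of which the
#' first three track soil salinity at both depths, and 5\% planted DE genes
#' at log2 fold change 2 under NB dispersion 0.1.
#'
#' @param seed master seed; fully determines all outputs.
#' @param groups group labels, low to high tidal flat.
#' @param quadratsPerGroup integer vector, quadrats per group.
#' @param shootsPerQuadrat shoots sampled per quadrat.
#' @param nSamplesRNA total RNA samples retained across groups.
#' @param nGenes number of genes.
#' @param moduleSizes sizes of planted modules (sum must not exceed
#'   \code{nGenes}); remaining genes are uncorrelated background.
#' @param salinityModules indices of modules planted to correlate with the
#'   per-sample salinity covariate at both depths.
#' @param deFraction fraction of genes planted DE per contrast.
#' @param deLog2fc planted absolute log2 fold change.
#' @param nbDispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param factorNoiseSD residual log2-scale noise on module genes.
#' @param traitCalibration per-group mean/SD table (columns trait, group,
#'   mean, sd).
#' @param salinityProfile per-group mean salinity at the two depths.
#' @return A list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg$nGenes
#' @export
simConfig <- function(seed = 1L,
                      groups = c("L", "IN", "M", "H"),
                      quadratsPerGroup = c(15L, 5L, 10L, 10L),
                      shootsPerQuadrat = 5L,
                      nSamplesRNA = 39L,
                      nGenes = 2000L,
                      moduleSizes = c(120L, 100L, 90L, 80L, 70L, 60L, 50L, 40L),
                      salinityModules = 1:3,
                      deFraction = 0.05,
                      deLog2fc = 2.0,
                      nbDispersion = 0.1,
                      factorNoiseSD = 0.5,
                      traitCalibration = .defaultTraitCalibration(),
                      salinityProfile = .defaultSalinityProfile()) {
  if (length(groups) < 2) stop("need at least two groups")
  if (length(quadratsPerGroup) != length(groups))
    stop("quadratsPerGroup must match groups")
  if (any(quadratsPerGroup < 1) || shootsPerQuadrat < 1)
    stop("non-positive group sizes")
  if (sum(moduleSizes) > nGenes)
    stop("module sizes exceed gene count")
  if (deFraction < 0 || deFraction >= 1)
    stop("deFraction must lie in [0,1)")
  if (nbDispersion < 0) stop("dispersion must be >= 0")
  if (any(salinityModules > length(moduleSizes)))
    stop("salinityModules out of range")
  structure(list(seed = as.integer(seed), groups = groups,
                 quadratsPerGroup = as.integer(quadratsPerGroup),
                 shootsPerQuadrat = as.integer(shootsPerQuadrat),
                 nSamplesRNA = as.integer(nSamplesRNA),
                 nGenes = as.integer(nGenes),
                 moduleSizes = as.integer(moduleSizes),
                 salinityModules = as.integer(salinityModules),
                 deFraction = deFraction, deLog2fc = deLog2fc,
                 nbDispersion = nbDispersion,
                 factorNoiseSD = factorNoiseSD,
                 traitCalibration = traitCalibration,
                 salinityProfile = salinityProfile),
            class = "SimConfig")
}

## Sites within each group: the low flat outside the dike is sampled as
## five discrete patches (A-E); other groups are single contiguous sites.
.groupSites <- function(config) {
  sites <- lapply(config$groups, function(g) {
    if (g == "L") paste0("", c("A", "B", "C", "D", "E")) else g
  })
  names(sites) <- config$groups
  sites
}

#' Simulate a shoot trait survey
#'
#' One row per sampled shoot.  Each trait is drawn from a truncated-at-zero
#' normal calibrated to the per-group mean/SD table; fresh and dry weight
#' are drawn jointly (correlation 0.9, pairs with DW >= FW resampled) so
#' the biological constraint DW < FW holds; leaf area and leaf dry weight
#' are generated jointly through SLA so derived SLA has realistic spread.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return data.frame with columns site, patch, quadrat, shoot, height,
#'   basal_diameter, fresh_weight, dry_weight, spad, leaf_area,
#'   leaf_dry_weight.
#' @examples
#' tab <- simulateTraitSurvey(simConfig(seed = 1))
#' nrow(tab)  # 200 with the default design
#' @export
simulateTraitSurvey <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withStream(config$seed, 1L, {
    cal <- config$traitCalibration
    sites <- .groupSites(config)
    rows <- list()
    for (gi in seq_along(config$groups)) {
      g <- config$groups[gi]
      nq <- config$quadratsPerGroup[gi]
      n <- nq * config$shootsPerQuadrat
      calg <- function(tr) {
        row <- cal[cal$trait == tr & cal$group == g, ]
        if (nrow(row) != 1) stop("missing calibration for ", tr, "/", g)
        row
      }
      ch <- calg("height"); cb <- calg("basal_diameter")
      cf <- calg("fresh_weight"); cd <- calg("dry_weight")
      cs <- calg("spad"); cl <- calg("sla")
      height <- .rtruncnorm0(n, ch$mean, ch$sd)
      bd <- .rtruncnorm0(n, cb$mean, cb$sd)
      ## FW/DW joint draw: correlated normals, reject invalid pairs
      rho <- 0.9
      drawPair <- function(m) {
        z1 <- rnorm(m); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
        cbind(cf$mean + cf$sd * z1, cd$mean + cd$sd * z2)
      }
      fwdw <- drawPair(n)
      bad <- which(fwdw[, 1] <= 0 | fwdw[, 2] <= 0 |
                     fwdw[, 2] >= fwdw[, 1])
      guard <- 0L
      while (length(bad) && guard < 1000L) {
        fwdw[bad, ] <- drawPair(length(bad))
        bad <- bad[fwdw[bad, 1] <= 0 | fwdw[bad, 2] <= 0 |
                     fwdw[bad, 2] >= fwdw[bad, 1]]
        guard <- guard + 1L
      }
      if (length(bad)) {
        fwdw[bad, 1] <- cf$mean
        fwdw[bad, 2] <- min(cd$mean, 0.9 * cf$mean)
      }
      spad <- .rtruncnorm0(n, cs$mean, cs$sd)
      ldw <- .rtruncnorm0(n, 0.25, 0.06)
      sla <- .rtruncnorm0(n, cl$mean, cl$sd)
      la <- sla * ldw
      patch_of_quadrat <- rep(sites[[g]], length.out = nq)
      rows[[gi]] <- data.frame(
        site = g,
        patch = rep(patch_of_quadrat, each = config$shootsPerQuadrat),
        quadrat = rep(paste0(g, "_q", seq_len(nq)),
                      each = config$shootsPerQuadrat),
        shoot = paste0(g, "_q", rep(seq_len(nq),
                                    each = config$shootsPerQuadrat),
                       "_s", rep(seq_len(config$shootsPerQuadrat),
                                 times = nq)),
        height = height, basal_diameter = bd,
        fresh_weight = fwdw[, 1], dry_weight = fwdw[, 2],
        spad = spad, leaf_area = la, leaf_dry_weight = ldw,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Simulate soil profiles
#'
#' Two depth layers (0-10 cm, 10-20 cm) per site.  A shared site effect
#' makes the two layers positively correlated within a site; group-mean
#' salinity follows the configured profile (low tidal flat highest).
#'
#' @param config a \code{\link{simConfig}} object.
#' @return data.frame with one row per site x depth layer: site, group,
#'   depth_layer, salinity, pH, TN, TP, AVP, NO3_N, NH4_N, SOC,
#'   water_content.
#' @examples
#' soil <- simulateSoilProfiles(simConfig(seed = 1))
#' table(soil$site)  # two rows per site
#' @export
simulateSoilProfiles <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withStream(config$seed, 2L, {
    sites <- .groupSites(config)
    prof <- config$salinityProfile
    out <- list()
    for (g in config$groups) {
      pg <- prof[prof$group == g, ]
      if (nrow(pg) != 1) stop("missing salinity profile for group ", g)
      for (s in sites[[g]]) {
        u <- rnorm(1)                      # site effect shared by layers
        sal <- c(pg$depth1, pg$depth2) +
          1.2 * (0.8 * u + 0.6 * rnorm(2))
        sal <- pmax(sal, 0.1)
        out[[length(out) + 1L]] <- data.frame(
          site = s, group = g,
          depth_layer = c("0-10 cm", "10-20 cm"),
          salinity = sal,
          pH = pmax(rnorm(2, 8.2, 0.2), 6),
          TN = pmax(rnorm(2, 1.2, 0.2), 0.05),
          TP = pmax(rnorm(2, 0.7, 0.1), 0.05),
          AVP = pmax(rnorm(2, 10, 2), 0.5),
          NO3_N = pmax(rnorm(2, 3, 0.6), 0.1),
          NH4_N = pmax(rnorm(2, 5, 1), 0.1),
          SOC = pmax(rnorm(2, 6, 1.2), 0.5),
          water_content = pmax(rnorm(2, 30, 5), 5),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

## RNA sample allocation across groups: 12/9/9/9 for the default 39-sample
## design, otherwise as even as possible with remainders to earlier groups.
.rnaAllocation <- function(config) {
  k <- length(config$groups)
  n <- config$nSamplesRNA
  if (n == 39L && k == 4L) return(setNames(c(12L, 9L, 9L, 9L),
                                           config$groups))
  base <- n %/% k
  alloc <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  setNames(as.integer(alloc), config$groups)
}

#' Simulate an FPKM matrix with planted co-expression modules
#'
#' Additive latent-factor model on the log2 scale, exponentiated to FPKM:
#' genes in a planted module share a latent factor; the factors of the
#' designated salinity modules track the per-sample site salinity (the two
#' depth layers of the sample's site, as the downstream screen assumes);
#' background genes are uncorrelated noise.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with elements \code{se} (a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"fpkm"} and colData columns sample, group, site, salinity_d1,
#'   salinity_d2) and \code{partition} (the ground-truth
#'   \linkS4class{ModulePartition}).
#' @examples
#' sim <- simulateExpression(simConfig(seed = 7, nGenes = 300,
#'                                     moduleSizes = c(60, 50, 40)))
#' dim(SummarizedExperiment::assay(sim$se))
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  soil <- simulateSoilProfiles(config)
  .withStream(config$seed, 3L, {
    alloc <- .rnaAllocation(config)
    sites <- .groupSites(config)
    sample_group <- rep(names(alloc), times = alloc)
    sample_site <- unlist(lapply(names(alloc), function(g)
      rep(sites[[g]], length.out = alloc[[g]])), use.names = FALSE)
    n <- length(sample_group)
    sample_id <- paste0("S", sprintf("%02d", seq_len(n)), "_", sample_group)
    s1 <- soil[soil$depth_layer == "0-10 cm", ]
    s2 <- soil[soil$depth_layer == "10-20 cm", ]
    sal1 <- s1$salinity[match(sample_site, s1$site)]
    sal2 <- s2$salinity[match(sample_site, s2$site)]

    g_ids <- paste0("gene", sprintf("%04d", seq_len(config$nGenes)))
    nmod <- length(config$moduleSizes)
    labels <- rep("unassigned", config$nGenes)
    idx <- 1L
    module_of <- vector("list", nmod)
    for (m in seq_len(nmod)) {
      sz <- config$moduleSizes[m]
      module_of[[m]] <- idx:(idx + sz - 1L)
      labels[module_of[[m]]] <- paste0("M", m)
      idx <- idx + sz
    }
    names(labels) <- g_ids

    ## latent factors: salinity modules load on the depth-1 salinity
    ## profile (depth 2 is strongly correlated by construction) but keep
    ## an independent residual so the modules stay mutually separable;
    ## other modules are iid
    zsal <- as.numeric(scale(sal1))
    aSal <- 0.75
    factors <- matrix(rnorm(nmod * n), nmod, n)
    for (m in config$salinityModules) {
      f <- aSal * zsal + sqrt(1 - aSal^2) * rnorm(n)
      factors[m, ] <- as.numeric(scale(f))
    }
    baseline <- rnorm(config$nGenes, 6, 1.5)
    lambda <- runif(config$nGenes, 0.9, 1.3)
    log2x <- matrix(rnorm(config$nGenes * n, 0, config$factorNoiseSD),
                    config$nGenes, n) + baseline
    for (m in seq_len(nmod))
      log2x[module_of[[m]], ] <- log2x[module_of[[m]], ] +
        outer(lambda[module_of[[m]]], factors[m, ])
    fpkm <- 2^log2x
    dimnames(fpkm) <- list(g_ids, sample_id)

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(fpkm = fpkm),
      colData = S4Vectors::DataFrame(sample = sample_id,
                                     group = sample_group,
                                     site = sample_site,
                                     salinity_d1 = sal1,
                                     salinity_d2 = sal2,
                                     row.names = sample_id))
    list(se = se, partition = modulePartition(labels))
  })
}

#' Simulate a gene annotation map
#'
#' One annotation term per planted module (the module's genes plus a few
#' random extras) and a number of size-matched noise terms of randomly
#' drawn genes, mimicking a reduced GO-style term-to-gene map for
#' enrichment testing.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param nNoiseTerms number of random background terms (default 10).
#' @return named list: term id -> character vector of gene ids.
#' @export
simulateAnnotation <- function(config, nNoiseTerms = 10L) {
  stopifnot(inherits(config, "SimConfig"))
  .withStream(config$seed, 5L, {
    g_ids <- paste0("gene", sprintf("%04d", seq_len(config$nGenes)))
    nmod <- length(config$moduleSizes)
    ann <- list()
    idx <- 1L
    for (m in seq_len(nmod)) {
      sz <- config$moduleSizes[m]
      members <- g_ids[idx:(idx + sz - 1L)]
      extras <- sample(setdiff(g_ids, members), max(2L, round(0.1 * sz)))
      ann[[paste0("TERM_M", m)]] <- sort(c(members, extras))
      idx <- idx + sz
    }
    meanSize <- max(5L, round(mean(config$moduleSizes)))
    for (t in seq_len(nNoiseTerms))
      ann[[paste0("TERM_R", t)]] <- sort(sample(g_ids, meanSize))
    ann
  })
}

## NB draw with variance mu + phi mu^2 (phi = 0 gives Poisson).
.rnb <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a count matrix with planted differential expression
#'
#' Counts follow NB(mean = library size x relative abundance, dispersion
#' phi).  A fraction of genes is planted DE between the two groups at the
#' configured log2 fold change (random sign, applied to group 2); all other
#' genes share their mean across groups.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param contrast length-2 character vector of group labels
#'   (reference first).
#' @param nPerGroup optional integer vector of length 2 overriding the RNA
#'   allocation for the two groups.
#' @param libSizes optional numeric vector of library sizes (length =
#'   total samples); by default drawn uniformly in [0.8, 1.2] million.
#' @param deGenes optional character vector of gene ids to plant as DE
#'   (overrides the random draw; use to keep the planted set consistent
#'   across contrasts).
#' @param deSigns optional +1/-1 vector (length of \code{deGenes}) fixing
#'   each planted gene's fold-change direction.
#' @return list with elements \code{se} (SummarizedExperiment, assay
#'   \code{"counts"}, colData column \code{group}) and \code{truth}
#'   (data.frame gene / log2fc of planted DE genes; empty when
#'   \code{deFraction = 0}).
#' @examples
#' sim <- simulateCounts(simConfig(seed = 1, nGenes = 200),
#'                       contrast = c("L", "H"), nPerGroup = c(5, 5))
#' nrow(sim$truth)  # round(0.05 * 200) = 10
#' @export
simulateCounts <- function(config, contrast = c("L", "H"),
                           nPerGroup = NULL, libSizes = NULL,
                           deGenes = NULL, deSigns = NULL) {
  stopifnot(inherits(config, "SimConfig"), length(contrast) == 2)
  if (is.null(nPerGroup)) {
    alloc <- .rnaAllocation(config)
    if (!all(contrast %in% names(alloc)))
      stop("contrast groups not in config groups")
    nPerGroup <- as.integer(alloc[contrast])
  }
  if (any(nPerGroup < 2)) stop("both groups need >= 2 samples")
  .withStream(config$seed, 4L, {
    n1 <- nPerGroup[1]; n2 <- nPerGroup[2]; n <- n1 + n2
    if (is.null(libSizes))
      libSizes <- round(runif(n, 0.8, 1.2) * 1e6)
    if (any(libSizes <= 0)) stop("zero library size")
    g_ids <- paste0("gene", sprintf("%04d", seq_len(config$nGenes)))
    mu <- exp(rnorm(config$nGenes, log(100), 1))
    p <- mu / sum(mu)
    if (is.null(deGenes)) {
      n_de <- round(config$deFraction * config$nGenes)
      de_idx <- if (n_de > 0) sample.int(config$nGenes, n_de)
                else integer(0)
      sign_de <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE)
                 else numeric(0)
    } else {
      de_idx <- match(deGenes, g_ids)
      if (anyNA(de_idx)) stop("unknown deGenes id(s)")
      sign_de <- if (is.null(deSigns))
        sample(c(-1, 1), length(de_idx), replace = TRUE) else deSigns
      if (length(sign_de) != length(de_idx))
        stop("deSigns must match deGenes")
    }
    fc2 <- rep(1, config$nGenes)
    fc2[de_idx] <- 2^(sign_de * config$deLog2fc)
    group <- rep(contrast, times = c(n1, n2))
    sample_id <- paste0(group, "_", c(seq_len(n1), seq_len(n2)))
    counts <- matrix(0L, config$nGenes, n,
                     dimnames = list(g_ids, sample_id))
    for (s in seq_len(n)) {
      m <- libSizes[s] * p * (if (group[s] == contrast[2]) fc2 else 1)
      counts[, s] <- .rnb(config$nGenes, m, config$nbDispersion)
    }
    truth <- data.frame(gene = g_ids[de_idx],
                        log2fc = sign_de * config$deLog2fc,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$gene), , drop = FALSE]
    rownames(truth) <- NULL
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(sample = sample_id, group = group,
                                     row.names = sample_id))
    list(se = se, truth = truth)
  })
}
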