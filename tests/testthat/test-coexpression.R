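test_that("expression filter keeps genes reaching the floor in any sample", {
  m <- rbind(allLow = rep(5, 4), oneHigh = c(0, 0, 25, 0),
             border = rep(20, 4))
  colnames(m) <- paste0("s", 1:4)
  out <- filterExpressed(m, 20)
  expect_setequal(rownames(out), c("oneHigh", "border"))
  expect_equal(colnames(out), colnames(m))
  expect_equal(filterExpressed(m, 0), m)
  expect_error(filterExpressed(m, 100), "no genes")
  ## SummarizedExperiment in, SummarizedExperiment out
  se <- SummarizedExperiment::SummarizedExperiment(list(fpkm = m))
  expect_s4_class(filterExpressed(se, 20), "SummarizedExperiment")
  expect_equal(nrow(filterExpressed(se, 20)), 2)
})

test_that("soft-threshold diagnostics: connectivity monotone, fit improves on planted data", {
  set.seed(5)
  m <- matrix(2^rnorm(80 * 10, 6), 80, 10,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:10)))
  st <- softThresholdDiagnostic(m, powers = c(1, 2, 6, 14))
  expect_true(all(diff(st$meanK) < 0))
  fx <- plantedFixture()
  stf <- softThresholdDiagnostic(fx$fm, powers = c(1, 14))
  expect_gt(stf$fitR2[stf$power == 14], stf$fitR2[stf$power == 1])
  expect_error(softThresholdDiagnostic(m[, 1:3]), ">= 4 samples")
})

test_that("adjacency powers correlations; TOM matches the triple-loop formula", {
  ## exact r = 0.8 pair by construction
  q <- orthoBasis(20, 2, seed = 4)
  x <- q[, 1]
  y <- 0.8 * q[, 1] + 0.6 * q[, 2]
  m <- rbind(g1 = x, g2 = y, g3 = q[, 2])
  at <- adjacencyTom(m, beta = 14)
  expect_equal(at$adjacency["g1", "g2"], 0.8^14, tolerance = 1e-10)
  expect_equal(at$adjacency["g1", "g1"], 1)
  ## identical profiles: adjacency 1 at any power
  dup <- rbind(a = x, b = x)
  expect_equal(adjacencyTom(rbind(dup, c = q[, 2]), 7)$adjacency["a", "b"],
               1, tolerance = 1e-12)
  ## TOM oracle on random matrices
  set.seed(6)
  for (rep in 1:5) {
    mm <- matrix(rnorm(8 * 12), 8, 12,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
    tt <- adjacencyTom(mm, beta = sample(c(2, 6, 14), 1))
    expect_equal(tt$tom, tomOracle(tt$adjacency), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(tt$tom >= 0 & tt$tom <= 1 + 1e-12))
    expect_equal(tt$tom, t(tt$tom))
    expect_equal(diag(tt$tom), rep(1, 8), ignore_attr = TRUE)
  }
  expect_error(adjacencyTom(rbind(const = rep(3, 10), g = rnorm(10)), 14),
               "constant gene")
})

test_that("adjacency and TOM are equivariant under gene and sample reordering", {
  set.seed(7)
  m <- matrix(rnorm(10 * 9), 10, 9,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:9)))
  at <- adjacencyTom(m, 6)
  pg <- sample(10); ps <- sample(9)
  at2 <- adjacencyTom(m[pg, ps], 6)
  expect_equal(at2$tom, at$tom[pg, pg], tolerance = 1e-12)
})

test_that("module detection separates planted blocks and ignores noise", {
  ## two blocks of mutually identical profiles
  set.seed(10)
  p1 <- rnorm(12); p2 <- rnorm(12)
  m <- rbind(matrix(rep(p1, each = 40), 40, 12),
             matrix(rep(p2, each = 40), 40, 12))
  rownames(m) <- paste0("g", sprintf("%02d", 1:80))
  colnames(m) <- paste0("s", 1:12)
  part <- detectModules(adjacencyTom(m, 14)$tom, minModuleSize = 30)
  truth <- rep(c("A", "B"), each = 40)
  expect_equal(length(unique(moduleLabels(part))), 2)
  expect_equal(phragnet:::.adjustedRand(truth, moduleLabels(part)), 1)
  ## labels deterministic: M1 is the block containing the smallest gene id
  expect_equal(unname(moduleLabels(part)[["g01"]]), "M1")

  ## i.i.d. noise: modal outcome over replicates is "no modules"
  none <- vapply(1:100, function(s) {
    set.seed(s)
    nz <- matrix(rnorm(100 * 39), 100, 39,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:39)))
    p <- detectModules(adjacencyTom(nz, 14)$tom, minModuleSize = 30)
    all(moduleLabels(p) == "unassigned")
  }, TRUE)
  expect_gt(mean(none), 0.5)
})

test_that("planted modules are recovered with high agreement", {
  fx <- plantedFixture()
  ari <- phragnet:::.adjustedRand(fx$truth, moduleLabels(fx$part))
  expect_gte(ari, 0.8)
  ## internal ARI helper agrees with the independent mclust implementation
  expect_equal(ari,
               mclust::adjustedRandIndex(fx$truth,
                                         moduleLabels(fx$part)),
               tolerance = 1e-12)
  ## recovery degrades on average as residual noise grows
  aris <- vapply(c(0.5, 1.5, 3), function(ns) {
    f <- plantedFixture(noise = ns)
    phragnet:::.adjustedRand(f$truth, moduleLabels(f$part))
  }, 1)
  expect_true(all(diff(aris) <= 0))
})

test_that("module eigengenes match the leading principal component", {
  ## module of identical profiles: eigengene correlates 1 with each member
  set.seed(12)
  p <- rnorm(10)
  m <- rbind(a = p, b = p, c = p, d = rnorm(10))
  part <- modulePartition(c(a = "M1", b = "M1", c = "M1",
                            d = "unassigned"))
  eig <- moduleEigengenes(m, part)
  expect_equal(unname(cor(eig["M1", ], p)), 1, tolerance = 1e-10)
  expect_equal(sd(eig["M1", ]), 1, tolerance = 1e-12)
  ## 3-gene toy vs dense eigendecomposition of the sample covariance
  m3 <- matrix(rnorm(3 * 8), 3, 8,
               dimnames = list(c("x", "y", "z"), paste0("s", 1:8)))
  p3 <- modulePartition(c(x = "M1", y = "M1", z = "M1"))
  e3 <- moduleEigengenes(m3, p3)["M1", ]
  z <- t(scale(t(m3)))
  ev <- eigen(t(z) %*% z, symmetric = TRUE)$vectors[, 1]
  ev <- ev / sd(ev)
  if (cor(ev, colMeans(z)) < 0) ev <- -ev
  expect_equal(unname(e3), ev, tolerance = 1e-8)
  ## sign contract holds for every detected module of the fixture
  fx <- plantedFixture()
  labs <- moduleLabels(fx$part)
  for (mod in rownames(fx$eig)) {
    zi <- t(scale(t(fx$fm[names(labs)[labs == mod], ])))
    expect_gte(cor(fx$eig[mod, ], colMeans(zi)), 0)
  }
  ## size-1 module: the gene's standardized profile
  p1 <- modulePartition(c(a = "M1", b = "unassigned", c = "unassigned",
                          d = "unassigned"))
  e1 <- moduleEigengenes(m, p1)["M1", ]
  expect_equal(unname(e1), unname(as.numeric(scale(m["a", ]))),
               tolerance = 1e-12)
})

test_that("dual-depth salinity screen applies the |r| > threshold rule at both depths", {
  q <- orthoBasis(24, 4, seed = 13)
  sal1 <- q[, 1]
  sal2 <- 0.9 * q[, 1] + sqrt(1 - 0.81) * q[, 2]
  mk <- function(a1, a2, a3) a1 * q[, 1] + a2 * q[, 2] + a3 * q[, 3]
  eig <- rbind(
    both = mk(0.62, 0, 0.4),            # r = .62 d1; r = .558 d2
    oneDepth = mk(0.60, -0.50, 0.3),    # r = .60 d1; r = .322 d2
    negBoth = -mk(0.70, 0, 0.3),        # r = -.70 / -.63
    none = q[, 4])
  eig <- eig / apply(eig, 1, sd)
  sal <- data.frame(salinity_d1 = sal1, salinity_d2 = sal2)
  scr <- moduleTraitScreen(eig, sal, threshold = 0.5)
  expect_setequal(scr$selected, c("both", "negBoth"))
  expect_equal(nrow(scr$table), 8)
  expect_true(all(scr$table$p >= 0 & scr$table$p <= 1))
  ## raising the threshold never adds modules
  scr2 <- moduleTraitScreen(eig, sal, threshold = 0.65)
  expect_true(all(scr2$selected %in% scr$selected))
  salNA <- sal; salNA$salinity_d2[3] <- NA
  expect_error(moduleTraitScreen(eig, salNA), "missing salinity")
})

test_that("hub screen uses strict kME and GS thresholds", {
  q <- orthoBasis(30, 3, seed = 14)
  e <- q[, 1] / sd(q[, 1])
  trait <- q[, 2]
  genes <- rbind(
    boundary = 0.8 * q[, 1] + 0.6 * q[, 2],   # kME exactly 0.8 -> not hub
    hubGene = 0.85 * q[, 1] + 0.52 * q[, 2] +
      sqrt(1 - 0.85^2 - 0.52^2) * q[, 3],
    lowGS = 0.95 * q[, 1] + 0.1 * q[, 2] + 0.2 * q[, 3])
  m <- genes
  eig <- rbind(M1 = e)
  part <- modulePartition(c(boundary = "M1", hubGene = "M1",
                            lowGS = "M1"))
  hs <- hubGeneScreen(m, eig, part, trait)
  expect_equal(hs$kME[hs$gene == "boundary"], 0.8, tolerance = 1e-10)
  expect_false(hs$hub[hs$gene == "boundary"])   # strict inequality
  expect_true(hs$hub[hs$gene == "hubGene"])
  expect_false(hs$hub[hs$gene == "lowGS"])
  ## unassigned genes are excluded and counted
  part2 <- modulePartition(c(boundary = "M1", hubGene = "M1",
                             lowGS = "unassigned"))
  hs2 <- hubGeneScreen(m, eig, part2, trait)
  expect_false("lowGS" %in% hs2$gene)
  expect_equal(attr(hs2, "nExcluded"), 1L)
})

test_that("most genes of planted salinity modules pass the hub screen at low noise", {
  fx <- plantedFixture(noise = 0.3)
  scr <- moduleTraitScreen(fx$eig, fx$cd)
  expect_true(length(scr$selected) >= 1)
  hs <- hubGeneScreen(fx$fm, fx$eig, fx$part, fx$cd$salinity_d1,
                      modules = scr$selected)
  expect_gte(mean(hs$hub), 0.8)
})
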