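test_that("TMM factors: trivial cases and invariances", {
  set.seed(3)
  base <- matrix(rnbinom(20 * 2, mu = 200, size = 10), 20, 2,
                 dimnames = list(paste0("g", 1:20), c("a", "b")))
  ## identical columns
  same <- cbind(a = base[, 1], b = base[, 1])
  expect_equal(tmmFactors(same), c(1, 1), ignore_attr = TRUE)
  ## pure depth difference: doubled column absorbs into library size
  dep <- cbind(a = base[, 1], b = base[, 1] * 2L)
  expect_equal(tmmFactors(dep), c(1, 1), ignore_attr = TRUE)
  ## shared scaling of all columns leaves factors unchanged
  m <- base; m[1:3, 1] <- m[1:3, 1] * 8L
  expect_equal(tmmFactors(m), tmmFactors(m * 3L), tolerance = 1e-12)
  expect_equal(prod(tmmFactors(m)), 1, tolerance = 1e-12)  # geometric mean
  expect_error(tmmFactors(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("TMM factors match the trim-and-weight formula and edgeR", {
  set.seed(4)
  for (rep in 1:5) {
    m <- matrix(rnbinom(20 * 4, mu = 150, size = 5), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    m[sample(80, 6)] <- 0
    m[1:2, 2] <- m[1:2, 2] + 2000L       # composition outliers
    ref <- 1
    expect_equal(tmmFactors(m, reference = ref), tmmOracle(m, ref),
                 tolerance = 1e-10)
  }
  ## independent cross-check against edgeR's implementation
  set.seed(5)
  m <- matrix(rnbinom(30 * 4, mu = 200, size = 10), 30, 4,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  m[1:3, 1] <- m[1:3, 1] * 8L
  f_edger <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  ## use edgeR's own reference column choice for the comparison
  refcol <- which.min(abs(apply(sweep(m, 2, colSums(m), "/"), 2,
                                quantile, 0.75) -
                            mean(apply(sweep(m, 2, colSums(m), "/"), 2,
                                       quantile, 0.75))))
  expect_equal(tmmFactors(m, reference = refcol), f_edger,
               tolerance = 1e-6)
})

test_that("NB exact test: null gene, swap symmetry, Poisson limit", {
  set.seed(6)
  half <- matrix(rnbinom(30 * 4, mu = 100, size = 10), 30, 4)
  m <- cbind(half, half)                 # both groups identical
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:8))
  grp <- rep(c("A", "B"), each = 4)
  res <- nbExactTest(m, grp, dispersion = 0.1)
  expect_equal(res$log2fc, rep(0, 30))
  expect_equal(res$p, rep(1, 30))
  ## label swap negates log2fc and preserves p
  set.seed(7)
  m2 <- matrix(rnbinom(40 * 8, mu = 80, size = 8), 40, 8,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  r1 <- nbExactTest(m2, grp, dispersion = 0.1)
  ## reorder samples so the former second group becomes the reference
  r2 <- nbExactTest(m2[, c(5:8, 1:4)], grp, dispersion = 0.1)
  expect_equal(r2$log2fc, -r1$log2fc, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  ## dispersion -> 0: p converges to the exact binomial test
  for (cs in list(c(35, 65), c(10, 4), c(0, 7), c(50, 50))) {
    p_nb <- phragnet:::.nbExactP(cs[1], cs[2], 3, 5, 1e-10)
    expect_equal(p_nb, binomOracle(cs[1], sum(cs), 3 / 8),
                 tolerance = 1e-5)
  }
  expect_error(nbExactTest(m2, rep("A", 8)), "exactly 2 groups")
  expect_error(nbExactTest(m2, grp, dispersion = -1), "positive")
})

test_that("null NB simulation is calibrated at the nominal level", {
  sim <- simulateCounts(simConfig(seed = 1, deFraction = 0),
                        nPerGroup = c(5, 5))
  res <- nbExactTest(sim$se,
                     SummarizedExperiment::colData(sim$se)$group)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  set.seed(8)
  p <- runif(100)
  fdr <- bhAdjust(p)
  expect_equal(fdr, bhOracle(p), tolerance = 1e-12)
  expect_true(all(fdr >= 0 & fdr <= 1))
  ## monotone in p-rank
  expect_true(all(diff(fdr[order(p)]) >= -1e-12))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("DEG calling applies strict fold-change and FDR thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    log2fc = c(1.0, 2, -1.2, -0.5, 3),
                    fdr = c(0.001, 0.04, 0.01, 0.001, 0.05))
  deg <- callDegs(res)
  expect_equal(deg$up, "b")              # a: lfc not > 1; e: fdr not < .05
  expect_equal(deg$down, "c")
})

test_that("DEG recovery on the planted fixture is sensitive and precise", {
  sim <- simulateCounts(simConfig(seed = 1), nPerGroup = c(5, 5))
  res <- nbExactTest(sim$se,
                     SummarizedExperiment::colData(sim$se)$group)
  deg <- callDegs(res)
  called <- c(deg$up, deg$down)
  tr <- sim$truth$gene
  expect_gte(length(intersect(called, tr)) / length(tr), 0.8)
  expect_gte(length(intersect(called, tr)) / length(called), 0.9)
  ## planted direction is respected
  up_true <- sim$truth$gene[sim$truth$log2fc > 0]
  expect_gt(mean(deg$up %in% up_true), 0.9)
})

test_that("cross-contrast intersections and the core screen are pure set operations", {
  dl <- list(list(up = c("a", "b", "c"), down = c("x", "y")),
             list(up = c("b", "c"), down = c("y", "z")),
             list(up = c("c", "b"), down = "y"))
  cm <- commonDegs(dl)
  expect_equal(cm$common_up, c("b", "c"))
  expect_equal(cm$common_down, "y")
  expect_equal(commonDegs(list(dl[[1]], list(up = character(0),
                                             down = "y")))$common_up,
               character(0))
  ## brute-force membership check
  set.seed(9)
  sets <- lapply(1:4, function(i)
    list(up = sample(letters, 12), down = sample(LETTERS, 12)))
  cm2 <- commonDegs(sets)
  brute <- sort(Filter(function(g) all(vapply(sets, function(s)
    g %in% s$up, TRUE)), letters))
  expect_equal(cm2$common_up, brute)
  expect_error(commonDegs(list(list(a = 1))), ">= 2 contrasts")
  expect_error(commonDegs(list(list(up = "a"), list(up = "a"))),
               "direction")

  core <- coreGeneScreen(c("a", "b", "c"), "b", c("c", "d"))
  expect_equal(geneSets(core)$core, c("b", "c"))
  expect_true(validObject(core))
  empty <- coreGeneScreen(character(0), "b", "c")
  expect_equal(geneSets(empty)$core, character(0))
  expect_warning(coreGeneScreen(c("q", "r"), "b", "c"), "share no gene")
  ## idempotence / subset invariants
  again <- coreGeneScreen(geneSets(core)$core, "b", c("c", "d"))
  expect_equal(geneSets(again)$core, geneSets(core)$core)
  expect_true(all(geneSets(core)$core %in% c("a", "b", "c")))
})

test_that("core-screen provenance carries module and DE filters", {
  hubTab <- data.frame(gene = c("a", "b"), module = c("M1", "M2"),
                       kME = c(0.9, 0.85), GS = c(0.6, -0.55),
                       hub = c(TRUE, TRUE))
  core <- coreGeneScreen(hubTab, commonUp = "a", commonDown = "b")
  prov <- screenProvenance(core)
  expect_equal(prov$gene, c("a", "b"))
  expect_equal(prov$direction, c("up", "down"))
  expect_equal(prov$module, c("M1", "M2"))
  expect_equal(prov$kME, c(0.9, 0.85))
})
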