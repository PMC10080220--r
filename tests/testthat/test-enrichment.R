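test_that("over-representation p matches explicit enumeration", {
  universe <- paste0("tst:", 1:10)
  pathway <- universe[1:4]
  ## no overlap: P(X >= 0) = 1
  expect_equal(runORA(universe[8:10], pathway[0], universe), 1)
  ## N=10, K=4, n=3, overlap=2: 0.3 + 1/30
  p <- runORA(c(universe[1], universe[2], universe[9]), pathway, universe)
  expect_equal(p, 0.3 + 1 / 30, tolerance = 1e-12)
  expect_equal(p, oracleHyper(2, 4, 3, 10), tolerance = 1e-12)
  ## pathway = universe: degenerate, p = 1
  expect_equal(runORA(universe[1:3], universe, universe), 1)
  expect_error(runORA("tst:1", pathway, character()), "empty universe")
})

test_that("hypergeometric p agrees with enumeration over random small cases", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    x <- sample(max(0, n + K - N):min(K, n), 1)
    expect_equal(spiaPNDE(x, K, n, N), oracleHyper(x, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("GSEA enrichment score and permutation p behave as expected", {
  ## single-gene set at rank 1 of 10: running profile peaks at 1
  st <- makeStats(paste0("tst:", 1:10), log2fc = 10:1, p = rep(0.5, 10))
  st$t <- 10:1
  g <- runGSEAPerm(st, "tst:1", permutations = 199, seed = 1)
  expect_equal(g$es, 1)

  ## set = exact top k of 200 ranked genes: minimal achievable p
  st2 <- makeStats(paste0("tst:", 1:200), log2fc = seq(5, 0.02, length = 200),
                   p = rep(0.5, 200))
  st2$t <- seq(5, 0.02, length = 200)
  g2 <- runGSEAPerm(st2, paste0("tst:", 1:10), permutations = 999, seed = 2)
  expect_lte(g2$p, 2 / 1000)
  expect_gt(g2$es, 0.9)

  ## deterministic under a fixed seed
  g3 <- runGSEAPerm(st2, paste0("tst:", 1:10), permutations = 999, seed = 2)
  expect_identical(g2, g3)

  expect_warning(expect_null(runGSEAPerm(st, "tst:99", 199, 1)),
                 "no measured genes")
})

test_that("GSEA type-I error is near nominal for random gene sets", {
  set.seed(33)
  st <- makeStats(paste0("tst:", 1:150), log2fc = rnorm(150),
                  p = runif(150))
  st$t <- rnorm(150)
  hits <- vapply(1:200, function(i) {
    gs <- sample(st$gene, 12)
    runGSEAPerm(st, gs, permutations = 199, seed = 1000 + i)$p < 0.05
  }, logical(1))
  ## binomial CI around 0.05 for 200 draws
  expect_lte(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("enrichment score matches fgsea's statistic on a shared ranking", {
  set.seed(34)
  st <- makeStats(paste0("tst:", 1:80), log2fc = rnorm(80), p = runif(80))
  st$t <- rnorm(80)
  gs <- sample(st$gene, 10)
  mine <- runGSEAPerm(st, gs, permutations = 199, seed = 5)$es
  ranks <- sort(setNames(st$t, st$gene), decreasing = TRUE)
  ref <- fgsea::calcGseaStat(unname(ranks),
                             match(gs, names(ranks)),
                             gseaParam = 1, scoreType = "std")
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("perturbation propagation solves the signed linear system", {
  ## no DEGs: identically zero
  ch <- makePathway("PC", c("tst:1", "tst:2"),
                    src = "tst:1", tgt = "tst:2", rel = "activation")
  beta <- pathwayBetaMatrices(ch)
  z <- spiaPerturbation(beta, setNames(numeric(0), character(0)))
  expect_true(all(z$PF == 0))
  expect_equal(z$tA, 0)

  ## 2-gene activation chain, dE = (1, 0): PF = (1, 1), tA = 1
  a <- spiaPerturbation(beta, c("tst:1" = 1))
  expect_equal(unname(a$PF), c(1, 1))
  expect_equal(a$tA, 1)

  ## inhibition flips the propagated sign
  inh <- makePathway("PI", c("tst:1", "tst:2"),
                     src = "tst:1", tgt = "tst:2", rel = "inhibition")
  b <- spiaPerturbation(pathwayBetaMatrices(inh), c("tst:1" = 1))
  expect_equal(unname(b$PF["tst:2"]), -1)
  expect_equal(b$tA, -1)
})

test_that("bootstrap pPERT handles degenerate cases and matches a high-rep oracle", {
  ch <- makePathway("PC", c("tst:1", "tst:2"),
                    src = "tst:1", tgt = "tst:2", rel = "activation")
  beta <- pathwayBetaMatrices(ch)
  ## no DEGs in the pathway
  r0 <- spiaPPERT(beta, setNames(numeric(0), character(0)), c(1, -1),
                  c("tst:1", "tst:2"), reps = 200, seed = 1)
  expect_equal(r0$pPERT, 1)
  expect_true(is.na(r0$status))

  ## edgeless pathway: tA identically zero, pPERT 1
  p0 <- pathwayBetaMatrices(makePathway("P0", c("tst:1", "tst:2")))
  re <- spiaPPERT(p0, c("tst:1" = 2), c(2, -1, 1), c("tst:1", "tst:2"),
                  reps = 200, seed = 1)
  expect_equal(re$pPERT, 1)

  expect_error(spiaPPERT(beta, c("tst:1" = 1), 1, "tst:1", reps = 50),
               "at least 200")

  ## 5-gene fixture: 500-rep estimate within 3 MC SEs of a 50000-rep run
  pw <- makePathway("P5", paste0("tst:", 1:5),
                    src = paste0("tst:", c(1, 1, 2, 3)),
                    tgt = paste0("tst:", c(2, 3, 4, 5)),
                    rel = c("activation", "inhibition", "activation",
                            "activation"))
  b5 <- pathwayBetaMatrices(pw)
  de <- c("tst:1" = 1.5, "tst:4" = -0.7)
  pool <- c(1.5, -0.7, 0.9, -1.2, 2.1)
  lo <- spiaPPERT(b5, de, pool, pathwayGenes(pw), reps = 500, seed = 7)
  hi <- spiaPPERT(b5, de, pool, pathwayGenes(pw), reps = 50000, seed = 8)
  se <- sqrt(hi$pPERT * (1 - hi$pPERT) / 500)
  expect_lt(abs(lo$pPERT - hi$pPERT), 3 * se + 1 / 500)
})

test_that("Fisher combination equals the chi-square(4) survival function", {
  expect_equal(combineFisher(1, 1), 1)
  expect_equal(combineFisher(0.1, 0.1), 0.01 * (1 - log(0.01)),
               tolerance = 1e-12)
  grid <- expand.grid(a = c(0.001, 0.01, 0.1, 0.5, 0.9, 1),
                      b = c(0.005, 0.05, 0.3, 0.7, 1))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]
    expect_equal(combineFisher(a, b),
                 pchisq(-2 * log(a * b), df = 4, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(combineFisher(a, b), combineFisher(b, a))
    expect_gte(combineFisher(a, b), a * b)
  }
  ## increasing in each argument
  expect_true(all(diff(combineFisher(c(0.01, 0.05, 0.2, 0.8), 0.3)) > 0))
  expect_warning(combineFisher(0, 0.5), "clamped")
})

test_that("BH and Bonferroni agree with the exhaustive step-up reference", {
  expect_equal(adjustPValues(0.03, "BH"), 0.03)
  expect_equal(adjustPValues(0.03, "Bonferroni"), 0.03)
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(35)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    bh <- adjustPValues(p, "BH")
    expect_equal(bh, oracleBH(p), tolerance = 1e-12)
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bh <= adjustPValues(p, "Bonferroni") + 1e-12))
  }
})

test_that("method dispatch yields uniform, seeded, reproducible tables", {
  fix <- makeFixture(seed = 41, nPathways = 10, sizeRange = c(5, 10))
  st <- fitGeneStats(fix$dataset)
  sc <- computeEdgeScores(st, buildGlobalGraph(fix$collection))
  degs <- selectDEGs(sc, hesThresholds(sc), st, hes = "HES1")

  ora <- runMethod(list(method_id = "ORA"), st, degs, fix$collection)
  measured <- vapply(fix$collection, function(pw) {
    length(intersect(pathwayGenes(pw), st$gene)) > 0
  }, logical(1))
  expect_equal(nrow(ora), sum(measured))
  expect_false(is.unsorted(ora$pG))

  ## EXTERNAL tables pass through verbatim
  tab <- data.frame(pathway_id = ora$pathway_id[1:3], p = c(0.2, 0.01, 0.8))
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(
    ext <- runMethod(list(method_id = "EXTERNAL:demo", externalTable = f),
                     st, degs, fix$collection),
    "absent")
  expect_equal(nrow(ext), 3L)
  expect_setequal(ext$pG, tab$p)

  ## SPIA under a fixed seed is byte-identical across runs
  s1 <- runMethod(list(method_id = "SPIA", reps = 200, seed = 9),
                  st, degs, fix$collection)
  s2 <- runMethod(list(method_id = "SPIA", reps = 200, seed = 9),
                  st, degs, fix$collection)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "methodSpec")$seed, 9)

  ## adjusted p-values dominate the raw ones
  expect_true(all(s1$pGFdr >= s1$pG - 1e-12, na.rm = TRUE))
})
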