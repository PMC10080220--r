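test_that("ground truth is KO-gene membership, independent of results", {
  fix <- makeFixture(seed = 51)
  truth <- buildGroundTruth(fix$collection, "syn:1")
  expect_equal(sum(truth), 21L)   # round(0.7 * 30)
  expect_equal(sum(!truth), 9L)

  ## union semantics over multiple KO genes
  other <- setdiff(pathwayGenes(fix$collection[[which(!truth)[1]]]), "syn:1")[1]
  t2 <- buildGroundTruth(fix$collection, c("syn:1", other))
  expect_gt(sum(t2), sum(truth) - 1L)

  expect_error(buildGroundTruth(fix$collection, "syn:99999"),
               "no positive class")
})

test_that("confusion classification thresholds the chosen p column", {
  truth <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE)
  res <- data.frame(pathway_id = c("A", "B", "C", "D"),
                    pG = c(0.001, 0.02, 0.004, 0.9))
  cc <- classifyConfusion(res, truth, alpha = 0.005, pField = "pG")
  expect_equal(cc[c("TPKO", "FNKO", "FPKO", "TNKO")],
               list(TPKO = 1L, FNKO = 1L, FPKO = 1L, TNKO = 1L),
               ignore_attr = TRUE)

  ## all p = 1: nothing reported significant
  res1 <- data.frame(pathway_id = names(truth), pG = rep(1, 4))
  c1 <- classifyConfusion(res1, truth, alpha = 0.005)
  expect_equal(c1$TPKO + c1$FPKO, 0L)
  expect_equal(c1$FNKO, 2L); expect_equal(c1$TNKO, 2L)

  ## missing pathways default to p = 1
  cm <- classifyConfusion(res[1:2, ], truth, alpha = 0.005)
  expect_equal(cm$TNKO, 2L)

  ## conservation at every alpha
  for (a in c(0.001, 0.01, 0.05, 0.5)) {
    cc <- classifyConfusion(res, truth, alpha = a)
    expect_equal(cc$TPKO + cc$FPKO + cc$TNKO + cc$FNKO, 4L)
  }
})

test_that("confusion metrics evaluate the rate formulas exactly", {
  m <- computeMetrics(list(TPKO = 3, FPKO = 1, TNKO = 5, FNKO = 1))
  expect_equal(unname(m["FDR"]), 0.25)
  expect_equal(unname(m["FPR"]), 1 / 6)
  expect_equal(unname(m["FNR"]), 0.25)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 5 / 6)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)

  z <- computeMetrics(list(TPKO = 0, FPKO = 0, TNKO = 5, FNKO = 2))
  expect_true(is.na(z["FDR"])); expect_true(is.na(z["precision"]))

  perfect <- computeMetrics(list(TPKO = 4, FPKO = 0, TNKO = 6, FNKO = 0))
  expect_equal(unname(perfect[c("accuracy", "precision", "recall")]),
               c(1, 1, 1))
})

test_that("trapezoidal AUC equals pair-counting concordance", {
  truth <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  res <- data.frame(pathway_id = names(truth),
                    pG = c(0.001, 0.2, 0.05, 0.5))
  cv <- buildROC(res, truth)
  expect_equal(aucValue(cv), 0.75)
  expect_equal(aucValue(cv), oracleAUCPairs(res$pG, truth))

  ## perfect separation and the all-tie curve
  resP <- data.frame(pathway_id = names(truth), pG = c(0.01, 0.02, 0.5, 0.9))
  expect_equal(aucValue(buildROC(resP, truth)), 1)
  resT <- data.frame(pathway_id = names(truth), pG = rep(0.3, 4))
  expect_equal(aucValue(buildROC(resT, truth)), 0.5)

  ## random fixtures with heavy ties, up to 500 pathways
  set.seed(61)
  for (i in 1:10) {
    n <- sample(10:500, 1)
    tr <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE,
                          prob = c(0.6, 0.4)), paste0("p", 1:n))
    if (!any(tr) || all(tr)) next
    p <- round(runif(n), 2)
    r <- data.frame(pathway_id = names(tr), pG = p)
    expect_equal(aucValue(buildROC(r, tr)), oracleAUCPairs(p, tr),
                 tolerance = 1e-10)
  }
  expect_error(buildROC(res, c(a = TRUE, b = TRUE, c = TRUE, d = TRUE)),
               "no negative class")
})

test_that("AUC agrees with pROC on a random fixture", {
  set.seed(62)
  tr <- c(rep(TRUE, 25), rep(FALSE, 15))
  p <- round(runif(40), 2)
  res <- data.frame(pathway_id = paste0("p", 1:40), pG = p)
  cv <- buildROC(res, setNames(tr, res$pathway_id))
  ref <- pROC::roc(response = tr, predictor = p, direction = ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(aucValue(cv), as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("partial AUCs follow the region geometry and McClish correction", {
  truth <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  resP <- data.frame(pathway_id = names(truth), pG = c(0.01, 0.02, 0.5, 0.9))
  perfect <- buildROC(resP, truth)
  expect_equal(partialAUC(perfect, "SP"), 0.1)
  expect_equal(partialAUC(perfect, "SE"), 0.1)
  expect_equal(partialAUC(perfect, "SP", corrected = TRUE), 1)
  expect_equal(partialAUC(perfect, "SE", corrected = TRUE), 1)

  resT <- data.frame(pathway_id = names(truth), pG = rep(0.3, 4))
  chance <- buildROC(resT, truth)
  expect_equal(partialAUC(chance, "SP"), 0.005)
  expect_equal(partialAUC(chance, "SE"), 0.005)
  expect_equal(partialAUC(chance, "SP", corrected = TRUE), 0.5)
  expect_equal(partialAUC(chance, "SE", corrected = TRUE), 0.5)

  ## fine-grid numeric integration oracle on the AUC = 0.75 example
  res <- data.frame(pathway_id = names(truth),
                    pG = c(0.001, 0.2, 0.05, 0.5))
  cv <- buildROC(res, truth)
  pts <- rocPoints(cv)
  x <- 1 - pts$specificity; y <- pts$sensitivity
  ## best sensitivity attainable at false-positive rate <= f, Riemann sum
  grid <- seq(0, 0.1, length.out = 20001)
  fy <- vapply(grid, function(f) max(y[x <= f]), numeric(1))
  oracle <- sum(diff(grid) * (head(fy, -1) + fy[-1]) / 2)
  expect_equal(partialAUC(cv, "SP"), oracle, tolerance = 1e-4)
})

test_that("Youden threshold maximizes J with the documented tie rules", {
  truth <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  resP <- data.frame(pathway_id = names(truth), pG = c(0.01, 0.02, 0.5, 0.9))
  y <- youdenThreshold(buildROC(resP, truth))
  expect_equal(y$specificity, 1); expect_equal(y$sensitivity, 1)
  expect_gt(y$p_threshold, 0.02); expect_lt(y$p_threshold, 0.5)
  expect_equal(y$p_threshold, (0.02 + 0.5) / 2)

  ## J tie between two thresholds resolves to the higher-specificity one
  res <- data.frame(pathway_id = names(truth),
                    pG = c(0.001, 0.2, 0.05, 0.5))
  cv <- buildROC(res, truth)
  yt <- youdenThreshold(cv)
  expect_equal(yt$J, 1.5)
  expect_equal(yt$specificity, 1)
  expect_gt(yt$p_threshold, 0.001); expect_lt(yt$p_threshold, 0.05)

  ## the returned point lies on the curve and dominates all others
  pts <- rocPoints(cv)
  expect_true(any(pts$specificity == yt$specificity &
                    pts$sensitivity == yt$sensitivity))
  expect_true(all(pts$specificity + pts$sensitivity <= yt$J + 1e-12))

  ## all-tie curve: J = 1 attained at the boundary
  resT <- data.frame(pathway_id = names(truth), pG = rep(0.3, 4))
  ya <- youdenThreshold(buildROC(resT, truth))
  expect_equal(ya$J, 1)
  expect_equal(ya$specificity, 1)
})

test_that("stratified bootstrap CIs are sane, stable and cover", {
  truth <- c(rep(TRUE, 12), rep(FALSE, 12))
  names(truth) <- paste0("p", 1:24)
  ## perfect separation with a wide margin: degenerate CI at 1
  res <- data.frame(pathway_id = names(truth),
                    pG = c(runif(12, 0, 0.01), runif(12, 0.9, 1)))
  cv <- buildROC(res, truth)
  ci <- bootstrapCI(cv, "AUC", B = 300, seed = 3)
  expect_equal(ci, c(1, 1))

  ## reproducible under seed; stable in B
  set.seed(63)
  res2 <- data.frame(pathway_id = names(truth),
                     pG = c(runif(12, 0, 0.4), runif(12, 0.2, 1)))
  cv2 <- buildROC(res2, truth)
  expect_identical(bootstrapCI(cv2, "AUC", B = 300, seed = 4),
                   bootstrapCI(cv2, "AUC", B = 300, seed = 4))
  c500 <- bootstrapCI(cv2, "AUC", B = 500, seed = 5)
  c5000 <- bootstrapCI(cv2, "AUC", B = 5000, seed = 6)
  expect_lt(max(abs(c500 - c5000)), 0.05)

  ## coverage under a binormal generator with true AUC 0.8
  mu <- sqrt(2) * qnorm(0.8)
  cover <- vapply(1:60, function(r) {
    set.seed(700 + r)
    p <- pnorm(c(rnorm(40, mu), rnorm(40))) # smaller p for positives
    p <- 1 - p
    tr <- setNames(c(rep(TRUE, 40), rep(FALSE, 40)), paste0("q", 1:80))
    rr <- data.frame(pathway_id = names(tr), pG = p)
    ci <- bootstrapCI(buildROC(rr, tr), "AUC", B = 200, seed = r)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  ## Youden operating point gets per-coordinate CIs
  pt <- bootstrapCI(cv2, "point", B = 200, seed = 7)
  expect_equal(dim(pt), c(2L, 2L))
  expect_true(all(pt >= 0 & pt <= 1))
})

test_that("paired curve comparisons detect differences and respect symmetry", {
  set.seed(64)
  tr <- setNames(c(rep(TRUE, 20), rep(FALSE, 20)), paste0("p", 1:40))
  pa <- c(runif(20, 0, 0.3), runif(20, 0.1, 1))
  res <- data.frame(pathway_id = names(tr), pG = pa)
  cv <- buildROC(res, tr)

  ## a curve against itself: no difference
  expect_equal(compareROCs(cv, cv, "bootstrap", B = 200, seed = 1), 1)
  expect_equal(compareROCs(cv, cv, "venkatraman", B = 200, seed = 1), 1)

  ## two-sided p unchanged under swapping the curves
  pb <- c(runif(20, 0, 0.6), runif(20, 0.05, 1))
  cvb <- buildROC(data.frame(pathway_id = names(tr), pG = pb), tr)
  expect_equal(compareROCs(cv, cvb, "bootstrap", B = 300, seed = 2),
               compareROCs(cvb, cv, "bootstrap", B = 300, seed = 2))

  ## unpaired inputs are rejected
  tr2 <- setNames(c(rep(TRUE, 19), rep(FALSE, 21)), paste0("p", 1:40))
  cv2 <- buildROC(data.frame(pathway_id = names(tr2), pG = pb), tr2)
  expect_error(compareROCs(cv, cv2), "unpaired")

  ## power: strong method vs a random one on 40 pathways
  hits <- vapply(1:30, function(r) {
    set.seed(800 + r)
    strong <- c(runif(20, 0, 0.05), runif(20, 0.3, 1))
    rand <- runif(40)
    ca <- buildROC(data.frame(pathway_id = names(tr), pG = strong), tr)
    cb <- buildROC(data.frame(pathway_id = names(tr), pG = rand), tr)
    compareROCs(ca, cb, "bootstrap", B = 200, seed = r) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
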