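#' Knockout ground truth over a pathway collection
#'
#' A pathway is a true KO pathway iff its gene set contains any of the
#' knocked-out genes; the label is independent of any method's output.
#'
#' @param collection named list of \linkS4class{PathwayGraph} objects.
#' @param koGenes knocked-out gene id(s).
#' @return named logical vector (pathway id -> contains_ko).
#' @export
buildGroundTruth <- function(collection, koGenes) {
  if (!length(koGenes)) stop("koGenes must be non-empty")
  truth <- vapply(collection, function(pw) {
    length(intersect(pathwayGenes(pw), koGenes)) > 0L
  }, logical(1))
  names(truth) <- vapply(collection, pathwayId, character(1))
  if (!any(truth)) stop("no positive class: KO gene(s) found in no pathway")
  truth
}

#' Confusion classification of pathways at a significance level
#'
#' TPKO: contains the KO gene and p < alpha; FNKO: contains it but
#' p >= alpha; FPKO: does not contain it and p < alpha; TNKO: neither.
#' Pathways in the truth set absent from the results receive the
#' missing-p default (1, i.e. never reported significant).
#'
#' @param results EnrichmentResult data.frame (from \code{\link{runMethod}})
#'   or any data.frame with \code{pathway_id} and the p column.
#' @param truth named logical vector from \code{\link{buildGroundTruth}}.
#' @param alpha significance level in (0, 1).
#' @param pField which p column to threshold (e.g. "pG", "pGFdr").
#' @param missingP p assigned to pathways absent from the results.
#' @return list with integer counts TPKO, FPKO, TNKO, FNKO plus the alpha
#'   and pField used.
#' @export
classifyConfusion <- function(results, truth, alpha = 0.005,
                              pField = "pG", missingP = 1) {
  stopifnot(alpha > 0, alpha < 1)
  p <- results[[pField]][match(names(truth), results$pathway_id)]
  if (anyNA(p)) p[is.na(p)] <- missingP
  sig <- p < alpha
  list(TPKO = sum(truth & sig), FPKO = sum(!truth & sig),
       TNKO = sum(!truth & !sig), FNKO = sum(truth & !sig),
       alpha = alpha, pField = pField)
}

#' Confusion-count metrics
#'
#' FDR, FPR, FNR, sensitivity (TPR), specificity (TNR), accuracy,
#' precision and recall from the four KO confusion counts; 0/0 yields NA.
#'
#' @param counts list from \code{\link{classifyConfusion}}.
#' @return named numeric vector of the eight rates.
#' @export
computeMetrics <- function(counts) {
  rt <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, c(
    FDR = rt(FPKO, FPKO + TPKO),
    FPR = rt(FPKO, FPKO + TNKO),
    FNR = rt(FNKO, FNKO + TPKO),
    sensitivity = rt(TPKO, TPKO + FNKO),
    specificity = rt(TNKO, TNKO + FPKO),
    accuracy = rt(TPKO + TNKO, TPKO + FPKO + TNKO + FNKO),
    precision = rt(TPKO, TPKO + FPKO),
    recall = rt(TPKO, TPKO + FNKO)))
}

#' Knockout ground-truth ROC curve
#'
#' The predictor is a per-pathway p-value (smaller means more positive).
#' Points are evaluated at a sentinel below every p and at each distinct p,
#' so the trapezoidal AUC equals the concordance (pair-counting) statistic
#' with ties contributing half.
#'
#' @inheritParams classifyConfusion
#' @return a \linkS4class{ROCCurve}.
#' @export
buildROC <- function(results, truth, pField = "pG", missingP = 1) {
  if (!any(truth)) stop("no positive class")
  if (all(truth)) stop("no negative class")
  p <- results[[pField]][match(names(truth), results$pathway_id)]
  if (anyNA(p)) p[is.na(p)] <- missingP
  thr <- c(-Inf, sort(unique(p)))
  pos <- p[truth]; neg <- p[!truth]
  sens <- vapply(thr, function(t) mean(pos <= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg > t), numeric(1))
  pts <- data.frame(threshold = thr, specificity = spec,
                    sensitivity = sens)
  fpr <- 1 - pts$specificity
  auc <- sum(diff(fpr) * (head(pts$sensitivity, -1) +
                            pts$sensitivity[-1]) / 2)
  new("ROCCurve", points = pts, auc = auc, p = as.numeric(p),
      truth = unname(truth), pField = pField)
}

## piecewise-linear partial area of y over x restricted to [lo, hi];
## (x, y) must be sorted with x non-decreasing
.clipArea <- function(x, y, lo, hi) {
  area <- 0
  for (i in seq_len(length(x) - 1L)) {
    x1 <- x[i]; x2 <- x[i + 1L]
    if (x2 <= lo || x1 >= hi || x2 == x1) next
    a <- max(x1, lo); b <- min(x2, hi)
    ya <- y[i] + (y[i + 1L] - y[i]) * (a - x1) / (x2 - x1)
    yb <- y[i] + (y[i + 1L] - y[i]) * (b - x1) / (x2 - x1)
    area <- area + (b - a) * (ya + yb) / 2
  }
  area
}

#' Partial AUC over a high-specificity or high-sensitivity region
#'
#' Original form: the trapezoidal area of the curve restricted to
#' specificity (region "SP") or sensitivity (region "SE") in [0.9, 1],
#' using curve inversion for SE. Corrected form: McClish standardization
#' 0.5 (1 + (pAUC - min) / (max - min)) onto [0.5, 1], where min and max
#' are the chance and perfect areas of the region (0.005 and 0.1).
#'
#' @param curve a \linkS4class{ROCCurve}.
#' @param region "SP" (90-100\% specificity) or "SE" (90-100\% sensitivity).
#' @param corrected return the McClish-standardized value.
#' @return the partial area.
#' @export
partialAUC <- function(curve, region = c("SP", "SE"), corrected = FALSE) {
  region <- match.arg(region)
  pts <- rocPoints(curve)
  if (region == "SP") {
    ## integrate sensitivity over FPR in [0, 0.1]
    x <- 1 - pts$specificity; y <- pts$sensitivity
    o <- order(x, y)
    pa <- .clipArea(x[o], y[o], 0, 0.1)
  } else {
    ## invert: max specificity attained at each distinct sensitivity
    s <- pts$sensitivity; sp <- pts$specificity
    us <- sort(unique(s))
    msp <- vapply(us, function(v) max(sp[s == v]), numeric(1))
    pa <- .clipArea(us, msp, 0.9, 1)
  }
  if (!corrected) return(pa)
  minA <- 0.005; maxA <- 0.1
  max(0.5, min(1, 0.5 * (1 + (pa - minA) / (maxA - minA))))
}

#' Youden's best p-value threshold
#'
#' The curve point maximizing specificity + sensitivity; ties resolve to
#' the higher-specificity point, then to the smaller threshold. The
#' returned p-value threshold is the midpoint between the chosen distinct
#' p and the next one above it (the midpoint of the separating gap for a
#' perfectly separated curve).
#'
#' @param curve a \linkS4class{ROCCurve}.
#' @return list(p_threshold, specificity, sensitivity, J).
#' @export
youdenThreshold <- function(curve) {
  pts <- rocPoints(curve)
  J <- pts$specificity + pts$sensitivity
  o <- order(-J, -pts$specificity, pts$threshold)
  best <- pts[o[1L], ]
  pv <- sort(unique(curve@p))
  t0 <- best$threshold
  pthr <- if (is.infinite(t0)) {
    pv[1L] / 2
  } else {
    nxt <- pv[pv > t0]
    if (length(nxt)) (t0 + nxt[1L]) / 2 else (t0 + 1) / 2
  }
  list(p_threshold = pthr, specificity = best$specificity,
       sensitivity = best$sensitivity, J = J[o[1L]])
}

.rocStat <- function(p, truth, target, pField = "p") {
  res <- data.frame(pathway_id = seq_along(p), p = p)
  cv <- buildROC(res, setNames(truth, seq_along(p)), pField = "p")
  switch(target,
         AUC = aucValue(cv),
         pAUC_SP = partialAUC(cv, "SP"),
         pAUC_SE = partialAUC(cv, "SE"),
         point = {
           y <- youdenThreshold(cv)
           c(specificity = y$specificity, sensitivity = y$sensitivity)
         })
}

#' Stratified bootstrap confidence interval for an ROC statistic
#'
#' Positives and negatives are resampled with replacement separately;
#' the 95\% interval is the 2.5/97.5 percentile of the bootstrap
#' distribution. Deterministic under the seed.
#'
#' @param curve a \linkS4class{ROCCurve}.
#' @param target "AUC", "pAUC_SP", "pAUC_SE" or "point" (the Youden
#'   operating point; returns CIs for both coordinates).
#' @param B bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return numeric c(lower, upper), or a 2-row matrix for "point".
#' @export
bootstrapCI <- function(curve, target = c("AUC", "pAUC_SP", "pAUC_SE",
                                          "point"),
                        B = 2000, seed = 1) {
  target <- match.arg(target)
  if (B < 200) stop("need at least 200 bootstrap replicates")
  p <- curve@p; truth <- curve@truth
  ip <- which(truth); ineg <- which(!truth)
  stat <- withSeed(seed, {
    reps <- lapply(seq_len(B), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      .rocStat(p[idx], truth[idx], target)
    })
    do.call(rbind, reps)
  })
  if (target == "point") {
    t(apply(stat, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  } else {
    quantile(stat[, 1], probs = c(0.025, 0.975), names = FALSE)
  }
}

#' Paired statistical comparison of two ROC curves
#'
#' Both curves must be built on the same pathways and truth labels.
#' \code{test = "bootstrap"}: the paired-bootstrap z test on the difference
#' of an ROC statistic (AUC or a partial AUC). \code{test = "venkatraman"}:
#' a paired permutation test on the integrated absolute difference between
#' the two (rank-based) curves, exchanging the two methods' ranks per
#' pathway with probability 1/2.
#'
#' @param curveA,curveB \linkS4class{ROCCurve} objects on the same truth.
#' @param test "bootstrap" or "venkatraman".
#' @param target statistic for the bootstrap test.
#' @param B replicates / permutations (>= 200).
#' @param seed integer seed.
#' @return two-sided p-value.
#' @export
compareROCs <- function(curveA, curveB, test = c("bootstrap", "venkatraman"),
                        target = c("AUC", "pAUC_SP", "pAUC_SE"),
                        B = 2000, seed = 1) {
  test <- match.arg(test); target <- match.arg(target)
  if (B < 200) stop("need at least 200 replicates")
  if (length(curveA@truth) != length(curveB@truth) ||
      !all(curveA@truth == curveB@truth)) {
    stop("unpaired curves: truth labels differ")
  }
  truth <- curveA@truth
  pa <- curveA@p; pb <- curveB@p
  if (test == "bootstrap") {
    obs <- .rocStat(pa, truth, target) - .rocStat(pb, truth, target)
    ip <- which(truth); ineg <- which(!truth)
    diffs <- withSeed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- c(sample(ip, length(ip), replace = TRUE),
                 sample(ineg, length(ineg), replace = TRUE))
        .rocStat(pa[idx], truth[idx], target) -
          .rocStat(pb[idx], truth[idx], target)
      }, numeric(1))
    })
    s <- sd(diffs)
    if (s == 0) return(1)
    2 * pnorm(-abs(obs / s))
  } else {
    ra <- rank(pa); rb <- rank(pb)
    grid <- seq(0, 1, length.out = 4L * length(truth) + 1L)
    sensAt <- function(pp) {
      cv <- buildROC(data.frame(pathway_id = seq_along(pp), p = pp),
                     setNames(truth, seq_along(pp)), pField = "p")
      pts <- rocPoints(cv)
      x <- 1 - pts$specificity; y <- pts$sensitivity
      o <- order(x, y)
      approx(x[o], y[o], xout = grid, ties = max, rule = 2)$y
    }
    E <- function(r1, r2) mean(abs(sensAt(r1) - sensAt(r2)))
    obs <- E(ra, rb)
    perm <- withSeed(seed, {
      vapply(seq_len(B), function(b) {
        swap <- runif(length(ra)) < 0.5
        r1 <- ifelse(swap, rb, ra)
        r2 <- ifelse(swap, ra, rb)
        E(r1, r2)
      }, numeric(1))
    })
    (1 + sum(perm >= obs)) / (B + 1)
  }
}

#' @importFrom stats approx
NULL
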