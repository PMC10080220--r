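#' Full ROC metric set for one dataset x method run
#'
#' Builds the KO ground-truth ROC, finds the Youden best p-value threshold,
#' classifies the pathways at that threshold and returns the local rates
#' together with the global AUC and partial AUCs (original scale; the
#' McClish-corrected values are appended with a \code{_corrected} suffix).
#'
#' @param results EnrichmentResult data.frame.
#' @param truth named logical ground truth.
#' @param pField predictor p-value column (raw method p by default).
#' @return named numeric vector (the per-run metric summary).
#' @export
computeMetricSet <- function(results, truth, pField = "pG") {
  curve <- buildROC(results, truth, pField = pField)
  yd <- youdenThreshold(curve)
  counts <- classifyConfusion(results, truth, alpha = yd$p_threshold,
                              pField = pField)
  c(computeMetrics(counts),
    p_threshold = yd$p_threshold,
    AUC = aucValue(curve),
    pAUC_SP = partialAUC(curve, "SP"),
    pAUC_SE = partialAUC(curve, "SE"),
    pAUC_SP_corrected = partialAUC(curve, "SP", corrected = TRUE),
    pAUC_SE_corrected = partialAUC(curve, "SE", corrected = TRUE))
}

#' Cross-dataset, cross-method benchmark aggregation
#'
#' Takes per-run metric sets in long format and produces the consolidated
#' summary plus pairwise paired Wilcoxon signed-rank p-values per metric
#' and method pair (datasets are the pairing unit). Zero differences are
#' dropped per the signed-rank convention; a pair with no non-zero
#' difference yields NA.
#'
#' @param long data.frame with columns \code{dataset}, \code{method},
#'   \code{metric}, \code{value}.
#' @param alternative passed to \code{wilcox.test} ("two.sided" default).
#' @return list with \code{table} (the long input, ordered), \code{wilcoxon}
#'   (metric, methodA, methodB, n, p) and \code{note} documenting the
#'   zero-difference policy.
#' @export
aggregateBenchmark <- function(long, alternative = "two.sided") {
  need <- c("dataset", "method", "metric", "value")
  if (!all(need %in% names(long))) {
    stop("long table needs columns dataset, method, metric, value")
  }
  methods <- sort(unique(long$method))
  datasets <- sort(unique(long$dataset))
  if (length(methods) < 2L || length(datasets) < 2L) {
    stop("need at least 2 methods and 2 datasets to aggregate")
  }
  long <- long[order(long$metric, long$method, long$dataset), , drop = FALSE]
  rownames(long) <- NULL
  rows <- list()
  for (met in sort(unique(long$metric))) {
    sub <- long[long$metric == met, , drop = FALSE]
    for (i in seq_len(length(methods) - 1L)) {
      for (j in seq(i + 1L, length(methods))) {
        a <- sub$value[match(paste(datasets, methods[i]),
                             paste(sub$dataset, sub$method))]
        b <- sub$value[match(paste(datasets, methods[j]),
                             paste(sub$dataset, sub$method))]
        d <- a - b
        d <- d[!is.na(d) & d != 0]
        p <- if (!length(d)) NA_real_ else {
          suppressWarnings(wilcox.test(d, alternative = alternative)$p.value)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(metric = met, methodA = methods[i],
                     methodB = methods[j], n = length(d), p = p,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(table = long, wilcoxon = do.call(rbind, rows),
       note = "zero differences dropped before the signed-rank test; all-zero pairs give NA")
}

#' Two-dimensional evidence-plot data for topology results
#'
#' Per-pathway coordinates (-ln pNDE, -ln pPERT) with the oblique
#' significance line x + y = -ln c*, where c* solves c (1 - ln c) = pG*
#' and pG* is the largest raw pG still significant at \code{alpha} after
#' the chosen correction. The intercept is NA when nothing is significant.
#'
#' @param results topology-method EnrichmentResult data.frame (pNDE and
#'   pPERT present).
#' @param alpha significance level for the line (default 0.05).
#' @param correction "BH" or "Bonferroni".
#' @return list(points, intercept, alpha, correction).
#' @export
evidencePlotData <- function(results, alpha = 0.05,
                             correction = c("BH", "Bonferroni")) {
  correction <- match.arg(correction)
  if (all(is.na(results$pNDE)) || all(is.na(results$pPERT))) {
    stop("evidence plots require topology results with pNDE and pPERT")
  }
  ok <- !is.na(results$pNDE) & !is.na(results$pPERT)
  res <- results[ok, , drop = FALSE]
  adj <- adjustPValues(res$pG, correction)
  sig <- adj <= alpha
  intercept <- NA_real_
  if (any(sig)) {
    pgStar <- max(res$pG[sig])
    cstar <- uniroot(function(cc) cc - cc * log(cc) - pgStar,
                     lower = .Machine$double.xmin, upper = 1,
                     tol = 1e-12)$root
    intercept <- -log(cstar)
  }
  pts <- data.frame(pathway_id = res$pathway_id,
                    x = -log(res$pNDE), y = -log(res$pPERT),
                    significant = sig, stringsAsFactors = FALSE)
  list(points = pts, intercept = intercept, alpha = alpha,
       correction = correction)
}
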