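#' Per-gene moderated statistics for a KO vs. control contrast
#'
#' Computes the per-gene log2 fold-change (KO minus control mean) and a
#' two-sided p-value. With \code{moderation = "eb"} the variance is
#' empirical-Bayes shrunken via limma (\code{lmFit}/\code{eBayes}):
#' s2_post = (d0 s0^2 + d s^2) / (d0 + d) with the prior (d0, s0^2)
#' estimated from the cross-gene variance distribution. With
#' \code{moderation = "off"} the ordinary pooled-variance two-sample t is
#' computed in closed form. \code{d0} overrides the estimated prior degrees
#' of freedom (Inf collapses every posterior variance onto s0^2).
#'
#' Genes with any missing value are dropped before fitting (count reported
#' via a message).
#'
#' @param dataset a \linkS4class{KODataset}.
#' @param moderation "eb" (default) or "off".
#' @param d0 optional prior degrees of freedom overriding the estimate.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{t},
#'   \code{p}, \code{df}, \code{s2post}.
#' @export
fitGeneStats <- function(dataset, moderation = c("eb", "off"), d0 = NULL) {
  moderation <- match.arg(moderation)
  mat <- exprsMatrix(dataset)
  groups <- sampleGroups(dataset)
  keep <- rowSums(is.na(mat)) == 0L
  if (any(!keep)) {
    message(sum(!keep), " gene(s) with missing values dropped before fitting")
    mat <- mat[keep, , drop = FALSE]
  }
  if (!nrow(mat)) stop("no complete genes to fit")
  ko <- groups == "KO"
  vKO <- apply(mat[, ko, drop = FALSE], 1, var)
  vCT <- apply(mat[, !ko, drop = FALSE], 1, var)
  if (max(vKO) == 0 || max(vCT) == 0) {
    stop("a group has zero variance for every gene; cannot fit")
  }
  if (nrow(mat) == 1L && moderation == "eb") {
    warning("single gene: moderation disabled")
    moderation <- "off"
  }
  n1 <- sum(ko); n2 <- sum(!ko)
  log2fc <- rowMeans(mat[, ko, drop = FALSE]) -
    rowMeans(mat[, !ko, drop = FALSE])

  if (moderation == "off") {
    s2 <- ((n1 - 1) * vKO + (n2 - 1) * vCT) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    t <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                log2fc / se)
    df <- n1 + n2 - 2
    p <- 2 * pt(-abs(t), df)
    return(data.frame(gene = rownames(mat), log2fc = log2fc, t = t, p = p,
                      df = df, s2post = s2, row.names = NULL,
                      stringsAsFactors = FALSE))
  }

  design <- cbind(CTRL = 1, KOvsCTRL = as.numeric(ko))
  fit <- limma::lmFit(mat, design)
  if (is.null(d0)) {
    eb <- limma::eBayes(fit)
    res <- data.frame(gene = rownames(mat),
                      log2fc = fit$coefficients[, "KOvsCTRL"],
                      t = eb$t[, "KOvsCTRL"],
                      p = eb$p.value[, "KOvsCTRL"],
                      df = eb$df.total, s2post = eb$s2.post,
                      row.names = NULL, stringsAsFactors = FALSE)
    return(res)
  }
  ## explicit prior df: keep limma's moment-matched prior variance
  sq <- limma::squeezeVar(fit$sigma^2, fit$df.residual)
  s02 <- sq$var.prior
  d <- fit$df.residual
  s2post <- if (is.infinite(d0)) rep(s02, length.out = nrow(mat))
            else (d0 * s02 + d * fit$sigma^2) / (d0 + d)
  se <- fit$stdev.unscaled[, "KOvsCTRL"] * sqrt(s2post)
  t <- log2fc / se
  df <- d + d0
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df)
  data.frame(gene = rownames(mat), log2fc = log2fc, t = t, p = p,
             df = df, s2post = s2post, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Edge scores over the global graph
#'
#' For two measured genes X, Y joined by an (undirected) global-graph edge,
#' the edge score is |FC_X| (1 - pX) + |FC_Y| (1 - pY), with |FC| the log2
#' fold-change magnitude and p the moderated-t p-value. Edges with an
#' unmeasured endpoint are skipped (count in attribute \code{skipped}).
#'
#' @param stats data.frame from \code{\link{fitGeneStats}}.
#' @param graph a \linkS4class{GlobalGraph}.
#' @return data.frame (geneX, geneY, score), sorted by descending score
#'   with ties broken by canonical pair order.
#' @export
computeEdgeScores <- function(stats, graph) {
  keys <- undirectedEdgeKeys(graph)
  ix <- match(keys$geneX, stats$gene)
  iy <- match(keys$geneY, stats$gene)
  ok <- !is.na(ix) & !is.na(iy)
  skipped <- sum(!ok)
  if (!any(ok)) stop("no scorable edges: graph and measured genes are disjoint")
  keys <- keys[ok, , drop = FALSE]; ix <- ix[ok]; iy <- iy[ok]
  score <- abs(stats$log2fc[ix]) * (1 - stats$p[ix]) +
           abs(stats$log2fc[iy]) * (1 - stats$p[iy])
  out <- data.frame(geneX = keys$geneX, geneY = keys$geneY, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$geneX, out$geneY), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Single change point of a descending score sequence
#'
#' At-most-one-change mean-shift: the split minimizing the total
#' within-segment sum of squared deviations, i.e. the point after which the
#' descending-sorted edge-score curve becomes flat. Returns the number of
#' scores in the elevated (left) segment, which is also the 0-based index
#' of the first score of the flat segment. SSE ties resolve to the smallest
#' split.
#'
#' @param scores numeric vector (sorted descending internally) or the
#'   edge-score table from \code{\link{computeEdgeScores}}.
#' @param method change-point engine; only \code{"amoc"} is provided.
#' @return integer change-point index in [1, n - 1].
#' @export
detectChangepoint <- function(scores, method = "amoc") {
  method <- match.arg(method, "amoc")
  y <- if (is.data.frame(scores)) scores$score else scores
  y <- sort(y, decreasing = TRUE)
  n <- length(y)
  if (n < 4L) stop("need at least 4 scores for change-point detection")
  if (max(y) == min(y)) stop("degenerate distribution: all scores equal")
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  k <- seq_len(n - 1L)
  sseL <- cs2[k] - cs[k]^2 / k
  sseR <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  as.integer(which.min(sseL + sseR))
}

#' High-edge-score (HES) thresholds from a change point
#'
#' Given the descending-sorted scores and the change point, HES1 is the
#' least elevated score (the lower boundary of the change point), HES3 the
#' maximal score, and HES2 the score at rank ceiling(0.75 k) among the k
#' elevated scores — a 25\% safety margin that drops the lowest quartile of
#' elevated edges. \code{rule = "scaled"} instead sets HES2 = 1.25 * HES1
#' (capped at HES3).
#'
#' @param scores numeric vector or edge-score table.
#' @param changepointIndex integer from \code{\link{detectChangepoint}}.
#' @param rule "rank" (default) or "scaled" HES2 rule.
#' @return a \linkS4class{HESThresholds}.
#' @export
deriveHesThresholds <- function(scores, changepointIndex,
                                rule = c("rank", "scaled")) {
  rule <- match.arg(rule)
  y <- if (is.data.frame(scores)) scores$score else scores
  y <- sort(y, decreasing = TRUE)
  n <- length(y)
  k <- as.integer(changepointIndex)
  if (k < 1L || k > n - 1L) stop("changepointIndex out of range")
  if (k == 1L) {
    warning("single elevated score: HES1 = HES2 = HES3")
    return(new("HESThresholds", hes1 = y[1], hes2 = y[1], hes3 = y[1],
               changepointIndex = 1L, nScores = as.integer(n)))
  }
  h1 <- y[k]
  h3 <- y[1]
  h2 <- if (rule == "rank") y[ceiling(0.75 * k)] else min(1.25 * h1, h3)
  new("HESThresholds", hes1 = h1, hes2 = h2, hes3 = h3,
      changepointIndex = k, nScores = as.integer(n))
}

#' Fit HES thresholds directly from an edge-score table
#'
#' Convenience wrapper: change-point detection followed by
#' \code{\link{deriveHesThresholds}}.
#'
#' @inheritParams deriveHesThresholds
#' @export
hesThresholds <- function(scores, rule = c("rank", "scaled")) {
  deriveHesThresholds(scores, detectChangepoint(scores),
                      rule = match.arg(rule))
}

#' Select differentially expressed genes at an edge-score threshold
#'
#' DEGs are the unique endpoints of every edge scoring at or above the
#' threshold, ranked by each gene's maximal qualifying incident edge score
#' (descending; ties broken by canonical gene id).
#'
#' @param scores edge-score table from \code{\link{computeEdgeScores}}.
#' @param threshold numeric score cutoff, or a
#'   \linkS4class{HESThresholds} plus \code{hes} selecting which cutoff.
#' @param stats gene statistics carried onto the DEG table.
#' @param hes which HES cutoff to use when \code{threshold} is a
#'   \linkS4class{HESThresholds} ("HES1", "HES2" or "HES3").
#' @return a \linkS4class{DEGSet}.
#' @export
selectDEGs <- function(scores, threshold, stats = NULL, hes = "HES1") {
  used <- "explicit"
  if (is(threshold, "HESThresholds")) {
    hes <- match.arg(hes, c("HES1", "HES2", "HES3"))
    used <- hes
    threshold <- switch(hes, HES1 = hes1(threshold), HES2 = hes2(threshold),
                        HES3 = hes3(threshold))
  }
  q <- scores[scores$score >= threshold, , drop = FALSE]
  if (!nrow(q)) {
    tab <- data.frame(gene = character(), log2fc = numeric(), p = numeric(),
                      bestEdgeScore = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
    return(new("DEGSet", table = tab, thresholdUsed = used,
               thresholdValue = threshold))
  }
  long <- data.frame(gene = c(q$geneX, q$geneY),
                     score = c(q$score, q$score), stringsAsFactors = FALSE)
  best <- tapply(long$score, long$gene, max)
  tab <- data.frame(gene = names(best), bestEdgeScore = as.numeric(best),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$bestEdgeScore, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(stats)) {
    i <- match(tab$gene, stats$gene)
    tab$log2fc <- stats$log2fc[i]
    tab$p <- stats$p[i]
  } else {
    tab$log2fc <- NA_real_; tab$p <- NA_real_
  }
  tab <- tab[, c("gene", "log2fc", "p", "bestEdgeScore", "rank")]
  rownames(tab) <- NULL
  new("DEGSet", table = tab, thresholdUsed = used, thresholdValue = threshold)
}

#' Extract the KO-gene-associated subnetwork
#'
#' The subgraph of the global graph induced on the DEG set: every directed
#' edge with both endpoints among the selected genes, with per-node
#' annotations (log2fc, p, rank) carried along.
#'
#' @param degs a \linkS4class{DEGSet}.
#' @param graph a \linkS4class{GlobalGraph}.
#' @return list with elements \code{graph} (induced
#'   \linkS4class{GlobalGraph}) and \code{nodes} (annotation data.frame).
#' @export
extractKoSubnetwork <- function(degs, graph) {
  gset <- degGenes(degs)
  ed <- pathwayEdges(graph)
  keep <- ed$source %in% gset & ed$target %in% gset
  sub <- new("GlobalGraph", genes = sort(gset),
             edges = { e <- ed[keep, , drop = FALSE]; rownames(e) <- NULL; e })
  list(graph = sub, nodes = degTable(degs))
}
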