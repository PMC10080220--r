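#' @import methods
NULL

#' PathwayGraph: a signed directed gene-interaction graph for one pathway
#'
#' Holds the gene set and signed relation edges parsed from one KGML file.
#' Edge endpoints are organism-prefixed gene identifiers; the \code{sign}
#' column is the configured mapping of the KGML relation subtype onto
#' \{-1, 0, +1\}.
#'
#' @slot pathwayId KEGG-style identifier, e.g. \code{"mmu04620"}.
#' @slot pathwayName display title.
#' @slot organism organism prefix, e.g. \code{"mmu"}.
#' @slot genes character vector of member gene ids (the all-genes pSize).
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{relation}, \code{sign}.
#' @exportClass PathwayGraph
setClass("PathwayGraph",
  representation(pathwayId = "character", pathwayName = "character",
                 organism = "character", genes = "character",
                 edges = "data.frame"),
  prototype(pathwayId = NA_character_, pathwayName = "", organism = "",
            genes = character(), edges = emptyEdgeFrame()))

setValidity("PathwayGraph", function(object) {
  msg <- character()
  if (length(object@pathwayId) != 1L || is.na(object@pathwayId) ||
      !nzchar(object@pathwayId))
    msg <- c(msg, "pathwayId must be a single non-empty string")
  ed <- object@edges
  need <- c("source", "target", "relation", "sign")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "edges must have columns source, target, relation, sign")
  else {
    bad <- !(ed$source %in% object@genes) | !(ed$target %in% object@genes)
    if (any(bad)) msg <- c(msg, "every edge endpoint must be a member gene")
    if (!all(ed$sign %in% c(-1L, 0L, 1L)))
      msg <- c(msg, "edge signs must lie in {-1, 0, +1}")
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "genes must be unique")
  if (length(msg)) msg else TRUE
})

#' GlobalGraph: the union graph over a pathway collection
#'
#' Directed edges are deduplicated on (source, target, relation); each edge
#' records the contributing pathway ids. The undirected key set collapses
#' (X,Y)/(Y,X) to a single scored pair.
#'
#' @slot genes union of member-pathway gene sets.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{relation}, \code{sign}, \code{pathways} (comma-separated ids).
#' @exportClass GlobalGraph
setClass("GlobalGraph",
  representation(genes = "character", edges = "data.frame"),
  prototype(genes = character(), edges = emptyEdgeFrame(pathways = TRUE)))

setValidity("GlobalGraph", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("source", "target", "relation", "sign", "pathways")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "edges must have columns source, target, relation, sign, pathways")
  else {
    if (nrow(ed)) {
      if (any(!(ed$source %in% object@genes) | !(ed$target %in% object@genes)))
        msg <- c(msg, "edge endpoints must belong to the gene set")
      key <- paste(ed$source, ed$target, ed$relation, sep = "\r")
      if (anyDuplicated(key))
        msg <- c(msg, "edges must be unique on (source, target, relation)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BetaMatrices: per-relation weight matrices for one pathway
#'
#' Square matrices indexed by the pathway's sorted gene list, one per
#' relation class (entries in \{-beta, 0, +beta\}), plus the combined
#' matrix \code{B} whose column u is normalized by N_ds(u), the number of
#' downstream targets of u carrying non-zero weight.
#'
#' @slot genes sorted gene ordering shared by all matrices.
#' @slot beta named numeric vector of relation weights used.
#' @slot matrices named list of per-relation signed weight matrices.
#' @slot B combined column-normalized matrix.
#' @exportClass BetaMatrices
setClass("BetaMatrices",
  representation(genes = "character", beta = "numeric",
                 matrices = "list", B = "matrix"))

setValidity("BetaMatrices", function(object) {
  p <- length(object@genes)
  if (!all(dim(object@B) == c(p, p)))
    return("B must be a pSize x pSize matrix")
  TRUE
})

#' HESThresholds: change-point-derived edge-score cutoffs
#'
#' @slot hes1 lower boundary of the change point (least high edge score).
#' @slot hes2 25\% safety margin above hes1 (top 75\% of elevated scores).
#' @slot hes3 maximal edge score.
#' @slot changepointIndex number of elevated scores; equivalently the
#'   0-based position, in the descending-sorted sequence, of the first score
#'   of the flat segment.
#' @slot nScores length of the score sequence the thresholds were fit on.
#' @exportClass HESThresholds
setClass("HESThresholds",
  representation(hes1 = "numeric", hes2 = "numeric", hes3 = "numeric",
                 changepointIndex = "integer", nScores = "integer"))

setValidity("HESThresholds", function(object) {
  msg <- character()
  if (!(object@hes1 <= object@hes2 && object@hes2 <= object@hes3))
    msg <- c(msg, "need hes1 <= hes2 <= hes3")
  if (object@changepointIndex < 1L ||
      object@changepointIndex > object@nScores - 1L)
    msg <- c(msg, "changepointIndex must lie in [1, n - 1]")
  if (length(msg)) msg else TRUE
})

#' DEGSet: differentially expressed genes selected at an edge-score threshold
#'
#' @slot table data.frame (gene, log2fc, p, bestEdgeScore, rank), ranked by
#'   best incident qualifying edge score.
#' @slot thresholdUsed one of "HES1", "HES2", "HES3" or "explicit".
#' @slot thresholdValue the numeric score cutoff applied.
#' @exportClass DEGSet
setClass("DEGSet",
  representation(table = "data.frame", thresholdUsed = "character",
                 thresholdValue = "numeric"))

setValidity("DEGSet", function(object) {
  if (anyDuplicated(object@table$gene)) "DEG list must be duplicate-free"
  else TRUE
})

#' ROCCurve: knockout ground-truth ROC over pathway p-values
#'
#' The predictor is a per-pathway p-value (smaller means more positive);
#' points are evaluated at every distinct threshold so that trapezoidal AUC
#' equals the pair-counting concordance statistic with ties at half weight.
#'
#' @slot points data.frame (threshold, specificity, sensitivity).
#' @slot auc trapezoidal area under the full curve.
#' @slot p per-pathway predictor p-values (kept for resampling).
#' @slot truth per-pathway logical ground-truth labels, aligned with p.
#' @slot pField name of the p-value column used as predictor.
#' @exportClass ROCCurve
setClass("ROCCurve",
  representation(points = "data.frame", auc = "numeric", p = "numeric",
                 truth = "logical", pField = "character"))

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (length(object@p) != length(object@truth))
    msg <- c(msg, "p and truth must be aligned")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "AUC must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
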