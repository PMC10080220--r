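#' @describeIn PathwayGraph-class pathway identifier
#' @param object a knockpath S4 object.
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))

#' @describeIn PathwayGraph-class pathway display name
#' @export
setGeneric("pathwayName", function(object) standardGeneric("pathwayName"))

#' @describeIn PathwayGraph-class member gene identifiers
#' @export
setGeneric("pathwayGenes", function(object) standardGeneric("pathwayGenes"))

#' @describeIn PathwayGraph-class edge table
#' @export
setGeneric("pathwayEdges", function(object) standardGeneric("pathwayEdges"))

#' @describeIn PathwayGraph-class number of member genes (all-genes pSize)
#' @export
setGeneric("pSize", function(object) standardGeneric("pSize"))

setMethod("pathwayId", "PathwayGraph", function(object) object@pathwayId)
setMethod("pathwayName", "PathwayGraph", function(object) object@pathwayName)
setMethod("pathwayGenes", "PathwayGraph", function(object) object@genes)
setMethod("pathwayEdges", "PathwayGraph", function(object) object@edges)
setMethod("pSize", "PathwayGraph", function(object) length(object@genes))

setMethod("pathwayGenes", "GlobalGraph", function(object) object@genes)
setMethod("pathwayEdges", "GlobalGraph", function(object) object@edges)

#' Undirected edge keys of a global graph
#'
#' @param object a \linkS4class{GlobalGraph}.
#' @return data.frame with columns \code{geneX}, \code{geneY} (canonical
#'   order, \code{geneX < geneY}), one row per unordered measured pair.
#' @export
setGeneric("undirectedEdgeKeys",
           function(object) standardGeneric("undirectedEdgeKeys"))

setMethod("undirectedEdgeKeys", "GlobalGraph", function(object) {
  ed <- object@edges
  if (!nrow(ed)) {
    return(data.frame(geneX = character(), geneY = character(),
                      stringsAsFactors = FALSE))
  }
  gx <- pmin(ed$source, ed$target)
  gy <- pmax(ed$source, ed$target)
  keep <- !duplicated(paste(gx, gy, sep = "|"))
  out <- data.frame(geneX = gx[keep], geneY = gy[keep],
                    stringsAsFactors = FALSE)
  out[order(out$geneX, out$geneY), , drop = FALSE]
})

#' @describeIn HESThresholds-class the HES1 cutoff
#' @param object a \linkS4class{HESThresholds}.
#' @export
setGeneric("hes1", function(object) standardGeneric("hes1"))
#' @describeIn HESThresholds-class the HES2 cutoff
#' @export
setGeneric("hes2", function(object) standardGeneric("hes2"))
#' @describeIn HESThresholds-class the HES3 cutoff
#' @export
setGeneric("hes3", function(object) standardGeneric("hes3"))
#' @describeIn HESThresholds-class elevated-segment length (change point)
#' @export
setGeneric("changepointIndex",
           function(object) standardGeneric("changepointIndex"))

setMethod("hes1", "HESThresholds", function(object) object@hes1)
setMethod("hes2", "HESThresholds", function(object) object@hes2)
setMethod("hes3", "HESThresholds", function(object) object@hes3)
setMethod("changepointIndex", "HESThresholds",
          function(object) object@changepointIndex)

#' @describeIn DEGSet-class ranked DEG identifiers
#' @param object a \linkS4class{DEGSet}.
#' @export
setGeneric("degGenes", function(object) standardGeneric("degGenes"))
#' @describeIn DEGSet-class the full ranked DEG table
#' @export
setGeneric("degTable", function(object) standardGeneric("degTable"))

setMethod("degGenes", "DEGSet", function(object) object@table$gene)
setMethod("degTable", "DEGSet", function(object) object@table)

#' @describeIn ROCCurve-class full area under the curve
#' @param object a \linkS4class{ROCCurve}.
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))
#' @describeIn ROCCurve-class the (threshold, specificity, sensitivity) table
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

setMethod("aucValue", "ROCCurve", function(object) object@auc)
setMethod("rocPoints", "ROCCurve", function(object) object@points)

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph ", object@pathwayId,
      if (nzchar(object@pathwayName)) paste0(" (", object@pathwayName, ")"),
      "\n  genes: ", length(object@genes),
      "  edges: ", nrow(object@edges), "\n", sep = "")
})

setMethod("show", "GlobalGraph", function(object) {
  cat("GlobalGraph\n  genes: ", length(object@genes),
      "  directed edges: ", nrow(object@edges),
      "  undirected pairs: ", nrow(undirectedEdgeKeys(object)), "\n",
      sep = "")
})

setMethod("show", "HESThresholds", function(object) {
  cat(sprintf(
    "HESThresholds over %d scores (change point at %d elevated edges)\n",
    object@nScores, object@changepointIndex))
  cat(sprintf("  HES1 = %g  HES2 = %g  HES3 = %g\n",
              object@hes1, object@hes2, object@hes3))
})

setMethod("show", "DEGSet", function(object) {
  cat(sprintf("DEGSet: %d genes at %s (score >= %g)\n",
              nrow(object@table), object@thresholdUsed,
              object@thresholdValue))
  if (nrow(object@table)) {
    print(utils::head(object@table, 5L), row.names = FALSE)
    if (nrow(object@table) > 5L) cat("  ...\n")
  }
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf(
    "ROCCurve on %d pathways (%d positive / %d negative), predictor '%s'\n",
    length(object@truth), sum(object@truth), sum(!object@truth),
    object@pField))
  cat(sprintf("  AUC = %.4f\n", object@auc))
})
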