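#' Build the global interaction graph over a pathway collection
#'
#' The global graph comprises all interactions among the entire gene set of
#' the collection: genes are the union over pathways and directed edges are
#' deduplicated on (source, target, relation), with every retained edge
#' recording the contributing pathway ids.
#'
#' @param pathways list of \linkS4class{PathwayGraph} objects.
#' @return a \linkS4class{GlobalGraph}.
#' @export
buildGlobalGraph <- function(pathways) {
  if (!length(pathways)) stop("need at least one pathway")
  stopifnot(all(vapply(pathways, is, logical(1), "PathwayGraph")))
  genes <- sort(unique(unlist(lapply(pathways, pathwayGenes))))
  eds <- lapply(pathways, function(p) {
    e <- pathwayEdges(p)
    if (nrow(e)) e$pathways <- pathwayId(p)
    else e$pathways <- character()
    e
  })
  ed <- do.call(rbind, eds)
  if (is.null(ed) || !nrow(ed)) {
    return(new("GlobalGraph", genes = genes,
               edges = emptyEdgeFrame(pathways = TRUE)))
  }
  key <- paste(ed$source, ed$target, ed$relation, sep = "\r")
  contrib <- split(ed$pathways, key)
  ded <- ed[!duplicated(key), , drop = FALSE]
  ded$pathways <- vapply(paste(ded$source, ded$target, ded$relation,
                               sep = "\r"),
                         function(k) paste(sort(unique(contrib[[k]])),
                                           collapse = ","),
                         character(1), USE.NAMES = FALSE)
  ded <- ded[order(ded$source, ded$target, ded$relation), , drop = FALSE]
  rownames(ded) <- NULL
  new("GlobalGraph", genes = genes, edges = ded)
}

#' Per-pathway signed weight matrices for perturbation propagation
#'
#' Builds one square matrix per relation class with entries sign * beta for
#' each edge j -> i, and the combined matrix B in which column u is divided
#' by N_ds(u), the number of distinct downstream targets of u over edges
#' with non-zero weight, so that each source distributes a total absolute
#' weight of beta across its targets. Gene ordering is the sorted canonical
#' id order and equals the matrix dimnames.
#'
#' @param pathway a \linkS4class{PathwayGraph}.
#' @inheritParams parseKGML
#' @return a \linkS4class{BetaMatrices}.
#' @export
pathwayBetaMatrices <- function(pathway,
                                relationConfig = defaultRelationConfig(),
                                strict = FALSE) {
  genes <- sort(pathwayGenes(pathway))
  p <- length(genes)
  ed <- pathwayEdges(pathway)
  i <- match(ed$relation, relationConfig$relation)
  if (anyNA(i)) {
    unknown <- unique(ed$relation[is.na(i)])
    if (strict) stop("unknown relation subtype(s): ",
                     paste(unknown, collapse = ", "))
    warning("unknown relation subtype(s) given weight 0: ",
            paste(unknown, collapse = ", "))
  }
  w <- ifelse(is.na(i), 0, relationConfig$beta[i] * relationConfig$sign[i])
  beta <- setNames(relationConfig$beta, relationConfig$relation)

  zero <- matrix(0, p, p, dimnames = list(genes, genes))
  mats <- list()
  raw <- zero
  if (nrow(ed)) {
    for (rel in unique(ed$relation)) {
      m <- zero
      sel <- ed$relation == rel
      m[cbind(match(ed$target[sel], genes), match(ed$source[sel], genes))] <-
        w[sel][1L] # constant within a relation class
      mats[[rel]] <- m
    }
    nz <- w != 0
    if (any(nz)) {
      ## distinct weighted targets per source
      nds <- vapply(genes, function(g) {
        length(unique(ed$target[nz & ed$source == g]))
      }, integer(1))
      for (k in which(nz)) {
        ti <- match(ed$target[k], genes); si <- match(ed$source[k], genes)
        raw[ti, si] <- raw[ti, si] + w[k]
      }
      pos <- nds > 0
      raw[, pos] <- sweep(raw[, pos, drop = FALSE], 2, nds[pos], "/")
    }
  }
  new("BetaMatrices", genes = genes, beta = beta, matrices = mats, B = raw)
}

#' Write a graph as tab-delimited edge-list text
#'
#' Columns: source, target, relation, sign, pathway_ids (comma-separated).
#'
#' @param graph a \linkS4class{PathwayGraph} or \linkS4class{GlobalGraph}.
#' @param file output path.
#' @export
writeEdgeList <- function(graph, file) {
  ed <- pathwayEdges(graph)
  pid <- if (is(graph, "PathwayGraph")) pathwayId(graph) else NULL
  out <- data.frame(source = ed$source, target = ed$target,
                    relation = ed$relation, sign = ed$sign,
                    pathway_ids = if (!is.null(pid)) rep(pid, nrow(ed))
                                  else ed$pathways,
                    stringsAsFactors = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an edge-list file written by \code{writeEdgeList}
#'
#' @param file edge-list path.
#' @return data.frame (source, target, relation, sign, pathway_ids).
#' @export
readEdgeList <- function(file) {
  read.delim(file, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "character",
                            "integer", "character"))
}

#' Convert a graph object to igraph
#'
#' @param graph a \linkS4class{PathwayGraph} or \linkS4class{GlobalGraph}.
#' @return a directed \code{igraph} graph with edge attributes
#'   \code{relation} and \code{sign}.
#' @export
asIgraph <- function(graph) {
  ed <- pathwayEdges(graph)
  igraph::graph_from_data_frame(
    ed[, c("source", "target", "relation", "sign")],
    directed = TRUE,
    vertices = data.frame(name = pathwayGenes(graph),
                          stringsAsFactors = FALSE))
}

#' Export a graph to GraphML
#'
#' @inheritParams asIgraph
#' @param file output path.
#' @export
exportGraphML <- function(graph, file) {
  igraph::write_graph(asIgraph(graph), file, format = "graphml")
  invisible(file)
}
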