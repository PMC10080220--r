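#' Default relation-subtype configuration
#'
#' Maps KGML relation subtypes onto an interaction sign and a perturbation
#' weight beta. Activating subtypes (activation, expression,
#' phosphorylation) carry +1 with unit weight; inhibitory subtypes
#' (inhibition, repression, dephosphorylation) carry -1 with unit weight;
#' binding/association and indirect effect are kept in the graph (so their
#' edges are scored) but carry zero weight and therefore do not enter
#' perturbation propagation. Pass a modified copy to \code{\link{parseKGML}}
#' or \code{\link{pathwayBetaMatrices}} to change the mapping.
#'
#' @return data.frame with columns \code{relation}, \code{sign}, \code{beta}.
#' @examples
#' defaultRelationConfig()
#' @export
defaultRelationConfig <- function() {
  data.frame(
    relation = c("activation", "expression", "phosphorylation",
                 "inhibition", "repression", "dephosphorylation",
                 "binding/association", "indirect effect",
                 "state change", "dissociation", "ubiquitination",
                 "missing interaction"),
    sign = c(1L, 1L, 1L, -1L, -1L, -1L, 1L, 1L, 0L, 0L, -1L, 0L),
    beta = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

.relationSign <- function(relation, config, strict = FALSE) {
  i <- match(relation, config$relation)
  if (anyNA(i)) {
    unknown <- unique(relation[is.na(i)])
    if (strict) {
      stop("unknown relation subtype(s): ", paste(unknown, collapse = ", "))
    }
    warning("unknown relation subtype(s) mapped to sign 0: ",
            paste(unknown, collapse = ", "))
  }
  s <- config$sign[i]
  s[is.na(s)] <- 0L
  as.integer(s)
}

#' Parse one KGML pathway file into a PathwayGraph
#'
#' Entries of type \code{gene} contribute genes (multi-gene entries are
#' expanded so every constituent receives the entry's relations); entries of
#' type \code{group} are expanded to their member genes with relations
#' copied to all members; all other entry types are dropped, together with
#' relations touching them. Self-edges arising from group/multi-gene
#' expansion are dropped.
#'
#' @param path path to a KGML (\code{.xml}) file.
#' @param relationConfig relation-to-sign mapping, see
#'   \code{\link{defaultRelationConfig}}.
#' @param strict error (rather than warn) on unknown relation subtypes.
#' @return a \linkS4class{PathwayGraph}. A file with zero gene entries yields
#'   an empty graph with a warning.
#' @export
parseKGML <- function(path, relationConfig = defaultRelationConfig(),
                      strict = FALSE) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed KGML XML in '", path, "': ", conditionMessage(e))
  })
  if (xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document (no <pathway> root): ", path)
  }
  org <- xml2::xml_attr(doc, "org")
  number <- xml2::xml_attr(doc, "number")
  pid <- xml2::xml_attr(doc, "name")
  pid <- sub("^path:", "", pid %||% NA_character_)
  if (is.na(pid) || !nzchar(pid)) pid <- paste0(org, number)
  title <- xml2::xml_attr(doc, "title")
  if (is.na(title)) title <- ""

  entries <- xml2::xml_find_all(doc, "entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")

  ## entry id -> member gene ids (gene entries may carry several ids)
  geneOf <- setNames(vector("list", length(eid)), eid)
  isGene <- etype == "gene"
  for (k in which(isGene)) {
    geneOf[[eid[k]]] <- strsplit(trimws(ename[k]), "\\s+")[[1]]
  }
  isGroup <- etype == "group"
  for (k in which(isGroup)) {
    comp <- xml2::xml_attr(xml2::xml_find_all(entries[[k]], "component"), "id")
    if (length(bad <- setdiff(comp, eid))) {
      stop("group entry ", eid[k], " in '", path,
           "' references missing entry id(s): ", paste(bad, collapse = ", "))
    }
    geneOf[[eid[k]]] <- unique(unlist(geneOf[comp], use.names = FALSE))
  }

  genes <- sort(unique(unlist(geneOf[isGene], use.names = FALSE)))
  if (!length(genes)) {
    warning("KGML file '", path, "' contains no gene entries")
    return(new("PathwayGraph", pathwayId = pid, pathwayName = title,
               organism = org %||% "", genes = character(),
               edges = emptyEdgeFrame()))
  }
  ## groups only contribute genes already present via member gene entries
  geneIdParts(genes)

  rel <- xml2::xml_find_all(doc, "relation")
  src <- character(); tgt <- character(); rname <- character()
  for (r in rel) {
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    if (!(e1 %in% eid) || !(e2 %in% eid)) {
      stop("relation references missing entry id(s) in '", path, "'")
    }
    g1 <- geneOf[[e1]]; g2 <- geneOf[[e2]]
    if (is.null(g1) || is.null(g2) || !length(g1) || !length(g2)) next
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "subtype"), "name")
    if (!length(subs)) subs <- xml2::xml_attr(r, "type")
    pairs <- expand.grid(s = g1, t = g2, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$t, , drop = FALSE]  # expansion self-loops
    if (!nrow(pairs)) next
    for (sb in subs) {
      src <- c(src, pairs$s); tgt <- c(tgt, pairs$t)
      rname <- c(rname, rep(sb, nrow(pairs)))
    }
  }
  edges <- data.frame(source = src, target = tgt, relation = rname,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges), , drop = FALSE]
  edges$sign <- if (nrow(edges)) {
    .relationSign(edges$relation, relationConfig, strict)
  } else integer()
  rownames(edges) <- NULL
  new("PathwayGraph", pathwayId = pid, pathwayName = title,
      organism = org %||% "", genes = genes, edges = edges)
}

#' Read a pathway collection described by a manifest
#'
#' The manifest is a JSON object mapping pathway id to a KGML file path
#' (relative paths are resolved against the manifest's directory).
#'
#' @param manifest path to a manifest JSON file.
#' @inheritParams parseKGML
#' @return named list of \linkS4class{PathwayGraph} objects.
#' @export
readPathwayCollection <- function(manifest,
                                  relationConfig = defaultRelationConfig(),
                                  strict = FALSE) {
  m <- jsonlite::read_json(manifest)
  files <- vapply(m$pathways, function(p) p$file, character(1))
  ids <- vapply(m$pathways, function(p) p$pathway_id, character(1))
  dir <- dirname(manifest)
  out <- lapply(files, function(f) {
    if (!file.exists(f)) f <- file.path(dir, f)
    parseKGML(f, relationConfig = relationConfig, strict = strict)
  })
  names(out) <- ids
  out
}
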