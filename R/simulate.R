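#' Synthetic-fixture specification
#'
#' Default study conditions for the self-contained fixtures: a 30-pathway
#' collection (8-25 genes each, 70\% containing the KO gene, roughly half
#' an extra edge per gene beyond the spanning tree), a balanced 5 vs. 5
#' two-group design, a 2.0 log2-unit knockout effect that propagates along
#' graph edges with decay 0.5 per hop, and Gaussian noise with sd 0.5.
#'
#' @param seed mandatory integer seed; all fixture randomness derives
#'   from it.
#' @param nPathways number of pathways in the collection.
#' @param sizeRange integer range of pathway gene counts.
#' @param koFraction fraction of pathways containing the KO gene (0, 1).
#' @param edgeDensity extra random edges per gene beyond the spanning tree.
#' @param nPerGroup samples per group.
#' @param effect knockout effect size at the KO gene, log2 units.
#' @param decay per-hop propagation decay in (0, 1).
#' @param noiseSd iid Gaussian noise standard deviation.
#' @param genePool number of genes in the shared gene universe.
#' @param corePool size of the shared "signaling core" subpool; pathways
#'   draw about half their genes from it, mimicking the heavy reuse of
#'   core signaling genes across related pathways.
#' @param coreFraction fraction of each pathway's genes drawn from the core.
#' @param koGene identifier of the knocked-out gene.
#' @return a \code{fixtureSpec} list.
#' @export
fixtureSpec <- function(seed, nPathways = 30, sizeRange = c(8, 25),
                        koFraction = 0.7, edgeDensity = 0.5,
                        nPerGroup = 5, effect = 2.0, decay = 0.5,
                        noiseSd = 0.5, genePool = 600, corePool = 60,
                        coreFraction = 0.5, koGene = "syn:1") {
  if (missing(seed)) stop("a seed is mandatory for fixture generation")
  stopifnot(nPathways >= 1, sizeRange[1] >= 2, koFraction > 0,
            koFraction < 1, edgeDensity >= 0, nPerGroup >= 2,
            decay >= 0, decay < 1, noiseSd > 0, effect >= 0,
            corePool < genePool, coreFraction >= 0, coreFraction <= 1)
  structure(list(seed = as.integer(seed), nPathways = nPathways,
                 sizeRange = sizeRange, koFraction = koFraction,
                 edgeDensity = edgeDensity, nPerGroup = nPerGroup,
                 effect = effect, decay = decay, noiseSd = noiseSd,
                 genePool = genePool, corePool = corePool,
                 coreFraction = coreFraction, koGene = koGene),
            class = "fixtureSpec")
}

.kgmlLines <- function(pid, number, title, genes, edges) {
  ids <- seq_along(genes)
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s" org="syn" number="%s" title="%s">',
            pid, number, title))
  lines <- c(lines, sprintf(
    '  <entry id="%d" name="%s" type="gene"><graphics name="%s" type="rectangle"/></entry>',
    ids, genes, sub("^syn:", "g", genes)))
  if (nrow(edges)) {
    arrow <- ifelse(edges$relation == "activation", "--&gt;", "--|")
    lines <- c(lines, sprintf(
      '  <relation entry1="%d" entry2="%d" type="PPrel"><subtype name="%s" value="%s"/></relation>',
      match(edges$source, genes), match(edges$target, genes),
      edges$relation, arrow))
  }
  c(lines, "</pathway>")
}

#' Generate a synthetic KGML pathway collection
#'
#' Writes one KGML file per pathway plus a manifest JSON (pathway_id ->
#' file, with recorded gene/edge counts). Each pathway has a random
#' connected topology (random spanning tree plus extra edges) with
#' relations drawn from \{activation, inhibition\}; exactly
#' round(koFraction * nPathways) pathways contain the KO gene. Re-running
#' with the same spec reproduces the files byte for byte.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path; parse the collection back with
#'   \code{\link{readPathwayCollection}}.
#' @export
generatePathwayCollection <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  if (spec$sizeRange[1] < 2) stop("infeasible spec: pathway size < 2")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pool <- paste0("syn:", seq_len(spec$genePool))
  core <- setdiff(pool[seq_len(spec$corePool %||% 0)], spec$koGene)
  periph <- setdiff(pool, c(core, spec$koGene))
  nKo <- round(spec$koFraction * spec$nPathways)
  manifest <- vector("list", spec$nPathways)
  withSeed(spec$seed, {
    hasKo <- c(rep(TRUE, nKo), rep(FALSE, spec$nPathways - nKo))
    for (i in seq_len(spec$nPathways)) {
      size <- sample(seq(spec$sizeRange[1], spec$sizeRange[2]), 1L)
      nFill <- size - as.integer(hasKo[i])
      nCore <- min(round(spec$coreFraction * nFill), length(core))
      fill <- c(sample(core, nCore), sample(periph, nFill - nCore))
      genes <- if (hasKo[i]) c(spec$koGene, sample(fill)) else sample(fill)
      ## rooted spanning tree directed downstream (signaling-cascade shape:
      ## the first gene — the KO gene in KO pathways — is the upstream
      ## regulator), then extra random crosstalk edges
      src <- character(); tgt <- character()
      for (k in seq(2L, size)) {
        anchor <- genes[sample.int(k - 1L, 1L)]
        src <- c(src, anchor); tgt <- c(tgt, genes[k])
      }
      nExtra <- round(spec$edgeDensity * size)
      tries <- 0L
      while (nExtra > 0L && tries < 50L * size) {
        a <- sample(genes, 2L)
        if (!any(src == a[1] & tgt == a[2])) {
          src <- c(src, a[1]); tgt <- c(tgt, a[2]); nExtra <- nExtra - 1L
        }
        tries <- tries + 1L
      }
      rel <- ifelse(runif(length(src)) < 0.7, "activation", "inhibition")
      edges <- data.frame(source = src, target = tgt, relation = rel,
                          stringsAsFactors = FALSE)
      number <- sprintf("%05d", i)
      pid <- paste0("syn", number)
      file <- file.path(dir, paste0(pid, ".xml"))
      writeLines(.kgmlLines(pid, number, paste0("synthetic pathway ", i),
                            genes, edges), file)
      manifest[[i]] <- list(pathway_id = pid,
                            file = basename(file),
                            n_genes = length(genes),
                            n_edges = nrow(edges),
                            contains_ko = hasKo[i])
    }
  })
  mpath <- file.path(dir, "manifest.json")
  writeJson(list(seed = spec$seed, ko_gene = spec$koGene,
                 pathways = manifest), mpath)
  invisible(mpath)
}

## deterministic BFS hop distances and sign products from the KO gene
.koPropagation <- function(graph, koGene) {
  keys <- undirectedEdgeKeys(graph)
  ed <- pathwayEdges(graph)
  ## undirected adjacency with a representative sign per unordered pair
  sgn <- ed$sign[match(.pairKey(keys$geneX, keys$geneY),
                       .pairKey(ed$source, ed$target))]
  adj <- split(data.frame(nb = c(keys$geneY, keys$geneX),
                          s = c(sgn, sgn), stringsAsFactors = FALSE),
               c(keys$geneX, keys$geneY))
  dist <- setNames(rep(NA_real_, length(pathwayGenes(graph))),
                   pathwayGenes(graph))
  sign <- dist
  if (!(koGene %in% names(dist))) return(list(dist = dist, sign = sign))
  dist[koGene] <- 0; sign[koGene] <- 1
  frontier <- koGene
  while (length(frontier)) {
    nxt <- character()
    for (g in frontier) {
      a <- adj[[g]]
      if (is.null(a)) next
      a <- a[order(a$nb), , drop = FALSE]
      for (r in seq_len(nrow(a))) {
        nb <- a$nb[r]
        if (is.na(dist[nb])) {
          dist[nb] <- dist[g] + 1
          sign[nb] <- sign[g] * a$s[r]
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  list(dist = dist, sign = sign)
}

#' Simulate a knockout expression dataset over a pathway collection
#'
#' Baseline expression is Normal(8, 1) per gene, shared by all samples.
#' In KO samples the KO gene is shifted by -effect and every gene at hop
#' distance d from it (shortest path on the global graph, edge signs
#' multiplied along the path) by -effect * decay^d * signproduct; iid
#' Normal(0, noiseSd) noise is added everywhere and groups are balanced.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param collection named list of \linkS4class{PathwayGraph} (e.g. from
#'   \code{\link{readPathwayCollection}} on the generated manifest).
#' @param datasetId dataset identifier.
#' @return a \linkS4class{KODataset}.
#' @export
simulateKoDataset <- function(spec, collection,
                              datasetId = paste0("sim", spec$seed)) {
  stopifnot(inherits(spec, "fixtureSpec"))
  graph <- buildGlobalGraph(collection)
  genes <- pathwayGenes(graph)
  if (!(spec$koGene %in% genes)) {
    stop("KO gene ", spec$koGene, " is absent from the collection")
  }
  prop <- .koPropagation(graph, spec$koGene)
  shift <- ifelse(is.na(prop$dist), 0,
                  -spec$effect * spec$decay^prop$dist * prop$sign)
  n <- spec$nPerGroup
  groups <- c(rep("CTRL", n), rep("KO", n))
  withSeed(spec$seed + 1000003L, {
    baseline <- rnorm(length(genes), mean = 8, sd = 1)
    mat <- matrix(baseline, nrow = length(genes), ncol = 2L * n) +
      matrix(rnorm(length(genes) * 2L * n, sd = spec$noiseSd),
             nrow = length(genes))
    mat[, groups == "KO"] <- mat[, groups == "KO"] + shift
    dimnames(mat) <- list(genes,
                          paste0(rep(c("ctrl", "ko"), each = n),
                                 rep(seq_len(n), 2L)))
    KODataset(mat, groups, spec$koGene, datasetId)
  })
}
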