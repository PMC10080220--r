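#' Over-representation p-value (upper-tail hypergeometric)
#'
#' P(X >= overlap) for drawing |DEGs| genes from a universe of size N
#' containing K pathway genes.
#'
#' @param degs a \linkS4class{DEGSet} or character vector of DEG ids.
#' @param pathway a \linkS4class{PathwayGraph} or character vector of genes.
#' @param universe character vector, the measured gene universe.
#' @return the hypergeometric upper-tail p-value.
#' @export
runORA <- function(degs, pathway, universe) {
  if (is(degs, "DEGSet")) degs <- degGenes(degs)
  if (is(pathway, "PathwayGraph")) pathway <- pathwayGenes(pathway)
  if (!length(universe)) stop("empty universe")
  degs <- intersect(degs, universe)
  K <- length(intersect(pathway, universe))
  n <- length(degs)
  x <- length(intersect(degs, pathway))
  spiaPNDE(x, K, n, length(universe))
}

#' Hypergeometric over-representation component (pNDE)
#'
#' @param NDE observed DEG count in the pathway.
#' @param pSizeMeasured measured pathway size (successes K).
#' @param totalDE number of DEGs drawn (n).
#' @param universeSize measured universe size (N).
#' @return P(X >= NDE).
#' @export
spiaPNDE <- function(NDE, pSizeMeasured, totalDE, universeSize) {
  if (universeSize <= 0) stop("empty universe")
  stopifnot(NDE <= pSizeMeasured, NDE <= totalDE,
            pSizeMeasured <= universeSize, totalDE <= universeSize)
  phyper(NDE - 1, pSizeMeasured, universeSize - pSizeMeasured, totalDE,
         lower.tail = FALSE)
}

#' Gene-permutation GSEA for one pathway
#'
#' Genes are ranked by the signed moderated t statistic; the enrichment
#' score is the weighted Kolmogorov-Smirnov running-sum extremum (weight
#' exponent 1). The p-value is the add-one-smoothed fraction of random
#' gene-label assignments whose |ES| reaches the observed |ES|.
#'
#' @param stats data.frame from \code{\link{fitGeneStats}}.
#' @param pathway a \linkS4class{PathwayGraph} or character gene vector.
#' @param permutations number of gene-label permutations (>= 100).
#' @param seed integer seed making the permutation null reproducible.
#' @return list(es, p, nGenes) or NULL (with a warning) if no pathway gene
#'   is measured.
#' @export
runGSEAPerm <- function(stats, pathway, permutations = 999, seed = 1) {
  if (permutations < 100) stop("need at least 100 permutations")
  if (is(pathway, "PathwayGraph")) pathway <- pathwayGenes(pathway)
  ord <- order(-stats$t, stats$gene)
  genes <- stats$gene[ord]
  r <- stats$t[ord]
  inSet <- genes %in% pathway
  nh <- sum(inSet)
  if (nh == 0L) {
    warning("no measured genes in pathway; GSEA result absent")
    return(NULL)
  }
  N <- length(genes)
  esOf <- function(hit) {
    w <- abs(r) * hit
    nr <- sum(w)
    inc <- if (nr > 0) w / nr else hit / nh
    dec <- (1 - hit) / (N - nh)
    run <- cumsum(inc - dec)
    run[which.max(abs(run))]
  }
  es <- esOf(as.numeric(inSet))
  perm <- withSeed(seed, {
    vapply(seq_len(permutations), function(i) {
      hit <- numeric(N)
      hit[sample.int(N, nh)] <- 1
      esOf(hit)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(es))) / (permutations + 1)
  list(es = es, p = p, nGenes = nh)
}

#' Net perturbation propagation through a pathway
#'
#' Solves the linear signaling model PF = dE + B PF, i.e. (I - B) PF = dE,
#' where B is the column-normalized signed weight matrix and dE holds the
#' log2 fold-changes of the pathway's DEGs (0 elsewhere). The total net
#' accumulated perturbation is tA = sum(PF - dE).
#'
#' @param beta a \linkS4class{BetaMatrices}.
#' @param deLog2fc named numeric vector, log2fc for pathway DEGs.
#' @return list(PF, acc, tA) or NULL if (I - B) is singular.
#' @export
spiaPerturbation <- function(beta, deLog2fc) {
  genes <- beta@genes
  de <- setNames(numeric(length(genes)), genes)
  hit <- intersect(names(deLog2fc), genes)
  de[hit] <- deLog2fc[hit]
  A <- diag(length(genes)) - beta@B
  pf <- tryCatch(solve(A, de), error = function(e) NULL)
  if (is.null(pf)) return(NULL)
  pf <- setNames(as.numeric(pf), genes)
  acc <- pf - de
  list(PF = pf, acc = acc, tA = sum(acc))
}

#' Bootstrap significance of the net perturbation (pPERT)
#'
#' The null distribution of tA is obtained by assigning NDE log2
#' fold-changes, sampled with replacement from the dataset-wide DEG pool,
#' to NDE random measured pathway genes. pPERT is the add-one-smoothed
#' two-sided exceedance around the null median; status is Activated when
#' the observed tA is above the null median, Inhibited otherwise.
#'
#' @param beta a \linkS4class{BetaMatrices}.
#' @param deLog2fc named numeric, the observed pathway DEG fold-changes.
#' @param allDEValues numeric pool of DEG log2 fold-changes (whole dataset).
#' @param measuredGenes measured genes of this pathway (bootstrap support).
#' @param reps bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return list(pPERT, status, tA, tAnullMedian) or NULL on singular model.
#' @export
spiaPPERT <- function(beta, deLog2fc, allDEValues, measuredGenes,
                      reps = 2000, seed = 1) {
  if (reps < 200) stop("config error: need at least 200 bootstrap reps")
  nde <- length(deLog2fc)
  if (nde == 0L) {
    return(list(pPERT = 1, status = NA_character_, tA = 0,
                tAnullMedian = 0))
  }
  genes <- beta@genes
  A <- diag(length(genes)) - beta@B
  Minv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Minv)) return(NULL)
  propagate <- function(de) {
    pf <- Minv %*% de
    sum(pf - de)
  }
  de <- setNames(numeric(length(genes)), genes)
  hit <- intersect(names(deLog2fc), genes)
  de[hit] <- deLog2fc[hit]
  tAobs <- propagate(de)
  support <- match(intersect(measuredGenes, genes), genes)
  if (!length(support)) return(NULL)
  tAnull <- withSeed(seed, {
    vapply(seq_len(reps), function(i) {
      den <- numeric(length(genes))
      idx <- if (length(support) == 1L) support
             else sample(support, min(nde, length(support)))
      den[idx] <- sample(allDEValues, length(idx), replace = TRUE)
      propagate(den)
    }, numeric(1))
  })
  med <- median(tAnull)
  p <- (1 + sum(abs(tAnull - med) >= abs(tAobs - med))) / (reps + 1)
  list(pPERT = p,
       status = if (tAobs > med) "Activated" else "Inhibited",
       tA = tAobs, tAnullMedian = med)
}

#' Fisher combination of pNDE and pPERT
#'
#' pG = c - c ln(c) with c = pNDE * pPERT; equal to the chi-square(4 df)
#' survival function at -2 ln(c). Zero inputs are clamped to the smallest
#' positive double with a warning.
#'
#' @param pNDE,pPERT p-values in (0, 1]; vectors recycle.
#' @return combined global p-value pG.
#' @export
combineFisher <- function(pNDE, pPERT) {
  if (any(pNDE <= 0, na.rm = TRUE) || any(pPERT <= 0, na.rm = TRUE)) {
    warning("zero p-value(s) clamped to the smallest positive double")
    pNDE <- pmax(pNDE, .Machine$double.xmin)
    pPERT <- pmax(pPERT, .Machine$double.xmin)
  }
  cc <- pNDE * pPERT
  cc - cc * log(cc)
}

#' Multiple-testing adjustment of pathway p-values
#'
#' @param p numeric vector of raw p-values.
#' @param method "BH" (step-up with monotone enforcement) or "Bonferroni".
#' @return adjusted p-values.
#' @export
adjustPValues <- function(p, method = c("BH", "Bonferroni")) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}

.emptyEnrichmentRow <- function() {
  data.frame(pathway_id = character(), name = character(),
             pSize = integer(), pSizeAll = integer(), NDE = integer(),
             pNDE = numeric(), tA = numeric(), pPERT = numeric(),
             status = character(), es = numeric(), pG = numeric(),
             pGFdr = numeric(), pGBonf = numeric(),
             stringsAsFactors = FALSE)
}

#' Full SPIA-style topology enrichment over a pathway collection
#'
#' Per pathway: pNDE (hypergeometric over-representation of DEGs among the
#' pathway's measured genes), the net accumulated perturbation tA with its
#' bootstrap pPERT and Activated/Inhibited status, and the combined global
#' p-value pG with BH and Bonferroni adjustments.
#'
#' @param degs a \linkS4class{DEGSet}.
#' @param stats gene statistics from \code{\link{fitGeneStats}}.
#' @param collection named list of \linkS4class{PathwayGraph} objects.
#' @param universe measured gene universe (default: all fitted genes).
#' @param reps bootstrap replicates for pPERT.
#' @param seed integer seed.
#' @inheritParams parseKGML
#' @return EnrichmentResult data.frame sorted by ascending pG.
#' @export
runSPIA <- function(degs, stats, collection, universe = stats$gene,
                    reps = 2000, seed = 1,
                    relationConfig = defaultRelationConfig()) {
  degTab <- degTable(degs)
  degIds <- intersect(degTab$gene, universe)
  fc <- setNames(degTab$log2fc, degTab$gene)[degIds]
  rows <- lapply(seq_along(collection), function(i) {
    pw <- collection[[i]]
    measured <- intersect(pathwayGenes(pw), universe)
    if (!length(measured)) return(NULL)
    nde <- length(intersect(degIds, measured))
    pnde <- spiaPNDE(nde, length(measured), length(degIds),
                     length(universe))
    beta <- pathwayBetaMatrices(pw, relationConfig)
    pert <- spiaPPERT(beta, fc[intersect(degIds, measured)], as.numeric(fc),
                      measured, reps = reps,
                      seed = seed + i)
    if (is.null(pert)) {
      message("singular perturbation model for ", pathwayId(pw),
              "; result NA")
      tA <- NA_real_; ppert <- NA_real_; status <- NA_character_
      pg <- NA_real_
    } else {
      tA <- pert$tA; ppert <- pert$pPERT; status <- pert$status
      pg <- combineFisher(pnde, ppert)
    }
    data.frame(pathway_id = pathwayId(pw), name = pathwayName(pw),
               pSize = length(measured), pSizeAll = pSize(pw),
               NDE = nde, pNDE = pnde, tA = tA, pPERT = ppert,
               status = status, es = NA_real_, pG = pg,
               pGFdr = NA_real_, pGBonf = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.emptyEnrichmentRow())
  out$pGFdr <- adjustPValues(out$pG, "BH")
  out$pGBonf <- adjustPValues(out$pG, "Bonferroni")
  out <- out[order(out$pG), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an external per-pathway p-value table
#'
#' Tab-delimited with at least columns \code{pathway_id} and \code{p}.
#'
#' @param file path to the table.
#' @return data.frame (pathway_id, p).
#' @export
readExternalTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "p") %in% names(d))) {
    stop("external table needs columns 'pathway_id' and 'p'")
  }
  d
}

#' Uniform dispatch over enrichment methods
#'
#' Runs one method over every pathway of the collection with measured
#' genes and returns a uniform result table (Table-2-style columns plus
#' evidence), sorted by ascending pG. For non-topology methods the single
#' pathway p is carried in pG; pNDE/tA/pPERT/status stay NA.
#'
#' @param methodSpec list with \code{method_id} in \{"ORA", "GSEA_PERM",
#'   "SPIA", "EXTERNAL:<name>"\} and optional parameters
#'   (\code{permutations}, \code{reps}, \code{seed},
#'   \code{relationConfig}, \code{externalTable}).
#' @param stats gene statistics.
#' @param degs a \linkS4class{DEGSet}.
#' @param collection named list of \linkS4class{PathwayGraph} objects.
#' @param universe measured gene universe.
#' @return EnrichmentResult data.frame; the method spec (seed included) is
#'   attached as attribute \code{"methodSpec"}.
#' @export
runMethod <- function(methodSpec, stats, degs, collection,
                      universe = stats$gene) {
  id <- methodSpec$method_id
  seed <- methodSpec$seed %||% 1L
  if (id == "SPIA") {
    out <- runSPIA(degs, stats, collection, universe,
                   reps = methodSpec$reps %||% 2000, seed = seed,
                   relationConfig = methodSpec$relationConfig %||%
                     defaultRelationConfig())
  } else if (id == "ORA") {
    rows <- lapply(collection, function(pw) {
      measured <- intersect(pathwayGenes(pw), universe)
      if (!length(measured)) return(NULL)
      nde <- length(intersect(degGenes(degs), measured))
      p <- runORA(degs, measured, universe)
      data.frame(pathway_id = pathwayId(pw), name = pathwayName(pw),
                 pSize = length(measured), pSizeAll = pSize(pw), NDE = nde,
                 pNDE = NA_real_, tA = NA_real_, pPERT = NA_real_,
                 status = NA_character_, es = NA_real_, pG = p,
                 pGFdr = NA_real_, pGBonf = NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else if (id == "GSEA_PERM") {
    rows <- lapply(seq_along(collection), function(i) {
      pw <- collection[[i]]
      measured <- intersect(pathwayGenes(pw), universe)
      if (!length(measured)) return(NULL)
      g <- runGSEAPerm(stats, measured,
                       permutations = methodSpec$permutations %||% 999,
                       seed = seed + i)
      if (is.null(g)) return(NULL)
      nde <- length(intersect(degGenes(degs), measured))
      data.frame(pathway_id = pathwayId(pw), name = pathwayName(pw),
                 pSize = length(measured), pSizeAll = pSize(pw), NDE = nde,
                 pNDE = NA_real_, tA = NA_real_, pPERT = NA_real_,
                 status = NA_character_, es = g$es, pG = g$p,
                 pGFdr = NA_real_, pGBonf = NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else if (grepl("^EXTERNAL:", id)) {
    tab <- methodSpec$externalTable
    if (is.character(tab)) tab <- readExternalTable(tab)
    if (is.null(tab)) stop("EXTERNAL method requires an externalTable")
    missing <- setdiff(vapply(collection, pathwayId, character(1)),
                       tab$pathway_id)
    if (length(missing)) {
      warning("external table lacks ", length(missing),
              " collection pathway(s); they are absent from results")
    }
    ids <- vapply(collection, pathwayId, character(1))
    nm <- vapply(collection, pathwayName, character(1))
    i <- match(tab$pathway_id, ids)
    out <- data.frame(pathway_id = tab$pathway_id,
                      name = ifelse(is.na(i), "", nm[i]),
                      pSize = NA_integer_, pSizeAll = NA_integer_,
                      NDE = NA_integer_, pNDE = NA_real_, tA = NA_real_,
                      pPERT = NA_real_, status = NA_character_,
                      es = NA_real_, pG = tab$p, pGFdr = NA_real_,
                      pGBonf = NA_real_, stringsAsFactors = FALSE)
  } else {
    stop("unknown method_id: ", id)
  }
  if (is.null(out) || !nrow(out)) out <- .emptyEnrichmentRow()
  out$pGFdr <- adjustPValues(out$pG, "BH")
  out$pGBonf <- adjustPValues(out$pG, "Bonferroni")
  out <- out[order(out$pG, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "methodSpec") <- modifyList(list(seed = seed), methodSpec)
  out
}
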