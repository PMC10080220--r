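#' Read a run configuration (JSON or YAML)
#'
#' A run configuration names the pathway collection manifest, the dataset
#' descriptors (matrix, design, ko_genes, dataset_id), the method specs,
#' the HES choice, alpha levels, replicate counts, the global seed and the
#' output root. It is serialized verbatim into every output directory.
#'
#' @param path configuration file; format chosen by extension
#'   (.json / .yml / .yaml).
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  ids <- vapply(cfg$datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("dataset_ids must be unique")
  cfg
}

.loadDataset <- function(desc) {
  if (is(desc$data, "KODataset")) return(desc$data)
  readExpressionDataset(desc$matrix, desc$design,
                        unlist(desc$ko_genes), desc$dataset_id)
}

.methodLabel <- function(spec) gsub("[^A-Za-z0-9_.-]", "_", spec$method_id)

## config copy safe for JSON: in-memory datasets reduced to their ids
.sanitizeConfig <- function(config) {
  config$datasets <- lapply(config$datasets, function(d) {
    if (is(d$data, "KODataset")) {
      d$data <- NULL
      d$in_memory <- TRUE
    }
    d
  })
  config$methods <- lapply(config$methods, function(m) {
    m$relationConfig <- NULL
    m
  })
  config
}

#' Run one dataset x method pair of the benchmark pipeline
#'
#' Executes the full chain — gene statistics, edge scores, HES thresholds,
#' DEG selection, KO subnetwork, enrichment, KO ground truth, ROC and
#' metrics — and writes every module output into
#' \code{outputRoot/datasetId/methodId/}: DEG table, edge-score table, HES
#' summary (JSON), subnetwork (edge list + GraphML), results table with a
#' method-spec JSON sidecar, ROC points (CSV), metrics (JSON) and a
#' machine-readable \code{summary.json}. Stage errors are recorded in
#' \code{run.log} and downstream stages are skipped. Re-running with the
#' same seed reproduces \code{summary.json} byte for byte.
#'
#' @param config run configuration list (see \code{\link{readRunConfig}}).
#' @param datasetId which dataset descriptor to run.
#' @param methodId \code{method_id} of the method spec to run.
#' @param collection optionally, the pre-parsed pathway collection.
#' @return invisibly, the output directory path.
#' @export
runSingle <- function(config, datasetId, methodId, collection = NULL) {
  if (is.null(collection)) {
    collection <- readPathwayCollection(config$collection)
  }
  descs <- config$datasets
  ids <- vapply(descs, function(d) d$dataset_id, character(1))
  desc <- descs[[match(datasetId, ids)]]
  specs <- config$methods
  mids <- vapply(specs, function(m) m$method_id, character(1))
  mspec <- specs[[match(methodId, mids)]]
  seed <- as.integer(config$seed %||% 1L)
  mspec$seed <- seed
  if (!is.null(config$reps) && is.null(mspec$reps)) mspec$reps <- config$reps
  if (!is.null(config$permutations) && is.null(mspec$permutations)) {
    mspec$permutations <- config$permutations
  }
  outDir <- file.path(config$outputRoot %||% ".",
                      datasetId, .methodLabel(mspec))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logFile,
                               append = TRUE)
  cat("", file = logFile)
  clean <- .sanitizeConfig(config)
  ## audit copy with paths; summary.json itself stays path-free so that
  ## re-runs under one seed are byte-identical wherever they land
  writeJson(clean, file.path(outDir, "config.json"))
  summary <- list(dataset_id = datasetId, method_id = methodId,
                  seed = seed,
                  config = clean[setdiff(names(clean),
                                         c("collection", "outputRoot"))])
  fail <- function(stage, e) {
    logLine("ERROR at ", stage, ": ", conditionMessage(e))
    summary$error <<- list(stage = stage, message = conditionMessage(e))
    writeJson(summary, file.path(outDir, "summary.json"))
    invisible(outDir)
  }

  res <- tryCatch({
    dataset <- .loadDataset(desc)
    truth <- buildGroundTruth(collection, koGenes(dataset))
    logLine("ground truth: ", sum(truth), " positive / ",
            sum(!truth), " negative pathways")

    stats <- fitGeneStats(dataset)
    graph <- buildGlobalGraph(collection)
    scores <- computeEdgeScores(stats, graph)
    logLine("scored ", nrow(scores), " edges (",
            attr(scores, "skipped") %||% 0L, " skipped)")
    hes <- hesThresholds(scores)
    hesChoice <- config$hes %||% "HES1"
    degs <- selectDEGs(scores, hes, stats, hes = hesChoice)
    subnet <- extractKoSubnetwork(degs, graph)

    write.table(degTable(degs), file.path(outDir, "deg_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scores, file.path(outDir, "edge_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeJson(list(hes1 = hes1(hes), hes2 = hes2(hes), hes3 = hes3(hes),
                   changepoint_index = changepointIndex(hes),
                   n_scores = hes@nScores, threshold_used = hesChoice),
              file.path(outDir, "hes.json"))
    writeEdgeList(subnet$graph, file.path(outDir, "subnetwork_edges.tsv"))
    exportGraphML(subnet$graph, file.path(outDir, "subnetwork.graphml"))
    ## plot-ready score distribution: sorted scores + the three cutoffs
    write.table(data.frame(rank = seq_len(nrow(scores)),
                           score = sort(scores$score, decreasing = TRUE)),
                file.path(outDir, "score_distribution.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)

    universe <- stats$gene
    results <- runMethod(mspec, stats, degs, collection, universe)
    write.table(results, file.path(outDir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeJson(attr(results, "methodSpec")[
      setdiff(names(attr(results, "methodSpec")), "relationConfig")],
      file.path(outDir, "methodspec.json"))

    pField <- config$pField %||% "pG"
    curve <- buildROC(results, truth, pField = pField)
    write.table(rocPoints(curve), file.path(outDir, "roc_points.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    ms <- computeMetricSet(results, truth, pField = pField)
    alpha <- config$alpha %||% 0.005
    conf <- classifyConfusion(results, truth, alpha = alpha,
                              pField = config$alphaField %||% "pGFdr")
    writeJson(as.list(ms), file.path(outDir, "metrics.json"))

    summary$n_degs <- nrow(degTable(degs))
    summary$hes <- list(hes1 = hes1(hes), hes2 = hes2(hes),
                        hes3 = hes3(hes))
    summary$threshold_used <- hesChoice
    summary$n_pathways <- nrow(results)
    summary$confusion <- conf
    summary$metrics <- as.list(ms)
    writeJson(summary, file.path(outDir, "summary.json"))
    logLine("completed")
    invisible(outDir)
  }, error = function(e) fail("pipeline", e))
  res
}

#' Batch execution over every dataset x method pair
#'
#' Runs each pair independently (isolated output directories, no shared
#' mutable state, order-independent results), then aggregates the per-run
#' metric sets into the consolidated long table with pairwise Wilcoxon
#' comparisons. Partial failures do not abort the batch; they are listed
#' in \code{batch.log} and in the returned object.
#'
#' @param config run configuration list.
#' @return list with \code{runs} (per-pair output directories),
#'   \code{metrics} (long data.frame), \code{aggregate} (see
#'   \code{\link{aggregateBenchmark}}; NULL when fewer than 2 methods or
#'   datasets succeeded) and \code{failures}.
#' @export
runBatch <- function(config) {
  collection <- readPathwayCollection(config$collection)
  root <- config$outputRoot %||% "."
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(config$datasets, function(d) d$dataset_id, character(1))
  mids <- vapply(config$methods, function(m) m$method_id, character(1))
  runs <- list(); failures <- list(); longRows <- list()
  for (d in ids) {
    for (m in mids) {
      dir <- runSingle(config, d, m, collection = collection)
      runs[[paste(d, m, sep = "/")]] <- dir
      summ <- jsonlite::read_json(file.path(dir, "summary.json"))
      if (!is.null(summ$error)) {
        failures[[paste(d, m, sep = "/")]] <- summ$error$message
      } else {
        mets <- unlist(summ$metrics)
        longRows[[length(longRows) + 1L]] <-
          data.frame(dataset = d, method = m, metric = names(mets),
                     value = as.numeric(mets), stringsAsFactors = FALSE)
      }
    }
  }
  long <- if (length(longRows)) do.call(rbind, longRows) else NULL
  agg <- NULL
  if (!is.null(long) && length(unique(long$method)) >= 2L &&
      length(unique(long$dataset)) >= 2L) {
    agg <- aggregateBenchmark(long)
    write.table(agg$table, file.path(root, "stats_long.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write.table(agg$wilcoxon, file.path(root, "wilcoxon.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  logPath <- file.path(root, "batch.log")
  cat(sprintf("%d/%d pairs succeeded\n",
              length(runs) - length(failures), length(runs)),
      file = logPath)
  for (nm in names(failures)) {
    cat("FAILED ", nm, ": ", failures[[nm]], "\n", sep = "",
        file = logPath, append = TRUE)
  }
  list(runs = runs, metrics = long, aggregate = agg, failures = failures)
}

#' Human-readable ranked pathway report
#'
#' One row per pathway, ranked by ascending pG, with the DEG percentage
#' rendered as "NDE (pct)" where pct = round(100 NDE / pSize, 2), and —
#' when a ground truth is supplied — the KO confusion call at the given
#' alpha on the chosen p column.
#'
#' @param results EnrichmentResult data.frame.
#' @param truth optional named logical ground truth.
#' @param alpha significance level for the calls.
#' @param pField p column used for the calls (default "pGFdr").
#' @param onlyTrue keep only pathways containing the KO gene.
#' @return data.frame report.
#' @export
formatReport <- function(results, truth = NULL, alpha = 0.005,
                         pField = "pGFdr", onlyTrue = FALSE) {
  res <- results[order(results$pG), , drop = FALSE]
  degPct <- ifelse(res$pSize > 0,
                   round(100 * res$NDE / res$pSize, 2), 0)
  out <- data.frame(Order = seq_len(nrow(res)),
                    pathway_id = res$pathway_id, name = res$name,
                    status = res$status, pSize = res$pSize,
                    DEGs = sprintf("%d (%.2f)", res$NDE, degPct),
                    pGFdr = res$pGFdr, stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    contains <- truth[match(res$pathway_id, names(truth))]
    sig <- res[[pField]] < alpha
    out$call <- ifelse(contains & sig, "TPKO",
                       ifelse(contains & !sig, "FNKO",
                              ifelse(!contains & sig, "FPKO", "TNKO")))
    if (onlyTrue) {
      out <- out[contains, , drop = FALSE]
      out$Order <- seq_len(nrow(out))
    }
  }
  rownames(out) <- NULL
  out
}
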