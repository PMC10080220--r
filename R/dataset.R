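#' KODataset: a two-group knockout expression dataset
#'
#' A log2 expression matrix (genes x samples) with a KO vs. control design
#' and the identity of the knocked-out gene(s). Row names are
#' organism-prefixed gene identifiers.
#'
#' @slot exprs numeric matrix of log2 intensities, genes x samples.
#' @slot groups character vector per sample, values in \{"KO", "CTRL"\}.
#' @slot koGenes non-empty character vector of knocked-out gene ids.
#' @slot datasetId identifier used to name output directories.
#' @exportClass KODataset
setClass("KODataset",
  representation(exprs = "matrix", groups = "character",
                 koGenes = "character", datasetId = "character"))

setValidity("KODataset", function(object) {
  msg <- character()
  if (ncol(object@exprs) != length(object@groups))
    msg <- c(msg, "one group label per sample column is required")
  if (!all(object@groups %in% c("KO", "CTRL")))
    msg <- c(msg, "groups must be 'KO' or 'CTRL'")
  if (sum(object@groups == "KO") < 2L || sum(object@groups == "CTRL") < 2L)
    msg <- c(msg, "need at least 2 samples per group")
  if (!length(object@koGenes)) msg <- c(msg, "koGenes must be non-empty")
  if (is.null(rownames(object@exprs)) || anyDuplicated(rownames(object@exprs)))
    msg <- c(msg, "exprs must have unique row names (gene ids)")
  if (length(msg)) msg else TRUE
})

#' Construct a KODataset
#'
#' @param exprs log2 expression matrix, genes x samples, row names gene ids.
#' @param groups per-sample labels, "KO" or "CTRL".
#' @param koGenes knocked-out gene id(s).
#' @param datasetId dataset identifier.
#' @return a \linkS4class{KODataset}.
#' @export
KODataset <- function(exprs, groups, koGenes, datasetId = "dataset") {
  new("KODataset", exprs = as.matrix(exprs), groups = as.character(groups),
      koGenes = koGenes, datasetId = datasetId)
}

setMethod("show", "KODataset", function(object) {
  cat(sprintf("KODataset '%s': %d genes x %d samples (%d KO / %d CTRL)\n",
              object@datasetId, nrow(object@exprs), ncol(object@exprs),
              sum(object@groups == "KO"), sum(object@groups == "CTRL")))
  cat("  KO gene(s): ", paste(object@koGenes, collapse = ", "), "\n",
      sep = "")
})

#' @describeIn KODataset-class expression matrix accessor
#' @param object a \linkS4class{KODataset}.
#' @export
setGeneric("exprsMatrix", function(object) standardGeneric("exprsMatrix"))
setMethod("exprsMatrix", "KODataset", function(object) object@exprs)

#' @describeIn KODataset-class per-sample group labels
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
setMethod("sampleGroups", "KODataset", function(object) object@groups)

#' @describeIn KODataset-class knocked-out gene ids
#' @export
setGeneric("koGenes", function(object) standardGeneric("koGenes"))
setMethod("koGenes", "KODataset", function(object) object@koGenes)

#' @describeIn KODataset-class dataset identifier
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))
setMethod("datasetId", "KODataset", function(object) object@datasetId)

#' Read an expression dataset from delimited text
#'
#' The matrix file is tab-delimited with the gene id in the first column and
#' sample ids in the header; the design file is tab-delimited with columns
#' \code{sample} and \code{group} (values KO/CTRL).
#'
#' @param matrixFile path to the expression matrix.
#' @param designFile path to the design table.
#' @param koGenes knocked-out gene id(s).
#' @param datasetId dataset identifier (defaults to the matrix file stem).
#' @return a \linkS4class{KODataset}.
#' @export
readExpressionDataset <- function(matrixFile, designFile, koGenes,
                                  datasetId = NULL) {
  m <- read.delim(matrixFile, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m[[1]]
  design <- read.delim(designFile, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(design))) {
    stop("design file must have columns 'sample' and 'group'")
  }
  i <- match(colnames(mat), design$sample)
  if (anyNA(i)) stop("design file is missing sample(s): ",
                     paste(colnames(mat)[is.na(i)], collapse = ", "))
  KODataset(mat, design$group[i], koGenes,
            datasetId %||% sub("\\.[^.]*$", "", basename(matrixFile)))
}

#' Write a KODataset as matrix + design text files
#'
#' @param dataset a \linkS4class{KODataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (matrix, design).
#' @export
writeExpressionDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mf <- file.path(dir, paste0(datasetId(dataset), "_matrix.tsv"))
  df <- file.path(dir, paste0(datasetId(dataset), "_design.tsv"))
  mat <- exprsMatrix(dataset)
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(mat),
                         group = sampleGroups(dataset)),
              df, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mf, design = df))
}
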