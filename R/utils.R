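#' @importFrom stats median pchisq phyper pnorm pt quantile rnorm runif sd
#'   setNames var wilcox.test p.adjust uniroot ks.test
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered key for a gene pair
#'
#' Collapses a directed pair to the sorted "x|y" form used for undirected
#' edge bookkeeping.
#' @param x,y character vectors of gene identifiers.
#' @return character vector of keys.
#' @keywords internal
.pairKey <- function(x, y) {
  paste(pmin(x, y), pmax(x, y), sep = "|")
}

## deterministic RNG scope: restores the caller's .Random.seed on exit
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## stable JSON writer: full double precision, unboxed scalars, no timestamps
writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

emptyEdgeFrame <- function(pathways = FALSE) {
  df <- data.frame(source = character(), target = character(),
                   relation = character(), sign = integer(),
                   stringsAsFactors = FALSE)
  if (pathways) df$pathways <- character()
  df
}

#' Split an organism-prefixed gene identifier
#'
#' Gene identities are organism-prefixed Entrez-style strings such as
#' \code{"mmu:17874"}; the canonical form is the full prefixed string and the
#' bare numeric/body part is available on request.
#' @param id character vector of prefixed identifiers.
#' @return data.frame with columns \code{prefix} and \code{body}.
#' @examples
#' geneIdParts(c("mmu:17874", "syn:12"))
#' @export
geneIdParts <- function(id) {
  ok <- grepl("^[^:]+:.+$", id)
  if (!all(ok)) {
    stop("malformed gene identifier(s): ",
         paste(utils::head(id[!ok], 5L), collapse = ", "))
  }
  data.frame(prefix = sub(":.*$", "", id),
             body = sub("^[^:]+:", "", id),
             stringsAsFactors = FALSE)
}
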