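# ---- hand-built KGML fixtures ------------------------------------------

kgmlThreeGene <- function() {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00001" org="tst" number="00001" title="three genes">',
    '  <entry id="1" name="tst:1" type="gene"/>',
    '  <entry id="2" name="tst:2" type="gene"/>',
    '  <entry id="3" name="tst:3" type="gene"/>',
    '  <relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
    '  <relation entry1="2" entry2="3" type="PPrel"><subtype name="inhibition" value="--|"/></relation>',
    '</pathway>'), f)
  f
}

kgmlMultiGeneEntry <- function() {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00002" org="tst" number="00002" title="multi">',
    '  <entry id="1" name="tst:11 tst:12" type="gene"/>',
    '  <entry id="2" name="tst:20" type="gene"/>',
    '  <relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
    '</pathway>'), f)
  f
}

kgmlGroupEntry <- function() {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00003" org="tst" number="00003" title="group">',
    '  <entry id="1" name="tst:1" type="gene"/>',
    '  <entry id="2" name="tst:2" type="gene"/>',
    '  <entry id="3" name="undefined" type="group">',
    '    <component id="1"/><component id="2"/>',
    '  </entry>',
    '  <entry id="4" name="tst:4" type="gene"/>',
    '  <entry id="5" name="cpd:C00001" type="compound"/>',
    '  <relation entry1="3" entry2="4" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
    '  <relation entry1="4" entry2="5" type="PCrel"><subtype name="activation" value="--&gt;"/></relation>',
    '</pathway>'), f)
  f
}

kgmlEmpty <- function() {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00009" org="tst" number="00009" title="empty">',
    '  <entry id="1" name="cpd:C00001" type="compound"/>',
    '</pathway>'), f)
  f
}

# in-memory graph builders ------------------------------------------------

makePathway <- function(id, genes, src = character(), tgt = character(),
                        rel = character()) {
  edges <- data.frame(source = src, target = tgt, relation = rel,
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$relation %in%
                         c("activation", "expression", "phosphorylation"),
                       1L,
                       ifelse(edges$relation %in%
                                c("inhibition", "repression",
                                  "dephosphorylation"), -1L, 0L))
  new("PathwayGraph", pathwayId = id, pathwayName = id, organism = "tst",
      genes = genes, edges = edges)
}

makeStats <- function(gene, log2fc, p) {
  data.frame(gene = gene, log2fc = log2fc, t = log2fc, p = p,
             df = 8, s2post = 1, stringsAsFactors = FALSE)
}

makeScoreTable <- function(geneX, geneY, score) {
  out <- data.frame(geneX = geneX, geneY = geneY, score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$geneX, out$geneY), , drop = FALSE]
}

# default-condition synthetic fixture, parsed back through KGML ------------

makeFixture <- function(seed, ...) {
  spec <- fixtureSpec(seed = seed, ...)
  dir <- file.path(tempfile("fix"), "collection")
  manifest <- generatePathwayCollection(spec, dir)
  collection <- readPathwayCollection(manifest)
  dataset <- simulateKoDataset(spec, collection)
  list(spec = spec, dir = dir, manifest = manifest,
       collection = collection, dataset = dataset)
}

# independent oracles ------------------------------------------------------

# concordance AUC: P(p_pos < p_neg) + 0.5 P(tie), all pos x neg pairs
oracleAUCPairs <- function(p, truth) {
  pos <- p[truth]; neg <- p[!truth]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a < b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# hypergeometric upper tail by explicit enumeration with choose()
oracleHyper <- function(x, K, n, N) {
  ks <- seq(x, min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force at-most-one-change split minimizing within-segment SSE
oracleChangepoint <- function(y) {
  y <- sort(y, decreasing = TRUE)
  n <- length(y)
  sse <- function(v) sum((v - mean(v))^2)
  tot <- vapply(seq_len(n - 1L),
                function(k) sse(y[1:k]) + sse(y[(k + 1):n]), numeric(1))
  which.min(tot)
}

# exhaustive BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}
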