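# small generator configuration for fast tests; plantAbove overridden since
# the full-scale defaults pin more genes than these group sizes hold
tinyConfig <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, nSF = 4L, nTF = 6L, nKinase = 5L,
                   nBackgroundGenes = 100L, nBound = 30L, nControl = 60L,
                   nRandomProteins = 60L, nTissues = 3L,
                   plantAbove = list(heart = c(SF = 2, TF = 3)))
  defaults[names(args)] <- args   # non-recursive: replace wholesale
  do.call(generatorConfig, defaults)
}

sortedEdges <- function(ed) {
  ed <- ed[, c("source", "target", "edge_type")]
  ed <- ed[do.call(order, ed), ]
  rownames(ed) <- NULL
  ed
}

expectSameEdgeSet <- function(a, b) {
  expect_identical(sortedEdges(a), sortedEdges(b))
}

# hand-wired network: node table + edge table -> RegulatoryNetwork
wireNet <- function(nodes, ...) {
  edges <- data.frame(rbind(...), stringsAsFactors = FALSE)
  names(edges) <- c("source", "target", "edge_type")
  makeNetwork(nodes, edges)
}

smallNodes <- data.frame(
  gene_id = c("s1", "s2", "t1", "t2", "k1", "k2"),
  group = c("SF", "SF", "TF", "TF", "KINASE", "KINASE"))
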