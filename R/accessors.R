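#' @include AllClasses.R
NULL

#' Accessors for network and gene-model containers
#'
#' \code{networkNodes} / \code{networkEdges} return the node and typed edge
#' tables of a \linkS4class{RegulatoryNetwork}; \code{geneTable},
#' \code{exonTable} and \code{eventTable} return the three tables of a
#' \linkS4class{GeneModels}; \code{atlasValues}, \code{tissueNames} and
#' \code{tissueMeans} expose an \linkS4class{ExpressionAtlas} (tissue means
#' are taken over all atlas genes, network and background alike).
#'
#' @param x the container.
#' @return a data.frame (tables), matrix (values) or named numeric vector
#'   (tissue means).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("atlasValues", function(x) standardGeneric("atlasValues"))
#' @rdname accessors
#' @export
setGeneric("tissueNames", function(x) standardGeneric("tissueNames"))
#' @rdname accessors
#' @export
setGeneric("tissueMeans", function(x) standardGeneric("tissueMeans"))

#' @rdname accessors
setMethod("networkNodes", "RegulatoryNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("geneTable", "GeneModels", function(x) x@genes)
#' @rdname accessors
setMethod("exonTable", "GeneModels", function(x) x@exons)
#' @rdname accessors
setMethod("eventTable", "GeneModels", function(x) x@events)
#' @rdname accessors
setMethod("geneTable", "SyntheticBundle", function(x) x@genes@genes)
#' @rdname accessors
setMethod("atlasValues", "ExpressionAtlas", function(x) x@values)
#' @rdname accessors
setMethod("tissueNames", "ExpressionAtlas", function(x) colnames(x@values))
#' @rdname accessors
setMethod("tissueMeans", "ExpressionAtlas", function(x) colMeans(x@values))

#' Per-node inedge counts of one edge type
#'
#' Counts, for every network node, the number of distinct regulators wiring
#' an edge of the given type into it. Self-loops are counted by default, as
#' autoregulation is a real regulatory edge.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param edgeType "splicing" or "transcription".
#' @param selfLoops count self-edges? Default TRUE.
#' @return named integer vector over all nodes (zeros included).
#' @export
inedgeCounts <- function(network, edgeType, selfLoops = TRUE) {
  edgeType <- assertEdgeType(edgeType)
  nd <- network@nodes
  ed <- network@edges
  ed <- ed[ed$edge_type == edgeType, , drop = FALSE]
  if (!selfLoops) ed <- ed[ed$source != ed$target, , drop = FALSE]
  counts <- table(factor(ed$target, levels = nd$gene_id))
  stats::setNames(as.integer(counts), nd$gene_id)
}

#' @rdname inedgeCounts
#' @export
outedgeCounts <- function(network, edgeType, selfLoops = TRUE) {
  edgeType <- assertEdgeType(edgeType)
  nd <- network@nodes
  ed <- network@edges
  ed <- ed[ed$edge_type == edgeType, , drop = FALSE]
  if (!selfLoops) ed <- ed[ed$source != ed$target, , drop = FALSE]
  counts <- table(factor(ed$source, levels = nd$gene_id))
  stats::setNames(as.integer(counts), nd$gene_id)
}

setMethod("show", "GeneModels", function(object) {
  g <- object@genes
  cat("GeneModels with", nrow(g), "genes (",
      paste(sprintf("%s=%d", names(table(g$group)), table(g$group)),
            collapse = ", "),
      "),", nrow(object@exons), "exons,", nrow(object@events), "AS events\n")
})

setMethod("show", "RegulatoryNetwork", function(object) {
  ed <- object@edges
  cat("RegulatoryNetwork:", nrow(object@nodes), "nodes,", nrow(ed),
      "typed edges (splicing:", sum(ed$edge_type == "splicing"),
      ", transcription:", sum(ed$edge_type == "transcription"),
      "), dataset", object@dataset, "\n")
  print(table(object@nodes$layer))
})

setMethod("show", "ExpressionAtlas", function(object) {
  cat("ExpressionAtlas:", nrow(object@values), "genes (",
      length(object@networkGenes), "network ) x",
      ncol(object@values), "tissues:",
      paste(utils::head(colnames(object@values), 5), collapse = ", "),
      if (ncol(object@values) > 5) "..." else "", "\n")
})

setMethod("show", "NullEnsembleResult", function(object) {
  cat(sprintf(
    "NullEnsembleResult [%s, %s null, n=%d]\n  observed = %.4f, null = %.4f +/- %.4f, z = %s, empirical p = %.3g\n",
    object@stat, object@nullModel, object@nRandom, object@observed,
    object@nullMean, object@nullSd,
    if (is.na(object@z)) "NA" else sprintf("%.2f", object@z),
    object@empiricalP))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle (seed", object@config$seed, ")\n")
  show(object@genes)
  cat(" ", nrow(object@sfHits), "SF motif hits,", nrow(object@tfHits),
      "TF motif hits\n")
  if (!is.null(object@atlas)) show(object@atlas)
})
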