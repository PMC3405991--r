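hitsToGRanges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    factor_id = hits$factor_id, conserved = hits$conserved)
}

checkHitFactors <- function(hits, genes, group) {
  g <- geneTable(genes)
  known <- g$gene_id[g$group == group]
  bad <- setdiff(unique(hits$factor_id), known)
  if (length(bad))
    stop("motif hits reference unknown ", group, " factors: ",
         paste(bad, collapse = ", "))
}

collapseEdges <- function(src, tgt, edge_type) {
  if (!length(src)) {
    return(data.frame(source = character(0), target = character(0),
                      edge_type = character(0), n_evidence = integer(0)))
  }
  key <- paste(src, tgt, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(source = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    edge_type = edge_type,
                    n_evidence = as.integer(tab))
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wire splicing regulatory edges from SF motif hits
#'
#' An edge (SF_i -> gene_j, splicing) is added iff gene_j has at least one
#' AS event (in the chosen dataset) such that at least one qualifying hit of
#' SF_i overlaps at least one of that event's search regions (see
#' \code{\link{splicingSearchRegions}}). Overlap means nonempty interval
#' intersection: a single shared base suffices, and a hit spanning an
#' exon/intron junction counts once. Self-edges (autoregulation) are
#' permitted. Parallel evidence for one (source, target) pair collapses into
#' an evidence count.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param hits SF motif-hit data.frame (factor_id, chrom, start, end,
#'   conserved).
#' @param windowNt intron search window (default 100).
#' @param requireConserved keep only conserved hits (default TRUE).
#' @param dataset AS-event dataset tag to wire from ("A" or "B").
#' @return edge data.frame (source, target, edge_type, n_evidence).
#' @export
buildSplicingEdges <- function(genes, hits, windowNt = 100,
                               requireConserved = TRUE, dataset = "A") {
  checkHitFactors(hits, genes, "SF")
  if (requireConserved) hits <- hits[hits$conserved, , drop = FALSE]
  if (!nrow(hits)) return(collapseEdges(character(0), character(0),
                                        "splicing"))
  regions <- eventSearchRegions(genes, windowNt = windowNt,
                                dataset = dataset)
  if (!length(regions)) return(collapseEdges(character(0), character(0),
                                             "splicing"))
  hitGr <- hitsToGRanges(hits)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(hitGr, regions, ignore.strand = TRUE))
  src <- hitGr$factor_id[S4Vectors::queryHits(ov)]
  tgt <- regions$gene_id[S4Vectors::subjectHits(ov)]
  # one hit supporting several regions of the same event, or several events
  # of the same gene, is a single piece of evidence per (hit, target)
  uniq <- !duplicated(paste(S4Vectors::queryHits(ov), tgt))
  collapseEdges(src[uniq], tgt[uniq], "splicing")
}

#' Wire transcription regulatory edges from TF promoter hits
#'
#' An edge (TF_i -> gene_j, transcription) is added iff at least one
#' qualifying hit of TF_i overlaps the \code{promoterNt} bases strictly
#' upstream of gene_j's TSS in transcript orientation (the TSS base itself
#' is excluded; see \code{\link{promoterRegions}}). Self-edges permitted.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param hits TF motif-hit data.frame.
#' @param promoterNt promoter span (default 5000).
#' @param requireConserved keep only conserved hits (default TRUE).
#' @return edge data.frame (source, target, edge_type, n_evidence).
#' @export
buildTranscriptionEdges <- function(genes, hits, promoterNt = 5000,
                                    requireConserved = TRUE) {
  checkHitFactors(hits, genes, "TF")
  if (requireConserved) hits <- hits[hits$conserved, , drop = FALSE]
  if (!nrow(hits)) return(collapseEdges(character(0), character(0),
                                        "transcription"))
  prom <- promoterRegions(genes, promoterNt = promoterNt)
  hitGr <- hitsToGRanges(hits)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(hitGr, prom, ignore.strand = TRUE))
  src <- hitGr$factor_id[S4Vectors::queryHits(ov)]
  tgt <- prom$gene_id[S4Vectors::subjectHits(ov)]
  collapseEdges(src, tgt, "transcription")
}

#' Assemble the typed network and classify nodes into layers
#'
#' Combines the splicing and transcription edge sets over the full node set
#' and labels each node: \emph{source} (outedges only), \emph{mixed} (both),
#' \emph{sink} (inedges only), \emph{isolated} (neither). Kinases emit no
#' edges by construction, so they can only be sink or isolated.
#'
#' @param genes a \linkS4class{GeneModels} (or its gene table).
#' @param splicingEdges,transcriptionEdges edge data.frames from the
#'   builders above.
#' @param dataset tag recorded on the network.
#' @param params wiring parameters to record.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
assembleNetwork <- function(genes, splicingEdges, transcriptionEdges,
                            dataset = "A", params = list()) {
  g <- if (is(genes, "GeneModels")) geneTable(genes) else genes
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids")
  edges <- rbind(splicingEdges, transcriptionEdges)
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$source, edges$target)), g$gene_id)
    if (length(missing))
      stop("edge endpoints not among genes: ",
           paste(missing, collapse = ", "))
  }
  outdeg <- table(factor(edges$source, levels = g$gene_id))
  indeg <- table(factor(edges$target, levels = g$gene_id))
  layer <- ifelse(outdeg > 0 & indeg > 0, "mixed",
           ifelse(outdeg > 0, "source",
           ifelse(indeg > 0, "sink", "isolated")))
  nodes <- data.frame(gene_id = g$gene_id, group = g$group,
                      layer = as.character(layer))
  rownames(edges) <- NULL
  new("RegulatoryNetwork", nodes = nodes, edges = edges,
      dataset = dataset, params = params)
}

#' Build the integrated network from a synthetic bundle in one call
#'
#' Convenience wrapper running \code{\link{buildSplicingEdges}},
#' \code{\link{buildTranscriptionEdges}} and \code{\link{assembleNetwork}}
#' on the tables of a \linkS4class{SyntheticBundle}.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dataset AS-event dataset ("A" or "B").
#' @param windowNt,promoterNt,requireConserved wiring parameters.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
buildNetwork <- function(bundle, dataset = "A",
                         windowNt = bundle@config$windowNt,
                         promoterNt = bundle@config$promoterNt,
                         requireConserved = TRUE) {
  sp <- buildSplicingEdges(bundle@genes, bundle@sfHits, windowNt = windowNt,
                           requireConserved = requireConserved,
                           dataset = dataset)
  tr <- buildTranscriptionEdges(bundle@genes, bundle@tfHits,
                                promoterNt = promoterNt,
                                requireConserved = requireConserved)
  assembleNetwork(bundle@genes, sp, tr, dataset = dataset,
                  params = list(windowNt = windowNt,
                                promoterNt = promoterNt,
                                requireConserved = requireConserved))
}

#' Construct a RegulatoryNetwork directly from node and edge tables
#'
#' Used by the loaders and by tests that wire small networks by hand; layer
#' labels are (re)derived from the edges.
#'
#' @param nodes data.frame with gene_id and group.
#' @param edges data.frame with source, target, edge_type (and optionally
#'   n_evidence).
#' @param dataset tag to record.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
makeNetwork <- function(nodes, edges, dataset = "A") {
  if (is.null(edges$n_evidence)) edges$n_evidence <- rep(1L, nrow(edges))
  edges <- edges[!duplicated(edges[, c("source", "target", "edge_type")]), ,
                 drop = FALSE]
  g <- data.frame(gene_id = nodes$gene_id, group = nodes$group)
  sp <- edges[edges$edge_type == "splicing", , drop = FALSE]
  tr <- edges[edges$edge_type == "transcription", , drop = FALSE]
  assembleNetwork(g, sp, tr, dataset = dataset)
}
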