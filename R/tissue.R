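#' Above-average expression filter for one tissue
#'
#' Keeps the network genes whose expression in the tissue is strictly above
#' the tissue mean, where the mean is taken over ALL atlas genes (network
#' plus background), mirroring normalization against everything on the
#' array. Genes at exactly the mean are excluded (ties have measure ~0 on
#' real arrays); network genes absent from the atlas are excluded with a
#' warning.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param tissue tissue (column) name.
#' @return character vector of retained gene ids.
#' @export
tissueFilter <- function(atlas, network, tissue) {
  v <- atlasValues(atlas)
  if (!tissue %in% colnames(v)) stop("tissue not in atlas: ", tissue)
  ids <- network@nodes$gene_id
  missing <- setdiff(ids, rownames(v))
  if (length(missing)) {
    warning(length(missing), " network gene(s) missing from the atlas, ",
            "excluded: ", paste(utils::head(missing, 5), collapse = ", "))
    ids <- setdiff(ids, missing)
  }
  m <- mean(v[, tissue])
  ids[v[ids, tissue] > m]
}

#' Induce a tissue-specific subnetwork and recompute group densities
#'
#' The induced subgraph keeps exactly the edges whose source AND target both
#' belong to the node subset, then recomputes layers and per-group inedge
#' densities (mean +/- sem of splicing and transcription inedges for the SF
#' and TF groups, the layout used for tissue-specific density tables).
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param nodeSubset character vector of gene ids (subset of the nodes).
#' @return list with \code{network} (the induced
#'   \linkS4class{RegulatoryNetwork}) and \code{density} (data.frame:
#'   group, edge_type, n, mean, sem; empty with a note when the subset is
#'   empty).
#' @export
induceSubnetwork <- function(network, nodeSubset) {
  extra <- setdiff(nodeSubset, network@nodes$gene_id)
  if (length(extra))
    stop("subset contains non-network genes: ",
         paste(utils::head(extra, 5), collapse = ", "))
  nd <- network@nodes[network@nodes$gene_id %in% nodeSubset, , drop = FALSE]
  ed <- network@edges
  ed <- ed[ed$source %in% nodeSubset & ed$target %in% nodeSubset, ,
           drop = FALSE]
  if (!nrow(nd)) {
    empty <- assembleNetwork(
      data.frame(gene_id = character(0), group = character(0)),
      ed[0, ], ed[0, ], dataset = network@dataset)
    return(list(network = empty,
                density = data.frame(group = character(0),
                                     edge_type = character(0),
                                     n = integer(0), mean = numeric(0),
                                     sem = numeric(0))))
  }
  sub <- assembleNetwork(
    data.frame(gene_id = nd$gene_id, group = nd$group),
    ed[ed$edge_type == "splicing", , drop = FALSE],
    ed[ed$edge_type == "transcription", , drop = FALSE],
    dataset = network@dataset, params = network@params)
  dens <- rbind(inedgeDensity(sub, "splicing"),
                inedgeDensity(sub, "transcription"))
  dens <- dens[dens$group %in% c("SF", "TF"),
               c("group", "edge_type", "n", "mean", "sem")]
  rownames(dens) <- NULL
  list(network = sub, density = dens)
}

#' One-call tissue-specific subnetwork
#'
#' \code{\link{tissueFilter}} followed by \code{\link{induceSubnetwork}}.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param tissue tissue name.
#' @return as \code{\link{induceSubnetwork}}, plus \code{kept} (the node
#'   subset).
#' @export
tissueSubnetwork <- function(atlas, network, tissue) {
  kept <- tissueFilter(atlas, network, tissue)
  out <- induceSubnetwork(network, kept)
  out$kept <- kept
  out
}
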