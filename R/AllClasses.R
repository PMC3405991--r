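#' @import methods
#' @importFrom S4Vectors isSorted
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Gene models for the regulatory network
#'
#' Container for the gene-level inputs of network construction: one row per
#' gene (identifier, regulator group, chromosome, strand, TSS, span), the
#' exon table in transcript order, and the alternative-splicing event table.
#' All coordinates are 1-based closed intervals; each gene lives on its own
#' chromosome in synthetic data, but nothing requires that.
#'
#' The event table stores, per event, the event exon and the flanking introns
#' resolved in transcript orientation (\code{up_*} is the transcript-upstream
#' intron regardless of strand). Alternative 3' events carry no downstream
#' search intron and alternative 5' events no upstream one (NA columns).
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{group} (SF, TF
#'   or KINASE), \code{chrom}, \code{strand}, \code{tss}, \code{start},
#'   \code{end}, \code{n_exons}, \code{gene_length}.
#' @slot exons data.frame with columns \code{gene_id}, \code{rank} (transcript
#'   order), \code{start}, \code{end}.
#' @slot events data.frame with columns \code{event_id}, \code{gene_id},
#'   \code{dataset} (A or B), \code{event_type} (cassette, alt3, alt5),
#'   \code{chrom}, \code{strand}, \code{exon_start}, \code{exon_end},
#'   \code{up_start}, \code{up_end}, \code{down_start}, \code{down_end}.
#' @aliases GeneModels
#' @export
setClass("GeneModels",
  representation(genes = "data.frame", exons = "data.frame",
                 events = "data.frame"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  msgs <- character(0)
  need <- c("gene_id", "group", "chrom", "strand", "tss", "start", "end",
            "n_exons", "gene_length")
  if (!all(need %in% names(g)))
    return(paste("genes table missing columns:",
                 paste(setdiff(need, names(g)), collapse = ", ")))
  if (anyDuplicated(g$gene_id)) msgs <- c(msgs, "duplicate gene ids")
  if (!all(g$group %in% GROUPS))
    msgs <- c(msgs, "group must be one of SF, TF, KINASE")
  if (!all(g$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be + or -")
  plus <- g$strand == "+"
  if (any(g$tss[plus] != g$start[plus]) || any(g$tss[!plus] != g$end[!plus]))
    msgs <- c(msgs, "tss inconsistent with strand (start on +, end on -)")
  ex <- object@exons
  if (nrow(ex)) {
    if (!all(ex$gene_id %in% g$gene_id))
      msgs <- c(msgs, "exon rows reference unknown genes")
    bad <- vapply(split(ex, ex$gene_id), function(d) {
      d <- d[order(d$start), , drop = FALSE]
      any(d$end < d$start) ||
        (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
    }, logical(1))
    if (any(bad)) msgs <- c(msgs, "exons must be disjoint ordered intervals")
  }
  ev <- object@events
  if (nrow(ev)) {
    if (!all(ev$gene_id %in% g$gene_id))
      msgs <- c(msgs, "event rows reference unknown genes")
    if (!all(ev$event_type %in% c("cassette", "alt3", "alt5")))
      msgs <- c(msgs, "bad event_type")
    if (!all(ev$dataset %in% c("A", "B")))
      msgs <- c(msgs, "event dataset must be A or B")
    if (any(ev$event_type == "alt3" & !is.na(ev$down_start)))
      msgs <- c(msgs, "alt3 events must not define a downstream intron")
    if (any(ev$event_type == "alt5" & !is.na(ev$up_start)))
      msgs <- c(msgs, "alt5 events must not define an upstream intron")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Typed directed regulatory network
#'
#' The assembled network: nodes are genes labelled by regulator group and
#' layer (source / mixed / sink / isolated); edges are typed (splicing edges
#' have SF sources, transcription edges TF sources), collapsed so at most one
#' edge exists per (source, target, type) with parallel motif evidence
#' recorded as a count. Self-loops (autoregulation) are permitted.
#'
#' @slot nodes data.frame with columns \code{gene_id}, \code{group},
#'   \code{layer}.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{edge_type}, \code{n_evidence}.
#' @slot dataset which AS-event dataset the splicing edges were wired from.
#' @slot params list of wiring parameters (window, promoter span, flags).
#' @aliases RegulatoryNetwork
#' @export
setClass("RegulatoryNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 dataset = "character", params = "list"))

setValidity("RegulatoryNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  msgs <- character(0)
  if (anyDuplicated(nd$gene_id)) msgs <- c(msgs, "duplicate node ids")
  if (!all(nd$group %in% GROUPS)) msgs <- c(msgs, "bad node group")
  if (!all(nd$layer %in% c("source", "mixed", "sink", "isolated")))
    msgs <- c(msgs, "bad layer label")
  if (nrow(ed)) {
    if (!all(ed$edge_type %in% c("splicing", "transcription")))
      msgs <- c(msgs, "bad edge_type")
    if (!all(c(ed$source, ed$target) %in% nd$gene_id))
      msgs <- c(msgs, "edge endpoints must be network nodes")
    grp <- stats::setNames(nd$group, nd$gene_id)
    if (any(ed$edge_type == "splicing" & grp[ed$source] != "SF"))
      msgs <- c(msgs, "splicing edges must have SF sources")
    if (any(ed$edge_type == "transcription" & grp[ed$source] != "TF"))
      msgs <- c(msgs, "transcription edges must have TF sources")
    if (anyDuplicated(ed[, c("source", "target", "edge_type")]))
      msgs <- c(msgs, "duplicate typed edges must be collapsed")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Gene-by-tissue expression atlas
#'
#' Expression values for the network genes plus a background gene set; the
#' per-tissue mean over ALL atlas genes (network and background) defines the
#' above-average expression filter used for tissue-specific subnetworks.
#'
#' @slot values numeric matrix, genes in rows, tissues in columns.
#' @slot networkGenes character vector of row names that are network genes.
#' @aliases ExpressionAtlas
#' @export
setClass("ExpressionAtlas",
  representation(values = "matrix", networkGenes = "character"))

setValidity("ExpressionAtlas", function(object) {
  v <- object@values
  msgs <- character(0)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have gene row names and tissue column names")
  if (!all(is.finite(v))) msgs <- c(msgs, "all expression values must be finite")
  if (!all(object@networkGenes %in% rownames(v)))
    msgs <- c(msgs, "networkGenes must be atlas rows")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Observed statistic versus a randomized network ensemble
#'
#' @slot observed observed value of the statistic.
#' @slot nullMean,nullSd moments of the null ensemble.
#' @slot z standardized score (NA when the null sd is zero).
#' @slot empiricalP upper-tail empirical p, (r + 1) / (nRandom + 1).
#' @slot nullValues the per-replicate statistic values.
#' @slot nRandom,seed,nullModel,stat ensemble bookkeeping.
#' @aliases NullEnsembleResult
#' @export
setClass("NullEnsembleResult",
  representation(observed = "numeric", nullMean = "numeric",
                 nullSd = "numeric", z = "numeric", empiricalP = "numeric",
                 nullValues = "numeric", nRandom = "integer",
                 seed = "integer", nullModel = "character",
                 stat = "character"))

setValidity("NullEnsembleResult", function(object) {
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must lie in (0, 1]")
  if (object@nRandom < 1L) return("nRandom must be >= 1")
  TRUE
})

#' Complete synthetic input bundle
#'
#' Everything the pipeline consumes, generated from one \code{generatorConfig}:
#' gene models with AS events, SF and TF motif-hit tables, expression atlas,
#' residue-level protein annotations, labelled 41-nt sequence sets, and the
#' ground-truth record of what was planted (sufficient to predict expected
#' per-group inedge means analytically).
#'
#' @slot config the generator configuration used.
#' @slot genes a \linkS4class{GeneModels}.
#' @slot sfHits,tfHits motif-hit data.frames (factor_id, chrom, start, end,
#'   conserved).
#' @slot atlas an \linkS4class{ExpressionAtlas} or NULL.
#' @slot annotations protein annotation data.frame or NULL.
#' @slot sequences labelled sequence sets (list) or NULL.
#' @slot truth ground-truth list: planted edge table per dataset, planted
#'   probabilities, per-tissue planted gene sets, etc.
#' @aliases SyntheticBundle
#' @export
setClass("SyntheticBundle",
  representation(config = "list", genes = "GeneModels",
                 sfHits = "data.frame", tfHits = "data.frame",
                 atlas = "ANY", annotations = "ANY",
                 sequences = "listOrNULL", truth = "list"))

setValidity("SyntheticBundle", function(object) {
  g <- object@genes@genes
  regs <- g$gene_id[g$group %in% c("SF", "TF")]
  msgs <- character(0)
  if (nrow(object@sfHits) &&
      !all(object@sfHits$factor_id %in% g$gene_id[g$group == "SF"]))
    msgs <- c(msgs, "sfHits factor ids must be SF genes")
  if (nrow(object@tfHits) &&
      !all(object@tfHits$factor_id %in% g$gene_id[g$group == "TF"]))
    msgs <- c(msgs, "tfHits factor ids must be TF genes")
  te <- object@truth$planted_edges
  if (!is.null(te) && nrow(te) &&
      !all(te$source %in% regs & te$target %in% g$gene_id))
    msgs <- c(msgs, "planted edges must connect known genes")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
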