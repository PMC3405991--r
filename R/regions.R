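#' Splicing-motif search regions for an alternative-splicing event
#'
#' An SF binding motif supports a splicing edge only if it falls close to the
#' regulated event. The searchable region depends on the event type:
#' \itemize{
#'   \item cassette exon: the last \code{windowNt} bases of the transcript-
#'     upstream intron, the entire event exon, and the first \code{windowNt}
#'     bases of the transcript-downstream intron;
#'   \item alternative 3' splice site: the upstream-intron window and the
#'     entire exon (no downstream search region);
#'   \item alternative 5' splice site: the entire exon and the downstream-
#'     intron window (no upstream search region).
#' }
#' Intron windows are truncated to the intron when it is shorter than
#' \code{windowNt}; upstream/downstream are resolved in transcript
#' orientation, so on the minus strand the upstream intron lies genomically
#' to the right of the exon. Coordinates are 1-based closed.
#'
#' @param event a single-row data.frame (one row of \code{eventTable}) with
#'   columns \code{event_type}, \code{strand}, \code{exon_start},
#'   \code{exon_end}, \code{up_start}, \code{up_end}, \code{down_start},
#'   \code{down_end} (NA where the intron is undefined).
#' @param windowNt nonnegative intron window size in nucleotides
#'   (default 100).
#' @return data.frame with columns \code{start}, \code{end}, \code{role}
#'   (one of "upstream_window", "event_exon", "downstream_window").
#' @examples
#' ev <- data.frame(event_type = "cassette", strand = "+",
#'                  exon_start = 1001, exon_end = 1100,
#'                  up_start = 801, up_end = 1000,
#'                  down_start = 1101, down_end = 1400)
#' splicingSearchRegions(ev)
#' @export
splicingSearchRegions <- function(event, windowNt = 100) {
  stopifnot(nrow(event) == 1L, windowNt >= 0)
  type <- as.character(event$event_type)
  if (!type %in% c("cassette", "alt3", "alt5"))
    stop("unknown event_type: ", type)
  stopifnot(as.character(event$strand) %in% c("+", "-"))
  for (col in c("gene_id", "event_id", "chrom"))
    if (is.null(event[[col]])) event[[col]] <- ""
  for (col in c("up_start", "up_end", "down_start", "down_end"))
    if (is.null(event[[col]])) event[[col]] <- NA_integer_
  out <- regionTable(event, windowNt)[, c("start", "end", "role")]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search regions for every event of a GeneModels object, as GRanges
#'
#' Vectorized companion of \code{\link{splicingSearchRegions}} used by the
#' edge builder: one range per (event, region) with the owning gene and
#' event recorded in the metadata columns.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param windowNt intron window size.
#' @param dataset restrict to events of this dataset tag ("A" or "B");
#'   NULL keeps all.
#' @return a \link[GenomicRanges]{GRanges} with mcols \code{gene_id},
#'   \code{event_id}, \code{role}.
#' @export
eventSearchRegions <- function(genes, windowNt = 100, dataset = NULL) {
  ev <- eventTable(genes)
  if (!is.null(dataset)) ev <- ev[ev$dataset == dataset, , drop = FALSE]
  if (!nrow(ev)) {
    return(GenomicRanges::GRanges(gene_id = character(0),
                                  event_id = character(0),
                                  role = character(0)))
  }
  tab <- regionTable(ev, windowNt)
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    gene_id = tab$gene_id, event_id = tab$event_id, role = tab$role)
}

# flat data.frame of search regions for an event table, fully vectorized
# (internal; splicingSearchRegions delegates here so the window rule has a
# single implementation)
regionTable <- function(ev, windowNt) {
  stopifnot(all(ev$event_type %in% c("cassette", "alt3", "alt5")),
            all(ev$strand %in% c("+", "-")), windowNt >= 0)
  plus <- ev$strand == "+"
  # transcript-upstream window abuts the exon start on +, the exon end on -
  upS <- ifelse(plus, pmax(ev$up_start, ev$exon_start - windowNt),
                ev$up_start)
  upE <- ifelse(plus, ev$up_end, pmin(ev$up_end, ev$exon_end + windowNt))
  downS <- ifelse(plus, ev$down_start,
                  pmax(ev$down_start, ev$exon_start - windowNt))
  downE <- ifelse(plus, pmin(ev$down_end, ev$exon_end + windowNt),
                  ev$down_end)
  meta <- data.frame(gene_id = ev$gene_id, event_id = ev$event_id,
                     chrom = ev$chrom)
  useUp <- ev$event_type %in% c("cassette", "alt3") & !is.na(ev$up_start) &
    windowNt > 0
  useDown <- ev$event_type %in% c("cassette", "alt5") &
    !is.na(ev$down_start) & windowNt > 0
  out <- rbind(
    cbind(data.frame(start = upS[useUp], end = upE[useUp],
                     role = rep("upstream_window", sum(useUp))),
          meta[useUp, , drop = FALSE]),
    cbind(data.frame(start = ev$exon_start, end = ev$exon_end,
                     role = rep("event_exon", nrow(ev))), meta),
    cbind(data.frame(start = downS[useDown], end = downE[useDown],
                     role = rep("downstream_window", sum(useDown))),
          meta[useDown, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Promoter intervals for a set of genes
#'
#' The promoter is the \code{promoterNt} bases strictly upstream of the TSS
#' in transcript orientation; the TSS base itself is excluded. On the plus
#' strand this is \code{[tss - promoterNt, tss - 1]}, on the minus strand
#' \code{[tss + 1, tss + promoterNt]} (1-based closed). Starts are clipped
#' at 1.
#'
#' @param genes a \linkS4class{GeneModels} or its gene data.frame.
#' @param promoterNt promoter span in nucleotides (default 5000).
#' @return a \link[GenomicRanges]{GRanges} with mcol \code{gene_id}.
#' @export
promoterRegions <- function(genes, promoterNt = 5000) {
  stopifnot(promoterNt > 0)
  g <- if (is(genes, "GeneModels")) geneTable(genes) else genes
  plus <- g$strand == "+"
  start <- ifelse(plus, pmax(1, g$tss - promoterNt), g$tss + 1)
  end <- ifelse(plus, g$tss - 1, g$tss + promoterNt)
  keep <- end >= start
  GenomicRanges::GRanges(
    seqnames = g$chrom[keep],
    ranges = IRanges::IRanges(start = start[keep], end = end[keep]),
    gene_id = g$gene_id[keep])
}
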