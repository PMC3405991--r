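writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write and read gene models as TSV
#'
#' Three tab-separated files: the gene table, the exon table and the AS
#' event table, 1-based closed coordinates throughout.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param dir output directory (created if needed).
#' @return (write) invisibly, the written paths; (read) a
#'   \linkS4class{GeneModels}.
#' @export
writeGeneModels <- function(genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genes.tsv", "exons.tsv", "events.tsv"))
  writeTsv(geneTable(genes), paths[1])
  writeTsv(exonTable(genes), paths[2])
  writeTsv(eventTable(genes), paths[3])
  invisible(paths)
}

#' @rdname writeGeneModels
#' @export
readGeneModels <- function(dir) {
  new("GeneModels",
      genes = readTsv(file.path(dir, "genes.tsv")),
      exons = readTsv(file.path(dir, "exons.tsv")),
      events = readTsv(file.path(dir, "events.tsv")))
}

#' Write and read motif hits as BED6
#'
#' BED name = factor id, score = 1000 for conserved hits and 0 otherwise,
#' strand ".". The BED convention (0-based half-open) is handled by
#' rtracklayer; in-memory coordinates are 1-based closed.
#'
#' @param hits motif-hit data.frame (factor_id, chrom, start, end,
#'   conserved).
#' @param path BED file path.
#' @return (write) the path invisibly; (read) the hits data.frame.
#' @export
writeMotifHitsBed <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(hits$start, hits$end),
    name = hits$factor_id,
    score = ifelse(hits$conserved, 1000L, 0L))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeMotifHitsBed
#' @export
readMotifHitsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(factor_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             score = as.integer(gr$score),
             conserved = gr$score > 0)[,
               c("factor_id", "chrom", "start", "end", "conserved")]
}

#' Write and read an expression atlas as a TSV matrix
#'
#' One row per gene with a \code{gene_id} column, a logical \code{network}
#' column separating network genes from array background, and one column
#' per tissue.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param path TSV path.
#' @return (write) the path invisibly; (read) an
#'   \linkS4class{ExpressionAtlas}.
#' @export
writeAtlas <- function(atlas, path) {
  v <- atlasValues(atlas)
  df <- data.frame(gene_id = rownames(v),
                   network = rownames(v) %in% atlas@networkGenes,
                   v, check.names = FALSE)
  writeTsv(df, path)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  df <- readTsv(path, check.names = FALSE)
  v <- as.matrix(df[, setdiff(names(df), c("gene_id", "network")),
                    drop = FALSE])
  rownames(v) <- df$gene_id
  new("ExpressionAtlas", values = v,
      networkGenes = df$gene_id[as.logical(df$network)])
}

#' Write and read a regulatory network as edge-list and node TSVs
#'
#' The edge list has columns source, target, edge_type, n_evidence; the node
#' table gene_id, group, layer. Reading rederives the layers from the edges.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param edgePath,nodePath TSV paths.
#' @param dataset dataset tag to record on the loaded network.
#' @return (write) the paths invisibly; (read) a
#'   \linkS4class{RegulatoryNetwork}.
#' @export
writeEdgeList <- function(network, edgePath, nodePath) {
  writeTsv(networkEdges(network), edgePath)
  writeTsv(networkNodes(network), nodePath)
  invisible(c(edgePath, nodePath))
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(edgePath, nodePath, dataset = "A") {
  edges <- readTsv(edgePath)
  nodes <- readTsv(nodePath)
  makeNetwork(nodes, edges, dataset = dataset)
}

#' Write protein annotations as TSV
#'
#' Phospho positions and disorder scores are serialized as comma-joined
#' fields; scores keep 3 decimals, enough to preserve classification at the
#' 0.75 cutoff (scores are generated away from the boundary).
#'
#' @param annotations annotation data.frame with list-columns.
#' @param path TSV path.
#' @return (write) the path invisibly; (read) the annotation data.frame.
#' @export
writeAnnotations <- function(annotations, path) {
  df <- data.frame(
    protein_id = annotations$protein_id,
    group = annotations$group,
    length = annotations$length,
    phospho = vapply(annotations$phospho, paste, "", collapse = ","),
    disorder = vapply(annotations$disorder,
                      function(s) paste(sprintf("%.3f", s), collapse = ","),
                      ""))
  writeTsv(df, path)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  df <- readTsv(path, colClasses = c(phospho = "character",
                                     disorder = "character"))
  out <- df[, c("protein_id", "group", "length")]
  out$phospho <- lapply(strsplit(df$phospho, ","), function(x)
    as.integer(x[nzchar(x)]))
  out$disorder <- lapply(strsplit(df$disorder, ","), function(x)
    as.numeric(x[nzchar(x)]))
  out
}

#' Write labelled sequence sets as FASTA
#'
#' @param sequences list as returned by \code{\link{generateSequenceSets}}.
#' @param dir output directory.
#' @return the written paths, invisibly.
#' @export
writeSequenceSets <- function(sequences, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("bound.fa", "control.fa"))
  bound <- sequences$bound
  names(bound) <- sprintf("bound_%04d", seq_along(bound))
  control <- sequences$control
  names(control) <- sprintf("control_%04d", seq_along(control))
  Biostrings::writeXStringSet(bound, paths[1])
  Biostrings::writeXStringSet(control, paths[2])
  invisible(paths)
}

#' Write a complete synthetic bundle to a directory
#'
#' Gene models, exons and events as TSV; SF and TF motif hits as BED6;
#' expression atlas and protein annotations as TSV; sequence sets as FASTA;
#' and the ground-truth record (planted edges, planting probabilities,
#' event fractions, expected inedge means, planted tissue sets) as JSON.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGeneModels(bundle@genes, dir)
  writeMotifHitsBed(bundle@sfHits, file.path(dir, "sf_hits.bed"))
  writeMotifHitsBed(bundle@tfHits, file.path(dir, "tf_hits.bed"))
  if (!is.null(bundle@atlas))
    writeAtlas(bundle@atlas, file.path(dir, "atlas.tsv"))
  if (!is.null(bundle@annotations))
    writeAnnotations(bundle@annotations, file.path(dir, "annotations.tsv"))
  if (!is.null(bundle@sequences))
    writeSequenceSets(bundle@sequences, dir)
  truth <- bundle@truth
  truth$plant_prob <- as.data.frame(truth$plant_prob)
  truth$frac_with_event <- as.data.frame(truth$frac_with_event)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' Export a per-node inedge table in the supplementary-spreadsheet layout
#'
#' One row per network node with its group and, per edge type, both the
#' regulator identity list (comma-joined) and the count, the two dialects a
#' supplementary inedge spreadsheet can carry once exported to TSV.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param path TSV path.
#' @param identities include the regulator identity columns (TRUE) or only
#'   counts (FALSE).
#' @return the path, invisibly.
#' @export
writeSupplementaryTable <- function(network, path, identities = TRUE) {
  nd <- networkNodes(network)
  ed <- networkEdges(network)
  regList <- function(type, tgt) {
    d <- ed[ed$edge_type == type & ed$target == tgt, , drop = FALSE]
    paste(sort(d$source), collapse = ",")
  }
  df <- data.frame(gene_id = nd$gene_id, group = nd$group)
  spl <- vapply(nd$gene_id, regList, "", type = "splicing")
  trn <- vapply(nd$gene_id, regList, "", type = "transcription")
  if (identities) {
    df$splicing_regulators <- spl
    df$transcription_regulators <- trn
  }
  df$splicing_inedges <- vapply(strsplit(spl, ","), function(x)
    sum(nzchar(x)), integer(1))
  df$transcription_inedges <- vapply(strsplit(trn, ","), function(x)
    sum(nzchar(x)), integer(1))
  writeTsv(df, path)
  invisible(path)
}

#' Load a supplementary-style per-node inedge table
#'
#' Accepts either dialect of a per-node inedge spreadsheet exported to TSV:
#' with regulator identity columns (\code{splicing_regulators},
#' \code{transcription_regulators}, comma-joined) the full network is
#' rebuilt and every downstream stage is possible; with counts only
#' (\code{splicing_inedges}, \code{transcription_inedges}) the density and
#' correlation stages remain possible while clustering and pair scans are
#' not. Capability flags mark which stages the loaded object supports.
#'
#' @param path TSV path.
#' @return list with \code{kind} ("network" or "counts"), \code{network}
#'   (a \linkS4class{RegulatoryNetwork}, or NULL), \code{counts} (per-node
#'   count data.frame), and \code{capabilities} (named logical:
#'   density, correlation, clustering, pairs).
#' @export
loadSupplementaryNetwork <- function(path) {
  df <- readTsv(path, colClasses = "character")
  need <- c("gene_id", "group")
  if (!all(need %in% names(df)))
    stop("malformed supplementary table: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  badGroup <- which(!df$group %in% GROUPS)
  if (length(badGroup))
    stop("malformed rows (bad group): ",
         paste(utils::head(badGroup, 10), collapse = ", "))
  hasIdent <- all(c("splicing_regulators", "transcription_regulators") %in%
                  names(df))
  hasCounts <- all(c("splicing_inedges", "transcription_inedges") %in%
                   names(df))
  if (!hasIdent && !hasCounts)
    stop("supplementary table carries neither regulator identities nor counts")
  parseList <- function(x) {
    lapply(strsplit(x, ","), function(v) v[nzchar(trimws(v))])
  }
  network <- NULL
  if (hasIdent) {
    spl <- parseList(df$splicing_regulators)
    trn <- parseList(df$transcription_regulators)
    regs <- unique(c(unlist(spl), unlist(trn)))
    unknown <- setdiff(regs, df$gene_id)
    if (length(unknown))
      stop("identity lists reference genes absent from the table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    edges <- rbind(
      data.frame(source = unlist(spl),
                 target = rep(df$gene_id, lengths(spl)),
                 edge_type = if (length(unlist(spl))) "splicing"
                   else character(0)),
      data.frame(source = unlist(trn),
                 target = rep(df$gene_id, lengths(trn)),
                 edge_type = if (length(unlist(trn))) "transcription"
                   else character(0)))
    network <- makeNetwork(
      data.frame(gene_id = df$gene_id, group = df$group), edges)
    counts <- data.frame(
      gene_id = df$gene_id, group = df$group,
      splicing_inedges = lengths(spl),
      transcription_inedges = lengths(trn))
  } else {
    splN <- suppressWarnings(as.integer(df$splicing_inedges))
    trnN <- suppressWarnings(as.integer(df$transcription_inedges))
    bad <- which(is.na(splN) | is.na(trnN))
    if (length(bad))
      stop("malformed rows (non-integer counts): ",
           paste(utils::head(bad, 10), collapse = ", "))
    counts <- data.frame(gene_id = df$gene_id, group = df$group,
                         splicing_inedges = splN,
                         transcription_inedges = trnN)
  }
  list(kind = if (hasIdent) "network" else "counts",
       network = network, counts = counts,
       capabilities = c(density = TRUE, correlation = TRUE,
                        clustering = hasIdent, pairs = hasIdent))
}

#' Group densities and correlations from a counts-only per-node table
#'
#' The recomputation entry point when only inedge counts (not regulator
#' identities) are available: per-group mean +/- sem of each edge type,
#' Mann-Whitney group comparisons, and per-group Spearman correlations
#' between splicing and transcription counts.
#'
#' @param counts data.frame with gene_id, group, splicing_inedges,
#'   transcription_inedges.
#' @return list with \code{density}, \code{tests} and \code{correlations}
#'   data.frames.
#' @export
countsDensityStats <- function(counts) {
  density <- do.call(rbind, lapply(c("splicing", "transcription"),
    function(ty) {
      col <- paste0(ty, "_inedges")
      do.call(rbind, lapply(GROUPS, function(g) {
        x <- counts[[col]][counts$group == g]
        data.frame(group = g, edge_type = ty, n = length(x),
                   mean = if (length(x)) mean(x) else NA_real_,
                   sem = semOf(x))
      }))
    }))
  comparisons <- list(c("SF", "TF"), c("SF", "KINASE"), c("TF", "KINASE"))
  tests <- do.call(rbind, lapply(c("splicing", "transcription"),
    function(ty) {
      col <- paste0(ty, "_inedges")
      do.call(rbind, lapply(comparisons, function(cmp) {
        a <- counts[[col]][counts$group == cmp[1]]
        b <- counts[[col]][counts$group == cmp[2]]
        if (!length(a) || !length(b)) return(NULL)
        mw <- mannWhitney(a, b, sides = "two")
        data.frame(edge_type = ty, group_a = cmp[1], group_b = cmp[2],
                   U = mw$U, p = mw$p, log10_p = log10(mw$p),
                   method = mw$method)
      }))
    }))
  correlations <- do.call(rbind, lapply(GROUPS, function(g) {
    d <- counts[counts$group == g, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    rho <- if (stats::sd(d$splicing_inedges) == 0 ||
               stats::sd(d$transcription_inedges) == 0) NA_real_
      else stats::cor(d$splicing_inedges, d$transcription_inedges,
                      method = "spearman")
    data.frame(group = g, rho = rho, n = nrow(d))
  }))
  rownames(density) <- rownames(tests) <- rownames(correlations) <- NULL
  list(density = density, tests = tests, correlations = correlations)
}
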