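#' Run the integrated analysis end to end on generated inputs
#'
#' Orchestrates the full pipeline: generate the synthetic bundle, wire the
#' network for the chosen AS-event dataset, compute global properties
#' against a null ensemble, per-group inedge densities with Mann-Whitney
#' comparisons, splicing-vs-transcription Spearman correlations, the
#' randomized-group control, the combinatorial pair scan with coverage,
#' tissue-specific subnetworks, motif enrichment on the labelled sequence
#' sets, and the phosphorylation / disorder summaries. All randomness fans
#' out from \code{config$seed} through per-stage child seeds, so two runs
#' with the same configuration produce identical reports. P-values are
#' reported in log10 alongside linear values.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param dataset AS-event dataset to wire ("A" or "B").
#' @param nRandom null-ensemble size for the clustering z-score.
#' @param nullModel "degree_swap" (default) or "density_matched".
#' @param alpha pair-scan significance cutoff (default 1e-16).
#' @param nControlIter iterations of the randomized-group control.
#' @param tissues tissue names for subnetworks; default: all atlas tissues
#'   named in \code{config$plantAbove}, else the first two.
#' @param outDir if non-NULL, per-stage TSVs and the JSON report are
#'   written there.
#' @return a nested report list (also written as JSON when \code{outDir} is
#'   given); stages that were skipped are noted under \code{$skipped}.
#' @export
runPipeline <- function(config, dataset = "A", nRandom = 200,
                        nullModel = "degree_swap", alpha = 1e-16,
                        nControlIter = 100, tissues = NULL, outDir = NULL) {
  stageSeeds <- childSeeds(config$seed + 101, 4L)
  bundle <- generateBundle(config)
  network <- buildNetwork(bundle, dataset = dataset)
  skipped <- character(0)

  ens <- nullZscore(network, stat = "clustering", nullModel = nullModel,
                    nRandom = nRandom, seed = stageSeeds[1])
  props <- list(
    n_nodes = nrow(networkNodes(network)),
    n_edges = nrow(networkEdges(network)),
    layers = as.list(table(networkNodes(network)$layer)),
    clustering = ens@observed,
    clustering_null = list(model = nullModel, n_random = nRandom,
                           mean = ens@nullMean, sd = ens@nullSd, z = ens@z,
                           empirical_p = ens@empiricalP,
                           log10_empirical_p = log10(ens@empiricalP)),
    sparseness = list(
      typed_bipartite = sparseness(network, "typed_bipartite"),
      simple_n2 = sparseness(network, "simple_n2"),
      paper_literal = sparseness(network, "paper_literal")))

  dens <- rbind(inedgeDensity(network, "splicing"),
                inedgeDensity(network, "transcription"))
  counts <- data.frame(
    gene_id = networkNodes(network)$gene_id,
    group = networkNodes(network)$group,
    splicing_inedges = as.integer(inedgeCounts(network, "splicing")),
    transcription_inedges = as.integer(
      inedgeCounts(network, "transcription")))
  stats <- countsDensityStats(counts)

  control <- randomGroupControl(network, nIter = nControlIter,
                                seed = stageSeeds[2])

  pairs <- pairCoregulationScan(network, alpha = alpha)
  coverage <- pairCoverage(pairs, network)
  sigCounts <- table(factor(pairs$pair_class[pairs$significant],
                            levels = c("SF-SF", "TF-TF", "SF-TF")))

  tissueOut <- NULL
  if (!is.null(bundle@atlas)) {
    if (is.null(tissues)) {
      pinned <- intersect(names(config$plantAbove),
                          tissueNames(bundle@atlas))
      tissues <- if (length(pinned)) pinned
        else utils::head(tissueNames(bundle@atlas), 2)
    }
    tissueOut <- lapply(stats::setNames(tissues, tissues), function(t) {
      sub <- tissueSubnetwork(bundle@atlas, network, t)
      keptGroups <- networkNodes(network)$group[
        networkNodes(network)$gene_id %in% sub$kept]
      list(n_kept = length(sub$kept),
           kept_by_group = as.list(table(factor(keptGroups,
                                                levels = GROUPS))),
           density = sub$density)
    })
  } else {
    skipped <- c(skipped, "tissue: no expression atlas generated")
  }

  enrich <- NULL
  if (!is.null(bundle@sequences)) {
    sq <- bundle@sequences
    fe <- fisherEnrichment(sq$bound, sq$control, sq$motif,
                           sides = "greater")
    enrich <- list(motif = sq$motif,
                   bound_hit_fraction = hitFraction(sq$bound, sq$motif),
                   control_hit_fraction = hitFraction(sq$control, sq$motif),
                   fisher_p = fe$p,
                   log10_fisher_p = log10(fe$p),
                   odds_ratio = fe$odds_ratio)
  } else skipped <- c(skipped, "enrichment: no sequence sets generated")

  annot <- NULL
  if (!is.null(bundle@annotations)) {
    phos <- phosphoSummary(bundle@annotations)
    dis <- disorderSummary(bundle@annotations, seed = stageSeeds[3])
    pp <- dis$perProtein
    mwDis <- function(g1, g2) {
      mw <- mannWhitney(pp$frac_disordered[pp$group == g1],
                        pp$frac_disordered[pp$group == g2])
      list(p = mw$p, log10_p = log10(mw$p))
    }
    annot <- list(phospho = phos, disorder_groups = dis$groups,
                  disorder_random = dis$random[
                    c("mean_frac_disordered", "frac_long_disordered")],
                  disorder_mw = list(SF_vs_KINASE = mwDis("SF", "KINASE"),
                                     TF_vs_KINASE = mwDis("TF", "KINASE")))
  } else skipped <- c(skipped, "annotation: no protein annotations generated")

  report <- list(
    config = list(seed = config$seed, dataset = dataset,
                  n_sf = config$nSF, n_tf = config$nTF,
                  n_kinase = config$nKinase,
                  window_nt = config$windowNt,
                  promoter_nt = config$promoterNt,
                  null_model = nullModel, n_random = nRandom,
                  alpha = alpha, n_control_iter = nControlIter),
    network = props,
    density = stats$density,
    density_tests = stats$tests,
    correlations = stats$correlations,
    random_group_control = control$aggregate,
    pairs = list(n_significant = as.list(sigCounts),
                 coverage = coverage),
    tissues = tissueOut,
    enrichment = enrich,
    annotation = annot,
    skipped = skipped)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeEdgeList(network, file.path(outDir, "edges.tsv"),
                  file.path(outDir, "nodes.tsv"))
    writeTsv(dens[, c("group", "edge_type", "n", "mean", "sem")],
             file.path(outDir, "density.tsv"))
    writeTsv(pairs, file.path(outDir, "pairs.tsv"))
    writeSupplementaryTable(network,
                            file.path(outDir, "inedge_table.tsv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}
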