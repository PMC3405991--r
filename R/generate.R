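#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the synthetic input generator. Defaults
#' reproduce the composition and calibration of the integrated network the
#' package analyzes: 20 splicing factors, 90 transcription factors and 147
#' kinases; planting probabilities chosen so that expected per-group inedge
#' densities match the reported group means (splicing inedges per SF about
#' 4.0, transcription inedges per TF about 8.3, and so on); kinase genes
#' longer with more exons; SFs with the most AS events per gene.
#'
#' @param seed integer master seed.
#' @param nSF,nTF,nKinase group sizes (defaults 20, 90, 147).
#' @param geneLengthMeanlog,geneLengthSdlog log-normal gene-length
#'   parameters, named per group.
#' @param exonCountMu,exonCountSize shifted negative-binomial exon-count
#'   parameters per group; counts are \code{minExons + NB(mu - minExons,
#'   size)}.
#' @param minExons minimum exons per gene (>= 4 so internal exons exist).
#' @param asRate 2 x 3 matrix of Poisson AS-event rates, rows datasets
#'   ("A", "B"), columns groups.
#' @param eventTypeProbs sampling weights for cassette / alt3 / alt5.
#' @param plantProb 2 x 3 matrix of edge-planting probabilities,
#'   rows \code{c("splicing", "transcription")}, columns groups: the chance
#'   that a given regulator plants a conserved motif hit in the eligible
#'   region of a given target.
#' @param promoterNt,windowNt promoter span and intron window (5000, 100).
#' @param motifHitLength length of a planted motif hit in nt.
#' @param decoyRate probability of an additional non-conserved decoy hit per
#'   (regulator, target) pair; decoys are ignored when wiring requires
#'   conservation.
#' @param nTissues,tissueNames expression-atlas tissues; the first two
#'   default to "heart" and "smooth_muscle".
#' @param nBackgroundGenes non-network genes defining the per-tissue mean.
#' @param plantAbove named list, tissue -> named counts per group, of
#'   exactly how many genes to plant above the tissue mean (default: 14 SFs
#'   and 33 TFs in heart; 11 SFs and 40 TFs in smooth muscle).
#' @param plantAboveFrac planting fraction for tissue/group combinations not
#'   pinned by \code{plantAbove}.
#' @param proteinLengthMeanlog,proteinLengthSdlog log-normal protein length
#'   parameters per group (kinases longest).
#' @param phosphoProteinFrac per-group probability a protein carries at
#'   least one predicted phosphorylation site (defaults 0.49 SF, 0.42 TF,
#'   0.77 kinase).
#' @param phosphoHighCovFrac among proteins with sites, probability the
#'   sites cover more than 10 percent of the length (default 0.88 for SFs).
#' @param disorderProb stationary per-residue probability of the disordered
#'   state, per group plus a RANDOM proteome pool.
#' @param disorderRunMean mean length of a disordered run, per group.
#' @param nRandomProteins size of the random proteome pool used for the
#'   disorder baseline (drawn 10 x 250 downstream).
#' @param motif planted sequence motif (ACGT string).
#' @param qBound,qControl motif-planting probabilities for bound and control
#'   sequence sets (defaults 0.75 and 0.05).
#' @param nBound,nControl sequence-set sizes (defaults 200 and 1000 control
#'   sequences).
#' @param seqLength sequence length in nt (41).
#' @return a validated list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(
    seed = 1L,
    nSF = 20L, nTF = 90L, nKinase = 147L,
    geneLengthMeanlog = c(SF = log(25000), TF = log(28000),
                          KINASE = log(60000)),
    geneLengthSdlog = c(SF = 0.5, TF = 0.5, KINASE = 0.5),
    exonCountMu = c(SF = 12, TF = 10, KINASE = 18),
    exonCountSize = c(SF = 8, TF = 8, KINASE = 8),
    minExons = 4L,
    asRate = rbind(A = c(SF = 3.0, TF = 1.0, KINASE = 1.2),
                   B = c(SF = 4.0, TF = 1.5, KINASE = 1.6)),
    eventTypeProbs = c(cassette = 0.6, alt3 = 0.2, alt5 = 0.2),
    plantProb = rbind(
      splicing = c(SF = 0.20, TF = 0.0475, KINASE = 0.05),
      transcription = c(SF = 0.0589, TF = 0.0922, KINASE = 0.0367)),
    promoterNt = 5000L, windowNt = 100L,
    motifHitLength = 7L, decoyRate = 0.05,
    nTissues = 8L, tissueNames = NULL,
    nBackgroundGenes = 2000L,
    plantAbove = list(heart = c(SF = 14, TF = 33),
                      smooth_muscle = c(SF = 11, TF = 40)),
    plantAboveFrac = 0.4,
    proteinLengthMeanlog = c(SF = log(450), TF = log(500), KINASE = log(650),
                             RANDOM = log(450)),
    proteinLengthSdlog = 0.35,
    phosphoProteinFrac = c(SF = 0.49, TF = 0.42, KINASE = 0.77),
    phosphoHighCovFrac = c(SF = 0.88, TF = 0.40, KINASE = 0.60),
    disorderProb = c(SF = 0.50, TF = 0.55, KINASE = 0.20, RANDOM = 0.30),
    disorderRunMean = c(SF = 45, TF = 45, KINASE = 12, RANDOM = 25),
    nRandomProteins = 1500L,
    motif = "CTCTCT",
    qBound = 0.75, qControl = 0.05,
    nBound = 200L, nControl = 1000L,
    seqLength = 41L) {
  cfg <- as.list(environment())
  if (is.null(cfg$tissueNames)) {
    base <- c("heart", "smooth_muscle", "liver", "brain", "kidney", "lung",
              "testis", "thymus", "spleen", "pancreas")
    cfg$tissueNames <- if (nTissues <= length(base)) base[seq_len(nTissues)]
      else c(base, sprintf("tissue%02d", seq_len(nTissues - length(base))))
  }
  validateGeneratorConfig(cfg)
  class(cfg) <- c("GeneratorConfig", "list")
  cfg
}

validateGeneratorConfig <- function(cfg) {
  counts <- c(cfg$nSF, cfg$nTF, cfg$nKinase, cfg$nBackgroundGenes,
              cfg$nTissues, cfg$nBound, cfg$nControl, cfg$nRandomProteins)
  if (any(counts < 0)) stop("all counts must be >= 0")
  probs <- c(cfg$plantProb, cfg$decoyRate, cfg$plantAboveFrac,
             cfg$phosphoProteinFrac, cfg$phosphoHighCovFrac,
             cfg$disorderProb, cfg$qBound, cfg$qControl)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (any(cfg$asRate < 0)) stop("AS-event rates must be >= 0")
  if (!identical(rownames(cfg$plantProb), c("splicing", "transcription")) ||
      !identical(colnames(cfg$plantProb), GROUPS))
    stop("plantProb must have rows splicing/transcription and columns SF/TF/KINASE")
  if (!identical(colnames(cfg$asRate), GROUPS) ||
      !identical(rownames(cfg$asRate), c("A", "B")))
    stop("asRate must have rows A/B and columns SF/TF/KINASE")
  if (cfg$minExons < 4) stop("minExons must be >= 4")
  if (nchar(cfg$motif) > cfg$seqLength)
    stop("motif longer than the sequence length")
  if (grepl("[^ACGT]", cfg$motif))
    stop("generator motif must be an ACGT string")
  invisible(TRUE)
}

groupSizes <- function(cfg) {
  c(SF = cfg$nSF, TF = cfg$nTF, KINASE = cfg$nKinase)
}

#' Generate gene models with group-specific feature distributions
#'
#' Samples one gene per node: log-normal gene length, shifted
#' negative-binomial exon count and per-dataset Poisson AS-event counts, all
#' with group-specific parameters, so that under the defaults kinase genes
#' are stochastically longer with more exons while SFs carry the most AS
#' events per gene. Each gene is laid out on its own chromosome with
#' non-overlapping ordered exons and introns of at least 300 nt (so search
#' windows of distinct events never touch), the TSS at least
#' \code{promoterNt + 1000} bases into the chromosome, and a random strand.
#' AS events are assigned to distinct internal exons; counts exceeding the
#' number of internal exons are truncated.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return a \linkS4class{GeneModels}.
#' @export
generateGeneModels <- function(config, seed = config$seed) {
  sizes <- groupSizes(config)
  for (grp in GROUPS) {
    if (sizes[[grp]] <= 0 && any(config$asRate[, grp] > 0))
      stop("group ", grp, " has non-positive size but positive AS rate")
  }
  withSeed(seed, {
    geneRows <- list(); exonRows <- list(); eventRows <- list()
    for (grp in GROUPS) {
      n <- sizes[[grp]]
      if (n <= 0) next
      for (i in seq_len(n)) {
        gid <- sprintf("%s%03d", grp, i)
        gene <- sampleGene(config, gid, grp)
        geneRows[[gid]] <- gene$gene
        exonRows[[gid]] <- gene$exons
        if (!is.null(gene$events)) eventRows[[gid]] <- gene$events
      }
    }
    bindCols <- function(rows, cols) {
      out <- lapply(cols, function(cl)
        do.call(c, lapply(rows, `[[`, cl)))
      names(out) <- cols
      as.data.frame(out, stringsAsFactors = FALSE)
    }
    genes <- bindCols(geneRows, c("gene_id", "group", "chrom", "strand",
                                  "tss", "start", "end", "n_exons",
                                  "gene_length"))
    exons <- bindCols(exonRows, c("gene_id", "rank", "start", "end"))
    events <- if (length(eventRows))
      bindCols(eventRows, names(emptyEventTable())) else emptyEventTable()
    rownames(genes) <- rownames(exons) <- rownames(events) <- NULL
    new("GeneModels", genes = genes, exons = exons, events = events)
  })
}

emptyEventTable <- function() {
  data.frame(event_id = character(0), gene_id = character(0),
             dataset = character(0), event_type = character(0),
             chrom = character(0), strand = character(0),
             exon_start = integer(0), exon_end = integer(0),
             up_start = integer(0), up_end = integer(0),
             down_start = integer(0), down_end = integer(0))
}

# draw one gene: structure first (exon/intron lengths), then AS events on
# distinct internal exons so event search regions are pairwise disjoint
sampleGene <- function(cfg, gid, grp) {
  minIntron <- 300L
  L <- round(stats::rlnorm(1, cfg$geneLengthMeanlog[[grp]],
                           cfg$geneLengthSdlog[[grp]]))
  nex <- cfg$minExons +
    stats::rnbinom(1, size = cfg$exonCountSize[[grp]],
                   mu = max(0.1, cfg$exonCountMu[[grp]] - cfg$minExons))
  exLen <- pmax(50L, round(stats::rlnorm(nex, log(150), 0.35)))
  nint <- nex - 1L
  spare <- max(0, L - sum(exLen) - nint * minIntron)
  w <- stats::rgamma(nint, shape = 1)
  intLen <- minIntron + floor(spare * w / sum(w))

  start <- cfg$promoterNt + 1001L
  strand <- sample(c("+", "-"), 1)
  exStart <- integer(nex); exEnd <- integer(nex)
  pos <- start
  for (k in seq_len(nex)) {
    exStart[k] <- pos
    exEnd[k] <- pos + exLen[k] - 1L
    pos <- exEnd[k] + 1L + if (k < nex) intLen[k] else 0L
  }
  end <- exEnd[nex]
  tss <- if (strand == "+") start else end
  chrom <- paste0("chr_", gid)
  gene <- list(gene_id = gid, group = grp, chrom = chrom,
               strand = strand, tss = tss, start = start, end = end,
               n_exons = nex, gene_length = end - start + 1L)
  rank <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
  exons <- list(gene_id = rep(gid, nex), rank = rank,
                start = exStart, end = exEnd)

  # AS events: Poisson per dataset, capped at the internal exon budget
  nEv <- stats::setNames(
    stats::rpois(2, cfg$asRate[, grp]), rownames(cfg$asRate))
  internal <- seq_len(nex)[-c(1L, nex)]
  if (sum(nEv) > length(internal)) {
    keep <- sample(rep(names(nEv), nEv), length(internal))
    nEv <- stats::setNames(
      as.integer(table(factor(keep, levels = names(nEv)))), names(nEv))
  }
  evExon <- sample(internal, sum(nEv))
  events <- NULL
  if (sum(nEv) > 0) {
    ds <- rep(names(nEv), nEv)
    type <- sample(names(cfg$eventTypeProbs), sum(nEv), replace = TRUE,
                   prob = cfg$eventTypeProbs)
    k <- evExon
    leftS <- exEnd[k - 1L] + 1L; leftE <- exStart[k] - 1L
    rightS <- exEnd[k] + 1L; rightE <- exStart[k + 1L] - 1L
    if (strand == "+") {
      upS <- leftS; upE <- leftE; downS <- rightS; downE <- rightE
    } else {
      upS <- rightS; upE <- rightE; downS <- leftS; downE <- leftE
    }
    upS[type == "alt5"] <- NA_integer_; upE[type == "alt5"] <- NA_integer_
    downS[type == "alt3"] <- NA_integer_
    downE[type == "alt3"] <- NA_integer_
    nE <- length(k)
    events <- list(event_id = sprintf("%s_ev%02d", gid, seq_len(nE)),
                   gene_id = rep(gid, nE), dataset = ds, event_type = type,
                   chrom = rep(chrom, nE), strand = rep(strand, nE),
                   exon_start = exStart[k], exon_end = exEnd[k],
                   up_start = as.integer(upS), up_end = as.integer(upE),
                   down_start = as.integer(downS),
                   down_end = as.integer(downE))
  }
  list(gene = gene, exons = exons, events = events)
}

#' Plant motif hits that encode a known edge set
#'
#' For each ordered (regulator, target) pair, a conserved motif hit is placed
#' strictly inside the target's eligible region with probability
#' \code{plantProb[edge_type, group(target)]}, independently: SF hits go into
#' a search window of a randomly chosen AS event of the target (drawn
#' independently for datasets A and B; a target without events in a dataset
#' cannot receive a splicing hit there), TF hits go into the target's
#' promoter. Because the generator's gene layout keeps event search regions
#' pairwise disjoint and promoters upstream of all exons, the network builder
#' recovers exactly the planted edge set. Additional non-conserved decoy hits
#' are placed at rate \code{decoyRate}; they only matter when wiring is run
#' with \code{requireConserved = FALSE}.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param genes a \linkS4class{GeneModels} from \code{generateGeneModels}.
#' @param seed RNG seed; defaults to \code{config$seed + 1}.
#' @return list with elements \code{sfHits}, \code{tfHits} (data.frames:
#'   factor_id, chrom, start, end, conserved) and \code{plantedEdges}
#'   (source, target, edge_type, dataset; dataset "*" marks transcription
#'   edges, which are dataset-independent).
#' @export
generateMotifHits <- function(config, genes, seed = config$seed + 1) {
  g <- geneTable(genes)
  ev <- eventTable(genes)
  sfs <- g$gene_id[g$group == "SF"]
  tfs <- g$gene_id[g$group == "TF"]
  grpOf <- stats::setNames(g$group, g$gene_id)
  hitLen <- config$motifHitLength

  hitProto <- data.frame(factor_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         conserved = logical(0))
  edgeProto <- data.frame(source = character(0), target = character(0),
                          edge_type = character(0), dataset = character(0))

  withSeed(seed, {
    sfHits <- hitProto; tfHits <- hitProto; planted <- edgeProto

    # splicing hits: Bernoulli per (SF, target) pair, independently per
    # dataset; hit placed uniformly in a random search region of a random
    # event of the target, strictly inside the region
    for (ds in c("A", "B")) {
      evd <- ev[ev$dataset == ds, , drop = FALSE]
      if (!nrow(evd) || !length(sfs)) next
      regions <- regionTable(evd, config$windowNt)
      regions <- regions[regions$end - regions$start + 1L >= hitLen, ,
                         drop = FALSE]
      if (!nrow(regions)) next
      regByGene <- split(seq_len(nrow(regions)), regions$gene_id)
      targets <- names(regByGene)
      # pair matrix: rows SFs, columns targets
      pTgt <- config$plantProb["splicing", grpOf[targets]]
      draw <- matrix(stats::runif(length(sfs) * length(targets)),
                     nrow = length(sfs))
      isDecoy <- matrix(stats::runif(length(sfs) * length(targets)),
                        nrow = length(sfs)) < config$decoyRate
      placeHits <- function(pairIdx, conserved) {
        if (!length(pairIdx)) return(NULL)
        sfI <- ((pairIdx - 1L) %% length(sfs)) + 1L
        tgI <- ((pairIdx - 1L) %/% length(sfs)) + 1L
        # pick a random eligible region of a random event of the target:
        # uniform over the target's (event, region) rows, which weights
        # events by their eligible-region counts -- any within-window
        # placement is valid, exact recovery does not depend on the weights
        regIdx <- vapply(tgI, function(ti) {
          rows <- regByGene[[ti]]
          rows[sample.int(length(rows), 1L)]
        }, integer(1))
        w <- regions$end[regIdx] - regions$start[regIdx] + 2L - hitLen
        s <- regions$start[regIdx] +
          floor(stats::runif(length(regIdx)) * w)
        list(hits = data.frame(factor_id = sfs[sfI],
                               chrom = regions$chrom[regIdx],
                               start = as.integer(s),
                               end = as.integer(s + hitLen - 1L),
                               conserved = conserved),
             sf = sfs[sfI], tgt = targets[tgI])
      }
      pl <- placeHits(which(draw < rep(pTgt, each = length(sfs))), TRUE)
      dc <- placeHits(which(isDecoy), FALSE)
      if (!is.null(pl)) {
        sfHits <- rbind(sfHits, pl$hits)
        planted <- rbind(planted,
                         data.frame(source = pl$sf, target = pl$tgt,
                                    edge_type = "splicing", dataset = ds))
      }
      if (!is.null(dc)) sfHits <- rbind(sfHits, dc$hits)
    }

    # transcription hits: Bernoulli per (TF, target) pair, hit uniform in
    # the target's promoter, dataset-independent
    if (length(tfs)) {
      plus <- g$strand == "+"
      promS <- ifelse(plus, pmax(1, g$tss - config$promoterNt), g$tss + 1)
      promE <- ifelse(plus, g$tss - 1, g$tss + config$promoterNt)
      ok <- promE - promS + 1L >= hitLen
      pTgt <- config$plantProb["transcription", g$group]
      draw <- matrix(stats::runif(length(tfs) * nrow(g)),
                     nrow = length(tfs))
      isDecoy <- matrix(stats::runif(length(tfs) * nrow(g)),
                        nrow = length(tfs)) < config$decoyRate
      placeProm <- function(pairIdx, conserved) {
        if (!length(pairIdx)) return(NULL)
        tfI <- ((pairIdx - 1L) %% length(tfs)) + 1L
        tgI <- ((pairIdx - 1L) %/% length(tfs)) + 1L
        keep <- ok[tgI]
        tfI <- tfI[keep]; tgI <- tgI[keep]
        if (!length(tgI)) return(NULL)
        w <- promE[tgI] - promS[tgI] + 2L - hitLen
        s <- promS[tgI] + floor(stats::runif(length(tgI)) * w)
        list(hits = data.frame(factor_id = tfs[tfI],
                               chrom = g$chrom[tgI],
                               start = as.integer(s),
                               end = as.integer(s + hitLen - 1L),
                               conserved = conserved),
             tf = tfs[tfI], tgt = g$gene_id[tgI])
      }
      pl <- placeProm(which(draw < rep(pTgt, each = length(tfs))), TRUE)
      dc <- placeProm(which(isDecoy), FALSE)
      if (!is.null(pl)) {
        tfHits <- rbind(tfHits, pl$hits)
        planted <- rbind(planted,
                         data.frame(source = pl$tf, target = pl$tgt,
                                    edge_type = "transcription",
                                    dataset = "*"))
      }
      if (!is.null(dc)) tfHits <- rbind(tfHits, dc$hits)
    }

    rownames(sfHits) <- rownames(tfHits) <- NULL
    list(sfHits = sfHits, tfHits = tfHits,
         plantedEdges = unique(planted))
  })
}

#' Generate a gene-by-tissue expression atlas with planted above-mean genes
#'
#' Background genes (emulating the rest of the array) are drawn from a
#' length-independent log-normal model; network genes are then pinned at
#' known multiples of the final per-tissue mean so that exactly the planted
#' genes exceed it. The construction solves for the mean analytically:
#' writing B for the background column total, n for the number of atlas
#' genes and m_i for the network multipliers, the final tissue mean is
#' \code{B / (n - sum(m_i))} and each network value \code{m_i} times that,
#' so planted genes (multiplier in [1.5, 3]) are strictly above the mean and
#' unplanted genes (multiplier in [0.05, 0.8]) strictly below.
#'
#' @param config a \code{\link{generatorConfig}}; \code{plantAbove} pins
#'   exact per-group planted counts for named tissues, all other
#'   tissue/group pairs plant each gene with probability
#'   \code{plantAboveFrac}.
#' @param genes a \linkS4class{GeneModels}.
#' @param seed RNG seed; defaults to \code{config$seed + 2}.
#' @return list with \code{atlas} (an \linkS4class{ExpressionAtlas}) and
#'   \code{plantedAbove} (list, tissue -> character vector of planted gene
#'   ids).
#' @export
generateExpressionAtlas <- function(config, genes, seed = config$seed + 2) {
  g <- geneTable(genes)
  tissues <- config$tissueNames
  nBg <- config$nBackgroundGenes
  nNet <- nrow(g)
  n <- nBg + nNet
  withSeed(seed, {
    bg <- matrix(stats::rlnorm(nBg * length(tissues), log(100), 1),
                 nrow = nBg,
                 dimnames = list(sprintf("BG%05d", seq_len(nBg)), tissues))
    net <- matrix(0, nrow = nNet, ncol = length(tissues),
                  dimnames = list(g$gene_id, tissues))
    plantedAbove <- stats::setNames(vector("list", length(tissues)), tissues)
    for (t in tissues) {
      pinned <- config$plantAbove[[t]]
      planted <- character(0)
      for (grp in GROUPS) {
        ids <- g$gene_id[g$group == grp]
        if (!length(ids)) next
        if (!is.null(pinned) && grp %in% names(pinned)) {
          k <- pinned[[grp]]
          if (k > length(ids))
            stop("cannot plant ", k, " ", grp, " genes above the mean in ",
                 t, ": only ", length(ids), " exist")
          planted <- c(planted, sample(ids, k))
        } else {
          planted <- c(planted,
                       ids[stats::runif(length(ids)) < config$plantAboveFrac])
        }
      }
      mult <- ifelse(g$gene_id %in% planted,
                     stats::runif(nNet, 1.5, 3),
                     stats::runif(nNet, 0.05, 0.8))
      B <- sum(bg[, t])
      denom <- n - sum(mult)
      if (denom <= 0)
        stop("atlas degenerate: background too small for the network size")
      m <- B / denom
      net[, t] <- mult * m
      plantedAbove[[t]] <- planted
    }
    atlas <- new("ExpressionAtlas", values = rbind(net, bg),
                 networkGenes = g$gene_id)
    list(atlas = atlas, plantedAbove = plantedAbove)
  })
}

#' Generate residue-level protein annotations
#'
#' Emulates the two predictor outputs the downstream summaries consume:
#' phosphorylation-site calls and per-residue disorder scores. Each protein
#' gets a log-normal length; with group-specific probability it carries
#' phosphorylation sites, and among site-carrying proteins a group-specific
#' fraction gets high-coverage site sets (more than 10 percent of residues).
#' Disorder scores follow a two-state Markov chain (disordered state emits
#' scores in [0.75, 1], ordered in [0, 0.749]) whose stationary probability
#' and mean run length are group-specific, so SFs/TFs are more disordered
#' with longer runs than kinases. A pool of \code{nRandomProteins} proteins
#' with group label RANDOM emulates the random proteome baseline.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param genes a \linkS4class{GeneModels}.
#' @param seed RNG seed; defaults to \code{config$seed + 3}.
#' @return data.frame with columns \code{protein_id}, \code{group},
#'   \code{length} and list-columns \code{phospho} (integer site positions)
#'   and \code{disorder} (numeric per-residue scores).
#' @export
generateProteinAnnotations <- function(config, genes,
                                       seed = config$seed + 3) {
  g <- geneTable(genes)
  ids <- c(g$gene_id, sprintf("RP%04d", seq_len(config$nRandomProteins)))
  grps <- c(g$group, rep("RANDOM", config$nRandomProteins))
  withSeed(seed, {
    lens <- pmax(60L, round(stats::rlnorm(
      length(ids), config$proteinLengthMeanlog[grps],
      config$proteinLengthSdlog)))
    phospho <- vector("list", length(ids))
    disorder <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      grp <- grps[i]; plen <- lens[i]
      nSites <- 0L
      if (grp %in% names(config$phosphoProteinFrac) &&
          stats::runif(1) < config$phosphoProteinFrac[[grp]]) {
        if (stats::runif(1) < config$phosphoHighCovFrac[[grp]]) {
          nSites <- min(plen, ceiling(plen * stats::runif(1, 0.105, 0.20)))
        } else {
          nSites <- max(1L, min(floor(0.10 * plen),
                                round(plen * stats::runif(1, 0.005, 0.09))))
        }
      }
      phospho[[i]] <- if (nSites > 0) sort(sample.int(plen, nSites))
        else integer(0)
      disorder[[i]] <- simulateDisorderScores(
        plen, config$disorderProb[[grp]], config$disorderRunMean[[grp]])
    }
    out <- data.frame(protein_id = ids, group = grps, length = lens)
    out$phospho <- phospho
    out$disorder <- disorder
    out
  })
}

# two-state Markov chain over residues; disordered state emits >= 0.75
simulateDisorderScores <- function(plen, piD, runMean) {
  pDO <- 1 / max(runMean, 1.0001)
  pOD <- if (piD >= 1) 1 else piD * pDO / (1 - piD)
  pOD <- min(pOD, 1)
  state <- logical(plen)
  state[1] <- stats::runif(1) < piD
  if (plen > 1) {
    u <- stats::runif(plen - 1)
    for (r in 2:plen) {
      state[r] <- if (state[r - 1]) u[r - 1] >= pDO else u[r - 1] < pOD
    }
  }
  ifelse(state, stats::runif(plen, 0.75, 1), stats::runif(plen, 0, 0.749))
}

#' Generate labelled 41-nt sequence sets for enrichment validation
#'
#' Produces a "bound" set (emulating experimentally selected CLIP/PAR-CLIP
#' sequences) and a "control" set (emulating random mid-intron sequences),
#' all of uniform length. The motif is planted at a random position with
#' probability \code{qBound} in bound and \code{qControl} in control
#' sequences; sequences not selected for planting are rejection-sampled to
#' be motif-free, so the per-sequence hit indicator equals the planting
#' indicator exactly and expected hit fractions are exactly the planting
#' probabilities.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed RNG seed; defaults to \code{config$seed + 4}.
#' @return list with \code{bound}, \code{control}
#'   (\link[Biostrings]{DNAStringSet}), \code{motif},
#'   \code{plantedBound}, \code{plantedControl} (logical vectors).
#' @export
generateSequenceSets <- function(config, seed = config$seed + 4) {
  motif <- config$motif
  L <- config$seqLength
  if (nchar(motif) > L) stop("motif longer than the sequence length")
  withSeed(seed, {
    randomSeq <- function() paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = "")
    makeSet <- function(nSeq, q) {
      plant <- stats::runif(nSeq) < q
      seqs <- character(nSeq)
      for (i in seq_len(nSeq)) {
        if (plant[i]) {
          s <- randomSeq()
          pos <- sample.int(L - nchar(motif) + 1L, 1)
          substr(s, pos, pos + nchar(motif) - 1L) <- motif
          seqs[i] <- s
        } else {
          repeat {
            s <- randomSeq()
            if (!grepl(motif, s, fixed = TRUE)) break
          }
          seqs[i] <- s
        }
      }
      list(seqs = Biostrings::DNAStringSet(seqs), plant = plant)
    }
    bound <- makeSet(config$nBound, config$qBound)
    control <- makeSet(config$nControl, config$qControl)
    list(bound = bound$seqs, control = control$seqs, motif = motif,
         plantedBound = bound$plant, plantedControl = control$plant)
  })
}

#' Generate the complete synthetic input bundle
#'
#' Runs every generator stage under child seeds fanned out from
#' \code{config$seed} and assembles a \linkS4class{SyntheticBundle}. The
#' ground-truth record includes the planted edge table, the planting
#' probabilities, the per-(dataset, group) fraction of genes carrying at
#' least one AS event, and the resulting analytic expected inedge means
#' (\code{plantProb * n_regulators * fracWithEvent} for splicing,
#' \code{plantProb * n_TF} for transcription).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param atlas,annotations,sequences logical switches to skip the optional
#'   stages.
#' @return a \linkS4class{SyntheticBundle}.
#' @export
generateBundle <- function(config, atlas = TRUE, annotations = TRUE,
                           sequences = TRUE) {
  seeds <- childSeeds(config$seed, 5L)
  genes <- generateGeneModels(config, seed = seeds[1])
  hits <- generateMotifHits(config, genes, seed = seeds[2])
  atl <- NULL; plantedAbove <- NULL
  if (atlas && config$nTissues > 0) {
    a <- generateExpressionAtlas(config, genes, seed = seeds[3])
    atl <- a$atlas; plantedAbove <- a$plantedAbove
  }
  ann <- if (annotations)
    generateProteinAnnotations(config, genes, seed = seeds[4]) else NULL
  seqs <- if (sequences) generateSequenceSets(config, seed = seeds[5])
    else NULL

  g <- geneTable(genes)
  ev <- eventTable(genes)
  fracWithEvent <- sapply(c(A = "A", B = "B"), function(ds) {
    sapply(GROUPS, function(grp) {
      ids <- g$gene_id[g$group == grp]
      if (!length(ids)) return(NA_real_)
      mean(ids %in% ev$gene_id[ev$dataset == ds])
    })
  })
  expected <- do.call(rbind, lapply(c("A", "B"), function(ds) {
    data.frame(dataset = ds, group = GROUPS,
               splicing = config$plantProb["splicing", ] * config$nSF *
                 fracWithEvent[, ds],
               transcription = config$plantProb["transcription", ] *
                 config$nTF)
  }))
  truth <- list(planted_edges = hits$plantedEdges,
                plant_prob = config$plantProb,
                frac_with_event = fracWithEvent,
                expected_inedge_means = expected,
                planted_above = plantedAbove)
  new("SyntheticBundle", config = unclass(config), genes = genes,
      sfHits = hits$sfHits, tfHits = hits$tfHits, atlas = atl,
      annotations = ann, sequences = seqs, truth = truth)
}

#' Planted ground-truth edges for one dataset
#'
#' Splicing edges planted for the given dataset plus the
#' dataset-independent transcription edges, as a (source, target, edge_type)
#' data.frame comparable with \code{networkEdges}.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dataset "A" or "B".
#' @return data.frame with columns source, target, edge_type.
#' @export
truthEdges <- function(bundle, dataset = "A") {
  te <- bundle@truth$planted_edges
  out <- te[te$dataset %in% c(dataset, "*"),
            c("source", "target", "edge_type")]
  rownames(out) <- NULL
  out[order(out$edge_type, out$source, out$target), ]
}
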