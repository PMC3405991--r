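test_that("configuration validation rejects bad counts and probabilities", {
  expect_error(generatorConfig(nSF = -1), "counts")
  expect_error(generatorConfig(qBound = 1.5), "probabilities")
  expect_error(generatorConfig(motif = paste(rep("A", 60), collapse = "")),
               "longer")
  expect_error(generatorConfig(motif = "ACGU"), "ACGT")
  expect_error(generatorConfig(minExons = 2), "minExons")
})

test_that("the same config and seed reproduce the bundle exactly", {
  cfg <- tinyConfig(seed = 42)
  b1 <- generateBundle(cfg)
  b2 <- generateBundle(cfg)
  expect_identical(geneTable(b1@genes), geneTable(b2@genes))
  expect_identical(eventTable(b1@genes), eventTable(b2@genes))
  expect_identical(b1@sfHits, b2@sfHits)
  expect_identical(b1@tfHits, b2@tfHits)
  expect_identical(atlasValues(b1@atlas), atlasValues(b2@atlas))
  expect_identical(b1@annotations$phospho, b2@annotations$phospho)
  expect_identical(as.character(b1@sequences$bound),
                   as.character(b2@sequences$bound))
  expect_identical(b1@truth$planted_edges, b2@truth$planted_edges)
})

test_that("gene models have ordered disjoint exons and strand-consistent TSS", {
  gm <- generateGeneModels(tinyConfig(seed = 2))
  g <- geneTable(gm)
  ex <- exonTable(gm)
  for (gid in g$gene_id) {
    d <- ex[ex$gene_id == gid, ]
    d <- d[order(d$start), ]
    expect_true(all(d$end >= d$start))
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    row <- g[g$gene_id == gid, ]
    expect_equal(row$tss,
                 if (row$strand == "+") min(d$start) else max(d$end))
  }
  # introns leave room for non-overlapping event windows
  gaps <- unlist(lapply(split(ex, ex$gene_id), function(d) {
    d <- d[order(d$start), ]
    d$start[-1] - d$end[-nrow(d)] - 1
  }))
  expect_true(all(gaps >= 300))
})

test_that("zero AS rate means zero events, and zero splicing edges downstream", {
  cfg <- tinyConfig(seed = 3,
                    asRate = rbind(A = c(SF = 0, TF = 0, KINASE = 0),
                                   B = c(SF = 0, TF = 0, KINASE = 0)))
  b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                      sequences = FALSE)
  expect_equal(nrow(eventTable(b@genes)), 0)
  net <- buildNetwork(b, "A")
  expect_equal(sum(networkEdges(net)$edge_type == "splicing"), 0)
})

test_that("configured group contrasts are realized across seeds", {
  # SFs dominate in AS events per gene; kinases in length and exon count
  wins <- sapply(1:25, function(i) {
    gm <- generateGeneModels(generatorConfig(seed = 20000 + i,
                                             nSF = 60, nTF = 60,
                                             nKinase = 60))
    g <- geneTable(gm)
    ev <- eventTable(gm)
    nEvents <- table(factor(ev$gene_id, levels = g$gene_id))
    byGroup <- split(as.integer(nEvents), g$group)
    lenByGroup <- split(g$gene_length, g$group)
    exByGroup <- split(g$n_exons, g$group)
    c(as = mean(byGroup$SF) > mean(byGroup$TF) &&
        mean(byGroup$SF) > mean(byGroup$KINASE),
      len = mean(lenByGroup$KINASE) > mean(lenByGroup$SF) &&
        mean(lenByGroup$KINASE) > mean(lenByGroup$TF),
      ex = mean(exByGroup$KINASE) > mean(exByGroup$SF) &&
        mean(exByGroup$KINASE) > mean(exByGroup$TF))
  })
  expect_gte(mean(wins["as", ]), 0.95)
  expect_gte(mean(wins["len", ]), 0.95)
  expect_gte(mean(wins["ex", ]), 0.95)
})

test_that("planted inedge means match the analytic binomial expectation", {
  # mean splicing inedges per group ~ p * nSF * fracWithEvent; averaged
  # over replicates the deviation shrinks within Monte-Carlo error
  nRep <- 30
  devs <- sapply(seq_len(nRep), function(s) {
    cfg <- generatorConfig(seed = 7000 + s, nSF = 10, nTF = 15,
                           nKinase = 12, decoyRate = 0)
    b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                        sequences = FALSE)
    net <- buildNetwork(b, "A")
    ex <- b@truth$expected_inedge_means
    d <- inedgeDensity(net, "splicing")
    d$mean - ex$splicing[ex$dataset == "A"]
  })
  se <- apply(devs, 1, sd) / sqrt(nRep)
  expect_true(all(abs(rowMeans(devs)) < 3 * se + 1e-9))
})

test_that("atlas planting pins exactly the requested genes above the mean", {
  cfg <- tinyConfig(seed = 9)
  gm <- generateGeneModels(cfg)
  a <- generateExpressionAtlas(cfg, gm)
  v <- atlasValues(a$atlas)
  for (t in colnames(v)) {
    m <- mean(v[, t])
    net <- a$atlas@networkGenes
    above <- net[v[net, t] > m]
    expect_setequal(above, a$plantedAbove[[t]])
  }
  # the pinned tissue plants exactly 2 SFs and 3 TFs
  grp <- setNames(geneTable(gm)$group, geneTable(gm)$gene_id)
  planted <- a$plantedAbove[["heart"]]
  expect_equal(sum(grp[planted] == "SF"), 2)
  expect_equal(sum(grp[planted] == "TF"), 3)
})

test_that("atlas extremes: everything planted or nothing planted", {
  gm <- generateGeneModels(tinyConfig(seed = 10))
  cfgAll <- tinyConfig(seed = 10, plantAbove = list(), plantAboveFrac = 1)
  aAll <- generateExpressionAtlas(cfgAll, gm)
  v <- atlasValues(aAll$atlas)
  net <- aAll$atlas@networkGenes
  expect_true(all(v[net, 1] > mean(v[, 1])))
  cfgNone <- tinyConfig(seed = 10, plantAbove = list(), plantAboveFrac = 0)
  aNone <- generateExpressionAtlas(cfgNone, gm)
  v <- atlasValues(aNone$atlas)
  expect_true(all(v[net, 1] < mean(v[, 1])))
})

test_that("protein annotations honor rate extremes and structure", {
  gm <- generateGeneModels(tinyConfig(seed = 11))
  cfg0 <- tinyConfig(seed = 11,
                     phosphoProteinFrac = c(SF = 0, TF = 0, KINASE = 0))
  ann0 <- generateProteinAnnotations(cfg0, gm)
  expect_true(all(lengths(ann0$phospho[ann0$group %in%
                                       c("SF", "TF", "KINASE")]) == 0))
  ann <- generateProteinAnnotations(tinyConfig(seed = 11), gm)
  expect_true(all(vapply(ann$disorder, length, integer(1)) == ann$length))
  expect_true(all(unlist(ann$disorder) >= 0 & unlist(ann$disorder) <= 1))
  expect_true(all(unlist(Map(function(p, l) all(p >= 1 & p <= l),
                             ann$phospho, ann$length))))
})

test_that("sequence sets realize exact planting and reject long motifs", {
  cfg <- tinyConfig(seed = 12, qBound = 1, qControl = 0, nBound = 20,
                    nControl = 20)
  s <- generateSequenceSets(cfg)
  expect_true(all(Biostrings::width(s$bound) == 41))
  expect_equal(hitFraction(s$bound, s$motif), 1)
  expect_equal(hitFraction(s$control, s$motif), 0)
  cfgBad <- tinyConfig(seed = 12)
  cfgBad$motif <- paste(rep("A", 60), collapse = "")
  expect_error(generateSequenceSets(cfgBad), "longer")
})

test_that("bound hit fraction concentrates at the planting probability", {
  cfg <- tinyConfig(seed = 13, nBound = 4000, qBound = 0.75)
  s <- generateSequenceSets(cfg)
  expect_lt(abs(hitFraction(s$bound, s$motif) - 0.75), 0.03)
})

test_that("non-positive group sizes with positive AS rates are an error", {
  cfg <- tinyConfig(seed = 14)
  cfg$nSF <- 0L
  expect_error(generateGeneModels(cfg), "non-positive size")
})
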