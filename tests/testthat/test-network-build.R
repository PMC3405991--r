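# hand-wired three-gene fixture: an SF regulator, a TF target carrying one
# cassette event (exon [6400,6500], introns of 299 nt either side), and a
# kinase without events; every gene on its own chromosome, plus strand,
# TSS 6001, promoter [1001, 6000]
handModels <- function() {
  mkGene <- function(id, group) {
    data.frame(gene_id = id, group = group, chrom = paste0("chr_", id),
               strand = "+", tss = 6001, start = 6001, end = 6900,
               n_exons = 3, gene_length = 900)
  }
  mkExons <- function(id) {
    data.frame(gene_id = id, rank = 1:3,
               start = c(6001, 6400, 6800), end = c(6100, 6500, 6900))
  }
  genes <- rbind(mkGene("s1", "SF"), mkGene("t1", "TF"),
                 mkGene("k1", "KINASE"))
  events <- data.frame(
    event_id = "t1_ev01", gene_id = "t1", dataset = "A",
    event_type = "cassette", chrom = "chr_t1", strand = "+",
    exon_start = 6400, exon_end = 6500,
    up_start = 6101, up_end = 6399, down_start = 6501, down_end = 6799)
  new("GeneModels", genes = genes,
      exons = rbind(mkExons("s1"), mkExons("t1"), mkExons("k1")),
      events = events)
}

hit <- function(factor, chrom, start, end, conserved = TRUE) {
  data.frame(factor_id = factor, chrom = chrom, start = start, end = end,
             conserved = conserved)
}

test_that("a splicing edge needs an AS event and an overlapping hit", {
  gm <- handModels()
  # hit inside the cassette exon of the target -> one edge
  ed <- buildSplicingEdges(gm, hit("s1", "chr_t1", 6450, 6456))
  expect_equal(nrow(ed), 1)
  expect_equal(ed$source, "s1")
  expect_equal(ed$target, "t1")
  # same interval on a gene without AS events -> no edge, hits or not
  expect_equal(nrow(buildSplicingEdges(gm, hit("s1", "chr_k1", 6450, 6456))),
               0)
  # 150 nt into the upstream intron with a 100 nt window -> outside
  expect_equal(nrow(buildSplicingEdges(gm, hit("s1", "chr_t1", 6245, 6251))),
               0)
  # just inside the upstream window ([6300, 6399]) -> edge
  expect_equal(nrow(buildSplicingEdges(gm, hit("s1", "chr_t1", 6295, 6301))),
               1)
})

test_that("conservation is required unless disabled", {
  gm <- handModels()
  h <- hit("s1", "chr_t1", 6450, 6456, conserved = FALSE)
  expect_equal(nrow(buildSplicingEdges(gm, h)), 0)
  expect_equal(nrow(buildSplicingEdges(gm, h, requireConserved = FALSE)), 1)
})

test_that("promoter edges respect the strictly-upstream boundary", {
  gm <- handModels()
  # overlapping the last promoter base (6000) -> edge
  expect_equal(nrow(buildTranscriptionEdges(gm, hit("t1", "chr_s1", 5998,
                                                    6004))), 1)
  # starting exactly at the TSS -> no edge
  expect_equal(nrow(buildTranscriptionEdges(gm, hit("t1", "chr_s1", 6001,
                                                    6007))), 0)
  # centered 4999 nt upstream of the TSS -> edge
  expect_equal(nrow(buildTranscriptionEdges(gm, hit("t1", "chr_s1", 999,
                                                    1005))), 1)
  # self-regulation through one's own promoter is a valid edge
  expect_equal(buildTranscriptionEdges(gm, hit("t1", "chr_t1", 3000,
                                               3006))$target, "t1")
})

test_that("hits referencing unknown factors are rejected by name", {
  gm <- handModels()
  expect_error(buildSplicingEdges(gm, hit("nosuch", "chr_t1", 6450, 6456)),
               "nosuch")
  expect_error(buildTranscriptionEdges(gm, hit("s1", "chr_t1", 3000, 3006)),
               "s1")
})

test_that("layers classify nodes by in/out edge presence", {
  gm <- handModels()
  sp <- buildSplicingEdges(gm, hit("s1", "chr_t1", 6450, 6456))
  tr <- buildTranscriptionEdges(gm, rbind(hit("t1", "chr_k1", 3000, 3006),
                                          hit("t1", "chr_s1", 3000, 3006)))
  net <- assembleNetwork(gm, sp, tr)
  lay <- setNames(networkNodes(net)$layer, networkNodes(net)$gene_id)
  expect_equal(lay[["s1"]], "mixed")    # regulates t1, regulated by t1
  expect_equal(lay[["t1"]], "mixed")
  expect_equal(lay[["k1"]], "sink")     # kinases never emit edges
  # empty edge sets -> everything isolated
  none <- assembleNetwork(gm, sp[0, ], tr[0, ])
  expect_true(all(networkNodes(none)$layer == "isolated"))
  expect_equal(nrow(networkEdges(none)), 0)
})

test_that("duplicate gene ids are rejected at assembly", {
  gm <- handModels()
  g2 <- rbind(geneTable(gm), geneTable(gm)[1, ])
  expect_error(assembleNetwork(g2, data.frame(), data.frame()), "duplicate")
})

test_that("edge wiring is independent of hit order and monotone in evidence", {
  cfg <- tinyConfig(seed = 11)
  b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                      sequences = FALSE)
  hits <- b@sfHits
  ed1 <- buildSplicingEdges(b@genes, hits)
  ed2 <- buildSplicingEdges(b@genes, hits[rev(seq_len(nrow(hits))), ])
  expectSameEdgeSet(ed1, ed2)
  # adding a hit never removes an edge
  extra <- rbind(hits, hit(hits$factor_id[1], hits$chrom[2],
                           hits$start[2], hits$end[2]))
  ed3 <- buildSplicingEdges(b@genes, extra)
  expect_true(all(edgeKeys(ed1) %in% edgeKeys(ed3)))
  # widening the window never removes an edge
  ed4 <- buildSplicingEdges(b@genes, hits, windowNt = 250)
  expect_true(all(edgeKeys(ed1) %in% edgeKeys(ed4)))
})

test_that("wiring equals a brute-force interval scan on small fixtures", {
  for (s in 1:4) {
    cfg <- tinyConfig(seed = 100 + s, decoyRate = 0.3)
    b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                        sequences = FALSE)
    # scatter extra random hits, conserved and not, across all chromosomes
    g <- geneTable(b@genes)
    set.seed(s)
    sfs <- g$gene_id[g$group == "SF"]
    idx <- sample.int(nrow(g), 40, replace = TRUE)
    starts <- g$start[idx] + floor(runif(40) * (g$gene_length[idx] + 2000)) -
      1000
    rough <- data.frame(factor_id = sample(sfs, 40, replace = TRUE),
                        chrom = g$chrom[idx],
                        start = starts, end = starts + 6,
                        conserved = runif(40) < 0.5)
    allHits <- rbind(b@sfHits, rough)
    for (rc in c(TRUE, FALSE)) {
      got <- buildSplicingEdges(b@genes, allHits, requireConserved = rc)
      expect_equal(edgeKeys(got),
                   oracleSplicingEdges(b@genes, allHits,
                                       requireConserved = rc))
    }
  }
})

test_that("the builder recovers exactly the planted edges, per dataset", {
  for (s in c(1, 2)) {
    b <- generateBundle(tinyConfig(seed = s), atlas = FALSE,
                        annotations = FALSE, sequences = FALSE)
    for (ds in c("A", "B")) {
      net <- buildNetwork(b, dataset = ds)
      expectSameEdgeSet(networkEdges(net), truthEdges(b, ds))
    }
  }
})

test_that("saturated planting wires every regulator to every eligible target", {
  # AS rate high enough that every gene carries at least one event in A
  cfg <- tinyConfig(seed = 5,
                    asRate = rbind(A = c(SF = 30, TF = 30, KINASE = 30),
                                   B = c(SF = 0, TF = 0, KINASE = 0)),
                    exonCountMu = c(SF = 40, TF = 40, KINASE = 40),
                    plantProb = rbind(
                      splicing = c(SF = 1, TF = 0, KINASE = 0),
                      transcription = c(SF = 0, TF = 1, KINASE = 0)),
                    decoyRate = 0)
  b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                      sequences = FALSE)
  ev <- eventTable(b@genes)
  expect_true(all(geneTable(b@genes)$gene_id[
    geneTable(b@genes)$group == "SF"] %in% ev$gene_id[ev$dataset == "A"]))
  net <- buildNetwork(b, "A")
  spl <- inedgeCounts(net, "splicing")
  trn <- inedgeCounts(net, "transcription")
  grp <- setNames(networkNodes(net)$group, networkNodes(net)$gene_id)
  # every SF receives splicing edges from all nSF SFs (self included)
  expect_true(all(spl[grp[names(spl)] == "SF"] == cfg$nSF))
  # every TF receives transcription edges from all nTF TFs
  expect_true(all(trn[grp[names(trn)] == "TF"] == cfg$nTF))
})

test_that("zero AS rates and zero planting give an edgeless network", {
  cfg <- tinyConfig(seed = 6,
                    asRate = rbind(A = c(SF = 0, TF = 0, KINASE = 0),
                                   B = c(SF = 0, TF = 0, KINASE = 0)),
                    plantProb = rbind(
                      splicing = c(SF = 0, TF = 0, KINASE = 0),
                      transcription = c(SF = 0, TF = 0, KINASE = 0)),
                    decoyRate = 0)
  b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                      sequences = FALSE)
  expect_equal(nrow(eventTable(b@genes)), 0)
  net <- buildNetwork(b, "A")
  expect_equal(nrow(networkEdges(net)), 0)
  expect_true(all(networkNodes(net)$layer == "isolated"))
})
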