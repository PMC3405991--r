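adjFromPairs <- function(n, pairs) {
  A <- matrix(0, n, n, dimnames = list(as.character(seq_len(n)),
                                       as.character(seq_len(n))))
  for (p in pairs) { A[p[1], p[2]] <- 1; A[p[2], p[1]] <- 1 }
  A
}

test_that("clustering reproduces hand-computed graphs", {
  # triangle
  expect_equal(clusteringFromAdjacency(
    adjFromPairs(3, list(c(1, 2), c(2, 3), c(1, 3)))), 1)
  # star with 3 leaves: no closed triple
  expect_equal(clusteringFromAdjacency(
    adjFromPairs(4, list(c(1, 2), c(1, 3), c(1, 4)))), 0)
  # 4-cycle plus one chord: 6 closed / 8 connected triples
  expect_equal(clusteringFromAdjacency(
    adjFromPairs(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))),
    0.75)
  # local values on the chorded cycle: chord endpoints see 2/3 closed pairs
  loc <- clusteringFromAdjacency(
    adjFromPairs(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))),
    scope = "local")
  expect_equal(unname(loc), c(2 / 3, 1, 2 / 3, 1))
})

test_that("clustering equals exhaustive triple enumeration on small graphs", {
  # all graphs on up to 5 nodes, plus random 6-node graphs
  for (n in 2:5) {
    m <- choose(n, 2)
    pairs <- utils::combn(n, 2, simplify = FALSE)
    for (code in 0:(2^m - 1)) {
      sel <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
      A <- adjFromPairs(n, pairs[sel])
      expect_equal(clusteringFromAdjacency(A), oracleClustering(A))
    }
  }
  set.seed(1)
  pairs6 <- utils::combn(6, 2, simplify = FALSE)
  for (r in 1:400) {
    A <- adjFromPairs(6, pairs6[runif(15) < 0.45])
    expect_equal(clusteringFromAdjacency(A), oracleClustering(A))
  }
})

test_that("network clustering ignores direction, type and self-loops", {
  net <- wireNet(smallNodes,
                 c("s1", "t1", "splicing"),
                 c("s1", "s1", "splicing"),      # self-loop, ignored
                 c("t1", "s1", "transcription"), # reciprocal, collapses
                 c("t1", "t2", "transcription"),
                 c("s1", "t2", "splicing"))
  # undirected simple graph: s1-t1, t1-t2, s1-t2 = a triangle
  expect_equal(clusteringCoefficient(net), 1)
  expect_identical(clusteringCoefficient(net, "local")[["k1"]], 0)
})

test_that("clustering is invariant to node relabeling", {
  set.seed(2)
  A <- adjFromPairs(6, utils::combn(6, 2, simplify = FALSE)[runif(15) < 0.5])
  perm <- sample(6)
  expect_equal(clusteringFromAdjacency(A),
               clusteringFromAdjacency(A[perm, perm]))
})

test_that("sparseness follows the chosen denominator convention", {
  net <- wireNet(smallNodes,
                 c("s1", "t1", "splicing"),
                 c("s1", "k1", "splicing"),
                 c("t1", "t2", "transcription"),
                 c("t2", "k2", "transcription"))
  # 6 nodes, 2 SFs + 2 TFs as regulators: denominator (2+2)*6 = 24
  expect_equal(sparseness(net, "typed_bipartite"), 4 / 24)
  expect_equal(sparseness(net, "simple_n2"), 4 / 36)
  expect_equal(sparseness(net, "paper_literal"), 1 / 4)
  emptyNet <- makeNetwork(smallNodes,
                          data.frame(source = character(0),
                                     target = character(0),
                                     edge_type = character(0)))
  for (conv in c("typed_bipartite", "simple_n2", "paper_literal"))
    expect_equal(sparseness(emptyNet, conv), 0)
})

test_that("a fully saturated planted network has typed_bipartite sparseness 1", {
  cfg <- tinyConfig(seed = 5,
                    asRate = rbind(A = c(SF = 30, TF = 30, KINASE = 30),
                                   B = c(SF = 0, TF = 0, KINASE = 0)),
                    exonCountMu = c(SF = 40, TF = 40, KINASE = 40),
                    plantProb = rbind(
                      splicing = c(SF = 1, TF = 1, KINASE = 1),
                      transcription = c(SF = 1, TF = 1, KINASE = 1)),
                    decoyRate = 0)
  b <- generateBundle(cfg, atlas = FALSE, annotations = FALSE,
                      sequences = FALSE)
  # saturation requires every gene to carry an event in dataset A
  ev <- eventTable(b@genes)
  expect_true(all(geneTable(b@genes)$gene_id %in%
                  ev$gene_id[ev$dataset == "A"]))
  expect_equal(sparseness(buildNetwork(b, "A")), 1)
})

test_that("degree_swap preserves typed in/out degree sequences exactly", {
  b <- generateBundle(tinyConfig(seed = 21, nSF = 6, nTF = 9, nKinase = 8),
                      atlas = FALSE, annotations = FALSE, sequences = FALSE)
  net <- buildNetwork(b, "A")
  ens <- randomizeNetwork(net, "degree_swap", nRandom = 5, seed = 3)
  nodes <- networkNodes(net)$gene_id
  degs <- function(ed, ty) {
    d <- ed[ed$edge_type == ty, ]
    list(outd = table(factor(d$source, levels = nodes)),
         ind = table(factor(d$target, levels = nodes)))
  }
  for (rep in ens) {
    for (ty in c("splicing", "transcription")) {
      expect_identical(degs(rep, ty), degs(networkEdges(net), ty))
      # no duplicate typed edges
      d <- rep[rep$edge_type == ty, ]
      expect_false(anyDuplicated(paste(d$source, d$target)) > 0)
    }
  }
})

test_that("density_matched preserves the typed edge counts and roles", {
  b <- generateBundle(tinyConfig(seed = 22), atlas = FALSE,
                      annotations = FALSE, sequences = FALSE)
  net <- buildNetwork(b, "A")
  grp <- setNames(networkNodes(net)$group, networkNodes(net)$gene_id)
  ens <- randomizeNetwork(net, "density_matched", nRandom = 5, seed = 4)
  obs <- networkEdges(net)
  for (rep in ens) {
    expect_equal(sum(rep$edge_type == "splicing"),
                 sum(obs$edge_type == "splicing"))
    expect_equal(sum(rep$edge_type == "transcription"),
                 sum(obs$edge_type == "transcription"))
    expect_true(all(grp[rep$source[rep$edge_type == "splicing"]] == "SF"))
    expect_true(all(grp[rep$source[rep$edge_type == "transcription"]] ==
                    "TF"))
  }
})

test_that("ensembles are reproducible under a fixed seed", {
  b <- generateBundle(tinyConfig(seed = 23), atlas = FALSE,
                      annotations = FALSE, sequences = FALSE)
  net <- buildNetwork(b, "A")
  for (nm in c("degree_swap", "density_matched")) {
    e1 <- randomizeNetwork(net, nm, nRandom = 3, seed = 9)
    e2 <- randomizeNetwork(net, nm, nRandom = 3, seed = 9)
    expect_identical(e1, e2)
  }
})

test_that("an unswappable edge type returns copies with a warning", {
  net <- wireNet(smallNodes, c("s1", "t1", "splicing"))
  w <- testthat::capture_warnings(
    ens <- randomizeNetwork(net, "degree_swap", nRandom = 2, seed = 1))
  expect_match(w, "unswappable", all = TRUE)
  expect_identical(ens[[1]]$source, "s1")
})

test_that("planted triadic closure is detected against the degree-swap null", {
  # wire a network of closed triangles: clustering far above any
  # degree-preserving rewiring
  nodes <- data.frame(gene_id = sprintf("f%02d", 1:30),
                      group = rep(c("SF", "TF"), 15))
  edges <- do.call(rbind, lapply(seq(1, 28, by = 3), function(i) {
    ids <- sprintf("f%02d", c(i, i + 1, i + 2))
    ty <- ifelse(rep(c("SF", "TF"), 15)[c(i, i + 1, i + 2)] == "SF",
                 "splicing", "transcription")
    data.frame(source = ids, target = ids[c(2, 3, 1)], edge_type = ty)
  }))
  net <- makeNetwork(nodes, edges)
  res <- nullZscore(net, nullModel = "degree_swap", nRandom = 100, seed = 11)
  expect_gt(res@z, 5)
  expect_equal(res@empiricalP, 1 / 101)
  # empirical p can never undercut its 1/(n+1) floor
  expect_gte(res@empiricalP, 1 / (res@nRandom + 1))
})

test_that("a zero-variance null reports z as NA but a valid empirical p", {
  # saturated splicing layer: the density-matched null has exactly one
  # possible edge set, so the null sd is zero
  nodes <- data.frame(gene_id = c("s1", "s2", "k1"),
                      group = c("SF", "SF", "KINASE"))
  edges <- expand.grid(source = c("s1", "s2"),
                       target = c("s1", "s2", "k1"),
                       stringsAsFactors = FALSE)
  edges$edge_type <- "splicing"
  net <- makeNetwork(nodes, edges)
  res <- nullZscore(net, nullModel = "density_matched", nRandom = 10,
                    seed = 2)
  expect_true(is.na(res@z))
  expect_equal(res@empiricalP, 1)
})

test_that("global and local clustering agree with igraph transitivity", {
  skip_if_not_installed("igraph")
  for (s in 1:3) {
    b <- generateBundle(tinyConfig(seed = 300 + s), atlas = FALSE,
                        annotations = FALSE, sequences = FALSE)
    net <- buildNetwork(b, "A")
    A <- undirectedAdjacency(net)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(clusteringCoefficient(net),
                 igraph::transitivity(g, type = "global"))
    loc <- igraph::transitivity(g, type = "local", isolates = "zero")
    expect_equal(unname(clusteringCoefficient(net, "local")),
                 unname(ifelse(is.nan(loc), 0, loc)))
  }
})
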