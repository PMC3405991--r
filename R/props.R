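#' Undirected simple projection of a typed network
#'
#' Drops edge types, directions and self-loops and collapses parallel edges,
#' returning the 0/1 symmetric adjacency matrix over all nodes. This is the
#' graph on which clustering is computed.
#'
#' @param network a \linkS4class{RegulatoryNetwork}, or an edge data.frame
#'   (source, target) together with \code{nodeIds}.
#' @param nodeIds node identifiers when \code{network} is a plain edge table.
#' @return symmetric logical-valued numeric matrix with zero diagonal.
#' @export
undirectedAdjacency <- function(network, nodeIds = NULL) {
  if (is(network, "RegulatoryNetwork")) {
    ed <- network@edges
    nodeIds <- network@nodes$gene_id
  } else {
    ed <- network
    stopifnot(!is.null(nodeIds))
  }
  n <- length(nodeIds)
  A <- matrix(0, n, n, dimnames = list(nodeIds, nodeIds))
  if (nrow(ed)) {
    i <- match(ed$source, nodeIds)
    j <- match(ed$target, nodeIds)
    keep <- i != j
    A[cbind(i[keep], j[keep])] <- 1
    A[cbind(j[keep], i[keep])] <- 1
  }
  A
}

#' Clustering coefficient from an adjacency matrix
#'
#' Global transitivity 3 x triangles / connected triples, computed by
#' adjacency algebra: with A the simple undirected adjacency and k the
#' degree vector, the value is trace(A^3) / sum(k * (k - 1)); the local
#' coefficient of node i is (A^3)_ii / (k_i (k_i - 1)), defined as 0 when
#' k_i < 2. The global value is NA for graphs without any connected triple.
#'
#' @param A symmetric 0/1 adjacency matrix, zero diagonal.
#' @param scope "global" or "local".
#' @return a scalar, or a named vector of local coefficients.
#' @export
clusteringFromAdjacency <- function(A, scope = c("global", "local")) {
  scope <- match.arg(scope)
  k <- rowSums(A)
  A3diag <- diag(A %*% A %*% A)
  denom <- k * (k - 1)
  if (scope == "global") {
    if (sum(denom) == 0) return(NA_real_)
    sum(A3diag) / sum(denom)
  } else {
    out <- ifelse(denom > 0, A3diag / denom, 0)
    stats::setNames(out, rownames(A))
  }
}

#' Clustering coefficient of a regulatory network
#'
#' Computed on the undirected simple projection (edge types, directions and
#' self-loops dropped), matching the transitivity convention of standard
#' graph libraries. Global: 3 x triangles over connected triples, in [0, 1].
#' Local: per-node fraction of closed neighbor pairs, 0 when the degree is
#' below 2.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param scope "global" (default) or "local".
#' @return scalar or named per-node vector.
#' @export
clusteringCoefficient <- function(network, scope = c("global", "local")) {
  clusteringFromAdjacency(undirectedAdjacency(network), match.arg(scope))
}

#' Network sparseness under alternative denominator conventions
#'
#' Edge count over a maximum-possible-edge denominator. Three conventions
#' are provided because the field's literature is ambiguous about the
#' denominator:
#' \itemize{
#'   \item \code{typed_bipartite} (default): E over the number of wireable
#'     typed pairs, sum over edge types of (regulators of that type) x N;
#'     equals 1 for a fully saturated planted network.
#'   \item \code{simple_n2}: E / N^2.
#'   \item \code{paper_literal}: E / E^2 = 1 / E, the literal reading of a
#'     published formula that cannot stay in [0, 1]; kept for comparison.
#' }
#' All conventions return 0 for an edgeless network.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param convention denominator convention.
#' @return scalar sparseness.
#' @export
sparseness <- function(network,
                       convention = c("typed_bipartite", "simple_n2",
                                      "paper_literal")) {
  convention <- match.arg(convention)
  E <- nrow(network@edges)
  if (E == 0) return(0)
  N <- nrow(network@nodes)
  grp <- network@nodes$group
  switch(convention,
    typed_bipartite = E / ((sum(grp == "SF") + sum(grp == "TF")) * N),
    simple_n2 = E / N^2,
    paper_literal = 1 / E)
}

#' Randomized network ensembles
#'
#' Two null models over the typed directed edge set:
#' \itemize{
#'   \item \code{degree_swap}: double-edge swaps within each edge type
#'     (default 10 x E attempted swaps per replicate), preserving every
#'     node's typed in- and out-degree exactly; swaps that would duplicate
#'     an existing typed edge are rejected, self-loops may form (degrees are
#'     still preserved).
#'   \item \code{density_matched}: uniform random typed edge sets with the
#'     observed number of edges per type and the same role constraints
#'     (splicing sources drawn from SFs, transcription sources from TFs,
#'     targets from all nodes), without duplicate typed edges.
#' }
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param nullModel "degree_swap" or "density_matched".
#' @param nRandom number of replicates (>= 1).
#' @param seed RNG seed.
#' @param swapFactor attempted swaps per edge for degree_swap.
#' @return list of edge data.frames (source, target, edge_type), one per
#'   replicate.
#' @export
randomizeNetwork <- function(network,
                             nullModel = c("degree_swap", "density_matched"),
                             nRandom = 1000, seed = NULL, swapFactor = 10) {
  nullModel <- match.arg(nullModel)
  stopifnot(nRandom >= 1)
  nodes <- network@nodes$gene_id
  grp <- network@nodes$group
  ed <- network@edges
  withSeed(seed, {
    lapply(seq_len(nRandom), function(r) {
      parts <- lapply(c("splicing", "transcription"), function(ty) {
        sub <- ed[ed$edge_type == ty, , drop = FALSE]
        if (nullModel == "degree_swap") {
          degreeSwapEdges(sub, nodes, swapFactor)
        } else {
          srcPool <- nodes[grp == if (ty == "splicing") "SF" else "TF"]
          densityMatchedEdges(nrow(sub), srcPool, nodes, ty)
        }
      })
      do.call(rbind, parts)
    })
  })
}

degreeSwapEdges <- function(sub, nodes, swapFactor) {
  E <- nrow(sub)
  if (E < 2) {
    if (E > 0) warning("fewer than 2 edges of type ", sub$edge_type[1],
                       ": degree sequence unswappable, returning a copy")
    return(sub[, c("source", "target", "edge_type"), drop = FALSE])
  }
  n <- length(nodes)
  src <- match(sub$source, nodes)
  tgt <- match(sub$target, nodes)
  M <- matrix(FALSE, n, n)
  M[cbind(src, tgt)] <- TRUE
  nTry <- ceiling(swapFactor * E)
  e1 <- sample.int(E, nTry, replace = TRUE)
  e2 <- sample.int(E, nTry, replace = TRUE)
  for (t in seq_len(nTry)) {
    i <- e1[t]; j <- e2[t]
    if (i == j) next
    a <- src[i]; b <- tgt[i]; cc <- src[j]; d <- tgt[j]
    if (b == d || a == cc) next            # swap would be a no-op
    if (M[a, d] || M[cc, b]) next          # would duplicate a typed edge
    M[a, b] <- FALSE; M[cc, d] <- FALSE
    M[a, d] <- TRUE; M[cc, b] <- TRUE
    tgt[i] <- d; tgt[j] <- b
  }
  data.frame(source = nodes[src], target = nodes[tgt],
             edge_type = sub$edge_type[1])
}

densityMatchedEdges <- function(E, srcPool, nodes, edge_type) {
  if (E == 0 || !length(srcPool)) {
    return(data.frame(source = character(0), target = character(0),
                      edge_type = character(0)))
  }
  nPairs <- length(srcPool) * length(nodes)
  if (E > nPairs) stop("more edges than wireable pairs")
  pick <- sample.int(nPairs, E)
  si <- ((pick - 1L) %% length(srcPool)) + 1L
  ti <- ((pick - 1L) %/% length(srcPool)) + 1L
  data.frame(source = srcPool[si], target = nodes[ti],
             edge_type = edge_type)
}

#' Significance of a network statistic against a null ensemble
#'
#' Computes the observed statistic, the null mean and sd over
#' \code{nRandom} randomized replicates, the standardized z-score (NA when
#' the null sd is zero) and the upper-tail empirical p-value
#' (r + 1) / (nRandom + 1), where r counts replicates with a statistic at
#' least as large as observed. The (r+1)/(n+1) estimator keeps the p-value
#' strictly positive with lower bound 1 / (nRandom + 1).
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param stat "clustering", or a function(edges, nodeIds) -> numeric.
#' @param nullModel,nRandom,seed,swapFactor passed to
#'   \code{\link{randomizeNetwork}}.
#' @return a \linkS4class{NullEnsembleResult}.
#' @export
nullZscore <- function(network, stat = "clustering",
                       nullModel = c("degree_swap", "density_matched"),
                       nRandom = 1000, seed = NULL, swapFactor = 10) {
  nullModel <- match.arg(nullModel)
  nodes <- network@nodes$gene_id
  statFun <- if (is.function(stat)) stat else switch(stat,
    clustering = function(edges, nodeIds)
      clusteringFromAdjacency(undirectedAdjacency(edges, nodeIds)),
    stop("unknown statistic: ", stat))
  statName <- if (is.function(stat)) "custom" else stat
  observed <- statFun(network@edges, nodes)
  ens <- randomizeNetwork(network, nullModel = nullModel, nRandom = nRandom,
                          seed = seed, swapFactor = swapFactor)
  nullValues <- vapply(ens, statFun, numeric(1), nodeIds = nodes)
  mu <- mean(nullValues, na.rm = TRUE)
  sdv <- stats::sd(nullValues, na.rm = TRUE)
  z <- if (is.na(sdv) || sdv == 0) NA_real_ else (observed - mu) / sdv
  r <- sum(nullValues >= observed, na.rm = TRUE)
  new("NullEnsembleResult", observed = observed, nullMean = mu,
      nullSd = sdv, z = z, empiricalP = (r + 1) / (nRandom + 1),
      nullValues = nullValues, nRandom = as.integer(nRandom),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nullModel = nullModel, stat = statName)
}
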