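#' Per-group inedge density of one edge type
#'
#' Partitions the per-node inedge counts of the given type by target group
#' and summarizes each group by its mean and standard error of the mean
#' (the +/- convention used for reported group densities).
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param edgeType "splicing" or "transcription".
#' @param selfLoops count autoregulatory edges (default TRUE).
#' @return data.frame with columns \code{group}, \code{edge_type}, \code{n},
#'   \code{mean}, \code{sem}, plus a list-column \code{counts} holding the
#'   per-node counts of the group.
#' @export
inedgeDensity <- function(network, edgeType, selfLoops = TRUE) {
  edgeType <- assertEdgeType(edgeType)
  counts <- inedgeCounts(network, edgeType, selfLoops = selfLoops)
  grp <- stats::setNames(network@nodes$group, network@nodes$gene_id)
  out <- do.call(rbind, lapply(GROUPS, function(g) {
    x <- counts[grp[names(counts)] == g]
    data.frame(group = g, edge_type = edgeType, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sem = semOf(x))
  }))
  out$counts <- lapply(GROUPS, function(g) counts[grp[names(counts)] == g])
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The U statistic counts pairs (x in a, y in b) with x > y, ties counting
#' one half. For small samples the p-value is exact, computed by full
#' enumeration of all ways to split the pooled values (so ties are handled
#' exactly); when the number of splits exceeds \code{maxEnum} the
#' tie-corrected normal approximation with continuity correction is used.
#' The two-sided exact p is the fraction of splits at least as far from the
#' null expectation n_a n_b / 2 as observed.
#'
#' @param a,b numeric samples (both nonempty).
#' @param sides "two" (default), "greater" (a tends larger) or "less".
#' @param maxEnum largest number of splits to enumerate exactly.
#' @return list with \code{U}, \code{p}, \code{sides}, \code{method}
#'   ("exact" or "normal_tie_corrected").
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6), sides = "less")  # exact p = 1/20
#' @export
mannWhitney <- function(a, b, sides = c("two", "greater", "less"),
                        maxEnum = 2e5) {
  sides <- match.arg(sides)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  pr <- rank(pooled)
  U <- sum(pr[seq_len(na)]) - na * (na + 1) / 2
  nSplit <- choose(n, na)
  if (nSplit <= maxEnum) {
    cmb <- utils::combn(n, na)
    allU <- colSums(matrix(pr[cmb], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- switch(sides,
      two = mean(abs(allU - na * nb / 2) >= abs(U - na * nb / 2) - eps),
      greater = mean(allU >= U - eps),
      less = mean(allU <= U + eps))
    list(U = U, p = p, sides = sides, method = "exact")
  } else {
    alt <- switch(sides, two = "two.sided", greater = "greater",
                  less = "less")
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                              exact = FALSE, correct = TRUE))
    list(U = U, p = wt$p.value, sides = sides,
         method = "normal_tie_corrected")
  }
}

#' Spearman correlation between splicing and transcription inedges
#'
#' For the nodes of one target group, the rank correlation between each
#' node's splicing inedge count and its transcription inedge count. Ties are
#' handled by average ranks; the correlation is NA (with a message in the
#' result) when either count vector is constant.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param group "SF", "TF" or "KINASE".
#' @param selfLoops count self-loops (default TRUE).
#' @return list with \code{rho}, \code{n}, \code{group}.
#' @export
splicingTranscriptionCorrelation <- function(network, group,
                                             selfLoops = TRUE) {
  group <- assertGroup(group)
  ids <- network@nodes$gene_id[network@nodes$group == group]
  if (!length(ids)) stop("group ", group, " is empty")
  x <- inedgeCounts(network, "splicing", selfLoops = selfLoops)[ids]
  y <- inedgeCounts(network, "transcription", selfLoops = selfLoops)[ids]
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y, method = "spearman")
  list(rho = rho, n = length(ids), group = group)
}

#' Randomized-group control for the inedge-density contrast
#'
#' Repeatedly partitions the pooled network nodes, without replacement, into
#' pseudo-groups of the original group sizes and records each pseudo-group's
#' mean splicing and transcription inedge counts. If the observed group
#' contrast merely reflected group sizes, the true means would fall inside
#' the spread of these pseudo-group means; a real planted contrast separates
#' from them.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param nIter number of random partitions (default 100).
#' @param seed RNG seed.
#' @param sizes named sizes of the pseudo-groups; defaults to the actual
#'   group sizes.
#' @return list with \code{perIteration} (iter, pseudo_group, splicing_mean,
#'   transcription_mean) and \code{aggregate} (pseudo_group, edge_type,
#'   mean, sd over iterations).
#' @export
randomGroupControl <- function(network, nIter = 100, seed = NULL,
                               sizes = NULL) {
  nodes <- network@nodes$gene_id
  if (is.null(sizes)) {
    tab <- table(factor(network@nodes$group, levels = GROUPS))
    sizes <- stats::setNames(as.integer(tab), GROUPS)
    sizes <- sizes[sizes > 0]
  }
  if (sum(sizes) > length(nodes))
    stop("pseudo-group sizes sum to more than the node count")
  sp <- inedgeCounts(network, "splicing")
  tr <- inedgeCounts(network, "transcription")
  withSeed(seed, {
    rows <- lapply(seq_len(nIter), function(it) {
      picked <- sample(nodes, sum(sizes))
      splits <- split(picked, rep(names(sizes), sizes))
      do.call(rbind, lapply(names(sizes), function(gname) {
        ids <- splits[[gname]]
        data.frame(iter = it, pseudo_group = gname,
                   splicing_mean = mean(sp[ids]),
                   transcription_mean = mean(tr[ids]))
      }))
    })
    perIter <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(names(sizes), function(gname) {
      d <- perIter[perIter$pseudo_group == gname, ]
      rbind(
        data.frame(pseudo_group = gname, edge_type = "splicing",
                   mean = mean(d$splicing_mean), sd = stats::sd(d$splicing_mean)),
        data.frame(pseudo_group = gname, edge_type = "transcription",
                   mean = mean(d$transcription_mean),
                   sd = stats::sd(d$transcription_mean)))
    }))
    rownames(perIter) <- rownames(agg) <- NULL
    list(perIteration = perIter, aggregate = agg)
  })
}
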