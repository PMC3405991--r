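# Independent brute-force oracles, deliberately naive: each one implements
# its statistic by direct enumeration, sharing no code with the package path
# it checks.

# global clustering by explicit triple enumeration over node index triples
oracleClustering <- function(A) {
  n <- nrow(A)
  closed <- 0; triples <- 0
  if (n < 3) return(NA_real_)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    for (j in nb) for (k in nb) {
      if (j >= k) next
      triples <- triples + 1
      if (A[j, k] > 0) closed <- closed + 1
    }
  }
  if (triples == 0) return(NA_real_)
  closed / triples
}

# Mann-Whitney p by full enumeration of label assignments
oracleMW <- function(a, b, sides) {
  pooled <- c(a, b)
  na <- length(a)
  uOf <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  uObs <- uOf(seq_len(na))
  cmb <- utils::combn(length(pooled), na)
  allU <- apply(cmb, 2, uOf)
  ctr <- na * length(b) / 2
  eps <- 1e-9
  switch(sides,
         two = mean(abs(allU - ctr) >= abs(uObs - ctr) - eps),
         greater = mean(allU >= uObs - eps),
         less = mean(allU <= uObs + eps))
}

# Spearman rho as Pearson on average ranks
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# upper-tail hypergeometric P(X >= k) by enumerating all placements of the
# K "type a" targets among N universe slots
oracleHyperTail <- function(N, K, n, k) {
  total <- choose(N, K)
  count <- 0
  for (placement in utils::combn(N, K, simplify = FALSE)) {
    overlap <- sum(placement <= n)  # wlog b's targets are slots 1..n
    if (overlap >= k) count <- count + 1
  }
  count / total
}

# one-tailed Fisher p by enumerating all tables with the observed margins
oracleFisherGreater <- function(a, b, cc, d) {
  rowA <- a + b; colHit <- a + cc; N <- a + b + cc + d
  probs <- vapply(0:min(rowA, colHit), function(x) {
    if (colHit - x > N - rowA) return(0)
    choose(rowA, x) * choose(N - rowA, colHit - x) / choose(N, colHit)
  }, numeric(1))
  sum(probs[(0:min(rowA, colHit)) >= a])
}

# longest TRUE run by scanning all substrings
oracleLongestRun <- function(flags) {
  n <- length(flags)
  best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    if (all(flags[i:j])) best <- max(best, j - i + 1)
  }
  best
}

# search regions recomputed from scratch from the window-rule statement
# (independent of the package's region code)
oracleRegions <- function(e, w) {
  regs <- list(c(e$exon_start, e$exon_end))
  if (e$event_type %in% c("cassette", "alt3") && !is.na(e$up_start) &&
      w > 0) {
    regs <- c(regs, list(
      if (e$strand == "+")
        c(max(e$up_start, e$exon_start - w), e$up_end)
      else c(e$up_start, min(e$up_end, e$exon_end + w))))
  }
  if (e$event_type %in% c("cassette", "alt5") && !is.na(e$down_start) &&
      w > 0) {
    regs <- c(regs, list(
      if (e$strand == "+")
        c(e$down_start, min(e$down_end, e$exon_end + w))
      else c(max(e$down_start, e$exon_start - w), e$down_end)))
  }
  regs
}

# splicing edge set by brute-force scan over every (hit, event, region)
# triple using plain interval arithmetic
oracleSplicingEdges <- function(genes, hits, windowNt = 100,
                                requireConserved = TRUE, dataset = "A") {
  ev <- eventTable(genes)
  ev <- ev[ev$dataset == dataset, , drop = FALSE]
  if (requireConserved) hits <- hits[hits$conserved, , drop = FALSE]
  found <- character(0)
  if (nrow(ev) && nrow(hits)) {
    for (h in seq_len(nrow(hits))) {
      for (e in seq_len(nrow(ev))) {
        if (hits$chrom[h] != ev$chrom[e]) next
        for (reg in oracleRegions(ev[e, , drop = FALSE], windowNt)) {
          if (max(reg[1], hits$start[h]) <= min(reg[2], hits$end[h])) {
            found <- c(found,
                       paste(hits$factor_id[h], ev$gene_id[e], sep = "->"))
          }
        }
      }
    }
  }
  sort(unique(found))
}

edgeKeys <- function(edges) {
  sort(unique(paste(edges$source, edges$target, sep = "->")))
}
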