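factorTargetSets <- function(network) {
  ed <- network@edges
  nd <- network@nodes
  sf <- nd$gene_id[nd$group == "SF"]
  tf <- nd$gene_id[nd$group == "TF"]
  spl <- ed[ed$edge_type == "splicing", , drop = FALSE]
  trn <- ed[ed$edge_type == "transcription", , drop = FALSE]
  list(
    SF = stats::setNames(
      lapply(sf, function(f) unique(spl$target[spl$source == f])), sf),
    TF = stats::setNames(
      lapply(tf, function(f) unique(trn$target[trn$source == f])), tf))
}

#' Scan all factor pairs for co-regulation of shared targets
#'
#' For every unordered pair of regulators, tests whether they share more
#' targets than expected by chance with an upper-tail hypergeometric test:
#' with N the universe size, K and n the two factors' target-set sizes and k
#' their overlap, p = P(X >= k). SF-SF pairs compare splicing target sets,
#' TF-TF transcription target sets, and SF-TF pairs compare the SF's
#' splicing targets with the TF's transcription targets. The tail is
#' computed in log space so p-values far below double precision's 1e-16
#' remain meaningful at the default significance cutoff. A factor with zero
#' targets yields p = 1 by convention.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param alpha significance cutoff on p (default 1e-16).
#' @param universe NULL for all network nodes (default), or a character
#'   vector of gene ids restricting both the universe and the target sets.
#' @return data.frame with one row per pair: \code{factor_a},
#'   \code{factor_b}, \code{pair_class}, \code{N_universe}, \code{K_a},
#'   \code{n_b}, \code{k_overlap}, \code{log10_p}, \code{p},
#'   \code{significant}.
#' @export
pairCoregulationScan <- function(network, alpha = 1e-16, universe = NULL) {
  if (is.null(universe)) universe <- network@nodes$gene_id
  N <- length(universe)
  sets <- factorTargetSets(network)
  sets$SF <- lapply(sets$SF, intersect, y = universe)
  sets$TF <- lapply(sets$TF, intersect, y = universe)
  factors <- data.frame(
    id = c(names(sets$SF), names(sets$TF)),
    grp = rep(c("SF", "TF"), c(length(sets$SF), length(sets$TF))))
  if (nrow(factors) < 2) {
    return(data.frame(factor_a = character(0), factor_b = character(0),
                      pair_class = character(0), N_universe = integer(0),
                      K_a = integer(0), n_b = integer(0),
                      k_overlap = integer(0), log10_p = numeric(0),
                      p = numeric(0), significant = logical(0)))
  }
  idx <- utils::combn(nrow(factors), 2)
  rows <- lapply(seq_len(ncol(idx)), function(c2) {
    i <- idx[1, c2]; j <- idx[2, c2]
    ga <- factors$grp[i]; gb <- factors$grp[j]
    # order SF before TF inside a mixed pair for a stable pair_class label
    if (ga == "TF" && gb == "SF") { tmp <- i; i <- j; j <- tmp
                                    ga <- "SF"; gb <- "TF" }
    ta <- sets[[ga]][[factors$id[i]]]
    tb <- sets[[gb]][[factors$id[j]]]
    K <- length(ta); n <- length(tb); k <- length(intersect(ta, tb))
    lp <- if (K == 0 || n == 0) 0
      else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                         log.p = TRUE)
    data.frame(factor_a = factors$id[i], factor_b = factors$id[j],
               pair_class = paste(ga, gb, sep = "-"), N_universe = N,
               K_a = K, n_b = n, k_overlap = k,
               log10_p = lp / log(10), p = exp(lp))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$log10_p < log10(alpha)
  out
}

#' Fraction of each group covered by significant co-regulating pairs
#'
#' For each target group and pair class, the fraction of the group's genes
#' that are shared targets (targets of BOTH factors) of at least one
#' significant pair of that class, plus a union row over all classes.
#'
#' @param results output of \code{\link{pairCoregulationScan}}.
#' @param network the scanned \linkS4class{RegulatoryNetwork}.
#' @return data.frame with columns \code{group}, \code{pair_class} (one of
#'   "SF-SF", "TF-TF", "SF-TF", "any"), \code{fraction}.
#' @export
pairCoverage <- function(results, network) {
  sets <- factorTargetSets(network)
  allSets <- c(sets$SF, sets$TF)
  sig <- results[results$significant, , drop = FALSE]
  classes <- c("SF-SF", "TF-TF", "SF-TF")
  coveredBy <- stats::setNames(lapply(classes, function(cl) {
    d <- sig[sig$pair_class == cl, , drop = FALSE]
    if (!nrow(d)) return(character(0))
    unique(unlist(lapply(seq_len(nrow(d)), function(r)
      intersect(allSets[[d$factor_a[r]]], allSets[[d$factor_b[r]]]))))
  }), classes)
  coveredBy$any <- unique(unlist(coveredBy))
  nd <- network@nodes
  out <- do.call(rbind, lapply(GROUPS, function(g) {
    ids <- nd$gene_id[nd$group == g]
    do.call(rbind, lapply(names(coveredBy), function(cl) {
      data.frame(group = g, pair_class = cl,
                 fraction = if (length(ids))
                   mean(ids %in% coveredBy[[cl]]) else NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}
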