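asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
}

#' Fraction of sequences containing a motif
#'
#' Counts the sequences with at least one match of the motif on the given
#' strand. The motif may be an exact ACGT string or an IUPAC-degenerate
#' pattern (degenerate codes matched via fixed = FALSE).
#'
#' @param sequences a \link[Biostrings]{DNAStringSet} or character vector.
#' @param motif motif string, no longer than the shortest sequence.
#' @return scalar fraction in [0, 1].
#' @export
hitFraction <- function(sequences, motif) {
  seqs <- asDNAStringSet(sequences)
  if (!length(seqs)) stop("empty sequence set")
  if (nchar(motif) > min(Biostrings::width(seqs)))
    stop("motif longer than the shortest sequence")
  hits <- Biostrings::vcountPattern(motif, seqs, fixed = FALSE)
  mean(hits > 0)
}

#' Fisher exact test for motif enrichment in bound versus control sequences
#'
#' Builds the 2x2 table of (motif hit / no hit) x (bound / control) and
#' tests, one-tailed by default, whether the motif is enriched among the
#' bound sequences. The odds ratio is the sample odds ratio with a Haldane
#' correction (0.5 added to every cell) when any cell is zero.
#'
#' @param bound,control sequence sets (DNAStringSet or character), both
#'   nonempty.
#' @param motif motif string (exact or IUPAC).
#' @param sides "greater" (default: enrichment in bound), "less" or "two".
#' @return list with cells \code{a}, \code{b}, \code{c}, \code{d} (a = bound
#'   hits, b = bound non-hits, c = control hits, d = control non-hits),
#'   \code{odds_ratio}, \code{p}, \code{sides}.
#' @export
fisherEnrichment <- function(bound, control, motif,
                             sides = c("greater", "less", "two")) {
  sides <- match.arg(sides)
  bSet <- asDNAStringSet(bound); cSet <- asDNAStringSet(control)
  if (!length(bSet) || !length(cSet)) stop("both sets must be nonempty")
  bHit <- Biostrings::vcountPattern(motif, bSet, fixed = FALSE) > 0
  cHit <- Biostrings::vcountPattern(motif, cSet, fixed = FALSE) > 0
  a <- sum(bHit); b <- sum(!bHit)
  cc <- sum(cHit); d <- sum(!cHit)
  tab <- matrix(c(a, cc, b, d), nrow = 2)
  alt <- switch(sides, greater = "greater", less = "less", two = "two.sided")
  p <- stats::fisher.test(tab, alternative = alt)$p.value
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  oddsRatio <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(a = a, b = b, c = cc, d = d, odds_ratio = oddsRatio, p = p,
       sides = sides)
}

#' Generic annotation-term enrichment among a target set
#'
#' For each term in the annotation table, an upper-tail hypergeometric test
#' of term membership among the targets against the background: with N
#' background genes, K carrying the term, n targets (inside the background)
#' and k targets carrying the term, p = P(X >= k). Terms with no background
#' member are skipped with a warning. Benjamini-Hochberg adjusted values are
#' included.
#'
#' @param targetSet,backgroundSet character vectors of gene ids; targets
#'   outside the background are dropped.
#' @param annotationTable data.frame with columns \code{gene_id} and
#'   \code{term}.
#' @return data.frame per term: \code{term}, \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{p}, \code{p_adj}; zero rows for an empty target set.
#' @export
termEnrichment <- function(targetSet, backgroundSet, annotationTable) {
  stopifnot(all(c("gene_id", "term") %in% names(annotationTable)))
  targets <- intersect(unique(targetSet), backgroundSet)
  empty <- data.frame(term = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      p_adj = numeric(0))
  if (!length(targets)) return(empty)
  N <- length(unique(backgroundSet))
  n <- length(targets)
  terms <- unique(annotationTable$term)
  rows <- lapply(terms, function(tm) {
    members <- unique(
      annotationTable$gene_id[annotationTable$term == tm])
    members <- intersect(members, backgroundSet)
    if (!length(members)) {
      warning("term absent from background, skipped: ", tm)
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(members, targets))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, N = N, K = K, n = n, k = k, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
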