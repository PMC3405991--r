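#' Per-group summary of predicted phosphorylation sites
#'
#' For each regulator group: the fraction of proteins with at least one
#' predicted site; among site-carrying proteins, the fraction whose site
#' coverage (site count over protein length) strictly exceeds
#' \code{coverageThreshold}; and the mean site density over all proteins of
#' the group.
#'
#' @param annotations protein annotation data.frame as produced by
#'   \code{\link{generateProteinAnnotations}} (columns protein_id, group,
#'   length, list-column phospho); rows with group RANDOM are ignored.
#' @param coverageThreshold coverage cutoff (default 0.10, strict).
#' @return data.frame per group: \code{group}, \code{n},
#'   \code{frac_with_site}, \code{frac_high_coverage} (denominator:
#'   proteins with >= 1 site; NA when none), \code{mean_density}.
#' @export
phosphoSummary <- function(annotations, coverageThreshold = 0.10) {
  ann <- annotations[annotations$group %in% GROUPS, , drop = FALSE]
  if (!nrow(ann)) stop("no annotated proteins in SF/TF/KINASE groups")
  if (any(ann$length <= 0)) stop("zero-length protein in annotations")
  nSites <- vapply(ann$phospho, length, integer(1))
  density <- nSites / ann$length
  out <- do.call(rbind, lapply(GROUPS, function(g) {
    sel <- ann$group == g
    has <- nSites[sel] >= 1
    data.frame(
      group = g, n = sum(sel),
      frac_with_site = if (sum(sel)) mean(has) else NA_real_,
      frac_high_coverage = if (any(has))
        mean(density[sel][has] > coverageThreshold) else NA_real_,
      mean_density = if (sum(sel)) mean(density[sel]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Longest run of disordered residues
#'
#' @param scores numeric per-residue disorder scores in [0, 1].
#' @param cutoff disorder cutoff (default 0.75).
#' @param inclusive score equal to the cutoff counts as disordered
#'   (default TRUE).
#' @return length of the longest consecutive disordered stretch.
#' @export
longestDisorderRun <- function(scores, cutoff = 0.75, inclusive = TRUE) {
  if (!length(scores)) return(0L)
  dis <- if (inclusive) scores >= cutoff else scores > cutoff
  r <- rle(dis)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Per-group summary of intrinsic protein disorder
#'
#' For each regulator group: the mean per-protein fraction of residues at or
#' above the disorder cutoff, and the fraction of proteins that are
#' long-disordered, i.e. contain at least one run of \code{minRun}
#' consecutive disordered residues. When the annotation table carries a
#' RANDOM proteome pool, a random baseline is computed as the mean over
#' \code{randomDraws} draws of \code{randomSize} pool proteins each.
#'
#' @param annotations protein annotation data.frame (list-column
#'   \code{disorder} of per-residue scores; group RANDOM rows form the
#'   baseline pool).
#' @param cutoff disorder score cutoff (default 0.75, inclusive).
#' @param minRun minimum run length defining a long-disordered protein
#'   (default 30).
#' @param inclusive whether a score equal to the cutoff is disordered.
#' @param randomDraws,randomSize baseline resampling scheme (default 10
#'   draws of 250).
#' @param seed RNG seed for the baseline draws.
#' @return list with \code{groups} (group, n, mean_frac_disordered,
#'   frac_long_disordered), \code{random} (per-draw and averaged baseline,
#'   or NULL without a pool) and \code{perProtein} (protein_id, group,
#'   frac_disordered, long_disordered) for downstream group comparisons.
#' @export
disorderSummary <- function(annotations, cutoff = 0.75, minRun = 30,
                            inclusive = TRUE, randomDraws = 10,
                            randomSize = 250, seed = NULL) {
  frac <- vapply(annotations$disorder, function(s) {
    if (!length(s)) return(0)
    mean(if (inclusive) s >= cutoff else s > cutoff)
  }, numeric(1))
  long <- vapply(annotations$disorder, function(s)
    longestDisorderRun(s, cutoff, inclusive) >= minRun, logical(1))
  perProtein <- data.frame(protein_id = annotations$protein_id,
                           group = annotations$group,
                           frac_disordered = frac, long_disordered = long)
  groups <- do.call(rbind, lapply(GROUPS, function(g) {
    sel <- perProtein$group == g
    data.frame(group = g, n = sum(sel),
               mean_frac_disordered = if (sum(sel)) mean(frac[sel])
                 else NA_real_,
               frac_long_disordered = if (sum(sel)) mean(long[sel])
                 else NA_real_)
  }))
  rownames(groups) <- NULL
  random <- NULL
  pool <- which(perProtein$group == "RANDOM")
  if (length(pool)) {
    draws <- withSeed(seed, {
      do.call(rbind, lapply(seq_len(randomDraws), function(d) {
        take <- sample(pool, min(randomSize, length(pool)))
        data.frame(draw = d,
                   mean_frac_disordered = mean(frac[take]),
                   frac_long_disordered = mean(long[take]))
      }))
    })
    random <- list(
      perDraw = draws,
      mean_frac_disordered = mean(draws$mean_frac_disordered),
      frac_long_disordered = mean(draws$frac_long_disordered))
  }
  list(groups = groups, random = random, perProtein = perProtein)
}
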