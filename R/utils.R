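#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed}, restoring the caller's
#' RNG state afterwards, so seeded package functions do not perturb the
#' session stream. With \code{seed = NULL} the expression runs on the current
#' stream.
#'
#' @param seed integer scalar or NULL.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from one parent seed
#'
#' One global seed fans out to per-stage seeds so any stage can be re-run in
#' isolation with the same stream it saw inside the pipeline. Children are
#' drawn uniformly below 2^31 - 1.
#'
#' @param seed parent integer seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}.
#' @export
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# standard error of the mean; NA for n < 2
semOf <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

GROUPS <- c("SF", "TF", "KINASE")

assertGroup <- function(group) {
  match.arg(group, GROUPS)
}

assertEdgeType <- function(edge_type) {
  match.arg(edge_type, c("splicing", "transcription"))
}
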