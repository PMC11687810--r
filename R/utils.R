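## Internal helpers shared across modules.

#' Geometric mean
#'
#' Applied directly to Ct values (which are already log-scale quantities);
#' used to pool the endogenous-control Cts per sample.
#'
#' @param x positive numeric vector.
#' @return the geometric mean of \code{x}.
#' @export
geomMean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(x > 0))
  exp(mean(log(x)))
}

#' Two-sided rank-sum (Mann-Whitney) p-value
#'
#' Exact when both groups have at most \code{exactMax} observations and there
#' are no ties; otherwise the normal approximation with tie correction (no
#' continuity correction). Degenerate inputs where every value is identical
#' across both groups give p = 1.
#'
#' @param x,y numeric vectors for the two groups (non-empty).
#' @param exactMax maximum per-group size for the exact distribution.
#' @return two-sided p-value.
#' @export
rankSumP <- function(x, y, exactMax = 8L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(x) <= exactMax && length(y) <= exactMax
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
  min(1, p)
}

## Candidate split points: midpoints between consecutive distinct sorted values
midpointsBetween <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(numeric())
  (u[-1L] + u[-length(u)]) / 2
}

## Deterministic RNG scope: run expr under a seed, restore global state after
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Spawn sub-seeds from a master seed (kept < 2^31)
spawnSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
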