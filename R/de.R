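## Per-miRNA case-vs-control testing: normality gate, rank-sum test,
## Benjamini-Hochberg correction and fold-difference reporting, per cohort.

#' Normality gate
#'
#' Shapiro-Wilk on every group; the miRNA is considered normally distributed
#' only when every group has p > 0.05. The pipeline applies non-parametric
#' tests regardless (the global study-design choice); the gate is computed
#' and recorded per miRNA for reporting. Groups with fewer than 3 values, or
#' constant groups (where the test is undefined), give \code{NA}.
#'
#' @param valuesByGroup list of numeric vectors, one per group.
#' @return TRUE / FALSE / NA.
#' @export
normalityGate <- function(valuesByGroup) {
  stopifnot(is.list(valuesByGroup), length(valuesByGroup) >= 1L)
  ps <- vapply(valuesByGroup, function(v) {
    if (length(v) < 3L || length(v) > 5000L) return(NA_real_)
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (anyNA(ps)) return(NA)
  all(ps > 0.05)
}

#' Two-sided rank-sum test for differential expression
#'
#' Exact when both groups have at most 8 observations and no ties, otherwise
#' the normal approximation with tie correction. Fully tied input gives
#' p = 1.
#'
#' @param caseValues,controlValues normalized expression vectors (non-empty).
#' @return two-sided p-value.
#' @export
deTest <- function(caseValues, controlValues) rankSumP(caseValues, controlValues)

#' Benjamini-Hochberg adjustment
#'
#' \eqn{p^{adj}_{(i)} = \min_{j \ge i} ( m\, p_{(j)} / j )} capped at 1,
#' applied across the miRNA panel within one cohort-vs-control comparison.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Differential-expression table for one cohort
#'
#' One row per retained miRNA comparing the cohort's cases to the single
#' control group: raw rank-sum p, BH-adjusted p (family = all retained
#' miRNAs in this comparison), median fold-difference, the normality-gate
#' record, and the direction call (\code{up}/\code{down} when the adjusted p
#' is below \code{alpha}, \code{ns} otherwise). Normalization-control assays
#' are excluded. Rows are sorted by adjusted then raw p.
#'
#' @param normalized a [NormalizedMatrix-class].
#' @param samples sample metadata with \code{sample_id}, \code{cohort},
#'   \code{group}.
#' @param cohort cohort label of the case population to compare.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame \code{assay_id}, \code{cohort}, \code{raw_p},
#'   \code{fdr_p}, \code{median_fd}, \code{normal}, \code{direction}.
#' @export
deTable <- function(normalized, samples, cohort, alpha = 0.05) {
  stopifnot(is(normalized, "NormalizedMatrix"))
  ex <- exprValues(normalized)
  samples <- samples[match(rownames(ex), samples$sample_id), , drop = FALSE]
  caseIdx <- which(samples$cohort == cohort & samples$group == "case")
  ctrlIdx <- which(samples$group == "control")
  if (!length(caseIdx)) {
    warnf("cohort '%s' has no case samples; returning an empty table", cohort)
    return(data.frame(assay_id = character(), cohort = character(),
                      raw_p = numeric(), fdr_p = numeric(),
                      median_fd = numeric(), normal = logical(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  assays <- setdiff(colnames(ex), controlAssays(normalized))
  rows <- lapply(assays, function(a) {
    cs <- ex[caseIdx, a]; ct <- ex[ctrlIdx, a]
    fc <- foldChange(cs, ct)
    data.frame(assay_id = a, cohort = cohort,
               raw_p = deTest(cs, ct),
               median_fd = foldDifference(stats::median(fc)),
               normal = normalityGate(list(case = cs, control = ct)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bhAdjust(out$raw_p)
  out$direction <- ifelse(out$fdr_p < alpha,
                          ifelse(out$median_fd >= 1, "up", "down"), "ns")
  out <- out[order(out$fdr_p, out$raw_p, out$assay_id),
             c("assay_id", "cohort", "raw_p", "fdr_p", "median_fd",
               "normal", "direction")]
  rownames(out) <- NULL
  out
}
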