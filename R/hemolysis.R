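## Spectrophotometric hemolysis screening.
##
## Sample admission and classification use absorbance at 414 nm (hemoglobin
## Soret peak) with a 375 nm lipemia correction; per-assay verdicts combine a
## linear trend of Ct against 414 nm absorbance with a hemolyzed vs
## non-hemolyzed rank-sum test.

#' Sample admission by absorbance
#'
#' A sample is admitted when its 414 nm absorbance is below 1.5, or its
#' 414/375 ratio is below 1.4 (the lipemic rescue: lipid content elevates
#' 414 nm absorbance without indicating hemolysis).
#'
#' @param a414,a375 absorbance values (positive).
#' @param a414Max admission cut-off on the 414 nm absorbance (default 1.5).
#' @param ratioMax admission/classification cut-off on the 414/375 ratio
#'   (default 1.4).
#' @return logical vector of admissions.
#' @export
admitSample <- function(a414, a375, a414Max = 1.5, ratioMax = 1.4) {
  stopifnot(length(a414) == length(a375))
  if (any(is.na(a414) | is.na(a375) | a414 <= 0 | a375 <= 0))
    stopf("absorbance values must be positive and non-missing")
  a414 < a414Max | (a414 / a375) < ratioMax
}

#' Classify admitted samples for hemolysis
#'
#' \code{non_hemolyzed}: 414 nm absorbance at or below 0.2.
#' \code{hemolyzed}: above 0.2 with 414/375 ratio at or above 1.4.
#' \code{lipemic_non_hemolyzed}: above 0.2 but ratio below 1.4 — counted with
#' the non-hemolyzed group in the rank-sum comparison and excluded from the
#' Ct-versus-absorbance regression.
#'
#' @param a414,a375 absorbance values of admitted samples (positive).
#' @param hemoCut 414 nm cut-off above which a sample is hemolyzed
#'   (default 0.2).
#' @param a414Max,ratioMax admission thresholds, as in [admitSample()].
#' @return character vector of classes.
#' @export
classifyHemolysis <- function(a414, a375, hemoCut = 0.2, a414Max = 1.5,
                              ratioMax = 1.4) {
  admitted <- admitSample(a414, a375, a414Max, ratioMax)
  if (!all(admitted))
    stopf("classifyHemolysis() expects admitted samples; %d fail admission",
          sum(!admitted))
  ratio <- a414 / a375
  ifelse(a414 <= hemoCut, "non_hemolyzed",
         ifelse(ratio >= ratioMax, "hemolyzed", "lipemic_non_hemolyzed"))
}

#' Per-assay hemolysis association verdict
#'
#' Two lines of evidence per assay: (1) the coefficient of determination
#' (R^2) of an ordinary least-squares fit of Ct on 414 nm absorbance over the
#' regression set (lipemic samples excluded); (2) a two-sided rank-sum
#' p-value comparing Ct in hemolyzed versus non-hemolyzed (including lipemic)
#' samples. The verdict is \code{affected} when R^2 > 0.3 and p < 0.01,
#' \code{unaffected} when R^2 < 0.2 and p > 0.05, and \code{indeterminate}
#' otherwise (boundary values are indeterminate: the inequalities are
#' strict). With no hemolyzed samples the verdict is indeterminate with
#' reason \code{no_hemolyzed_samples}.
#'
#' @param ct numeric Ct values, one per sample.
#' @param a414 absorbance at 414 nm, aligned with \code{ct}.
#' @param status classes from [classifyHemolysis()], aligned with \code{ct}.
#' @param r2Hi,pLo thresholds for the \code{affected} call (defaults 0.3,
#'   0.01).
#' @param r2Lo,pHi thresholds for the \code{unaffected} call (defaults 0.2,
#'   0.05).
#' @return one-row data.frame: \code{r2}, \code{p}, \code{class},
#'   \code{reason}.
#' @export
mirnaHemolysisAssociation <- function(ct, a414, status, r2Hi = 0.3,
                                      pLo = 0.01, r2Lo = 0.2, pHi = 0.05) {
  stopifnot(length(ct) == length(a414), length(ct) == length(status))
  regSet <- status != "lipemic_non_hemolyzed"
  if (sum(regSet) < 3L)
    stopf("need at least 3 samples in the regression set")
  r2 <- if (stats::sd(ct[regSet]) == 0 || stats::sd(a414[regSet]) == 0) 0
        else stats::cor(ct[regSet], a414[regSet])^2
  hem <- status == "hemolyzed"
  if (!any(hem) || all(hem))
    return(data.frame(r2 = r2, p = NA_real_, class = "indeterminate",
                      reason = "no_hemolyzed_samples",
                      stringsAsFactors = FALSE))
  p <- rankSumP(ct[hem], ct[!hem])
  cls <- if (r2 > r2Hi && p < pLo) "affected"
         else if (r2 < r2Lo && p > pHi) "unaffected"
         else "indeterminate"
  data.frame(r2 = r2, p = p, class = cls, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Hemolysis screen over a Ct matrix
#'
#' Classifies every sample and issues a per-assay verdict via
#' [mirnaHemolysisAssociation()].
#'
#' @param matrix a [CtMatrix-class] (IPC-corrected, ceilinged).
#' @param samples sample metadata with \code{sample_id}, \code{a414},
#'   \code{a375}.
#' @param thresholds named list overriding any of \code{a414Max},
#'   \code{ratioMax}, \code{hemoCut}, \code{r2Hi}, \code{pLo},
#'   \code{r2Lo}, \code{pHi}.
#' @return list: \code{statuses} (data.frame \code{sample_id}, \code{a414},
#'   \code{a375}, \code{admitted}, \code{class}) and \code{verdicts}
#'   (data.frame \code{assay_id}, \code{r2}, \code{p}, \code{class},
#'   \code{reason}).
#' @export
hemolysisScreen <- function(matrix, samples, thresholds = list()) {
  stopifnot(is(matrix, "CtMatrix"))
  th <- list(a414Max = 1.5, ratioMax = 1.4, hemoCut = 0.2,
             r2Hi = 0.3, pLo = 0.01, r2Lo = 0.2, pHi = 0.05)
  th[names(thresholds)] <- thresholds
  ids <- rownames(ctValues(matrix))
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stopf("metadata missing for matrix sample(s)")
  admitted <- admitSample(samples$a414, samples$a375, th$a414Max, th$ratioMax)
  class <- rep(NA_character_, length(ids))
  class[admitted] <- classifyHemolysis(samples$a414[admitted],
                                       samples$a375[admitted], th$hemoCut,
                                       th$a414Max, th$ratioMax)
  statuses <- data.frame(sample_id = ids, a414 = samples$a414,
                         a375 = samples$a375, admitted = admitted,
                         class = class, stringsAsFactors = FALSE)
  use <- admitted
  ct <- ctValues(matrix)[use, , drop = FALSE]
  verdicts <- do.call(rbind, lapply(colnames(ct), function(a) {
    v <- mirnaHemolysisAssociation(ct[, a], samples$a414[use], class[use],
                                   th$r2Hi, th$pLo, th$r2Lo, th$pHi)
    cbind(data.frame(assay_id = a, stringsAsFactors = FALSE), v)
  }))
  rownames(verdicts) <- NULL
  list(statuses = statuses, verdicts = verdicts)
}
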