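## Endogenous-control selection, comparative-Ct normalization, and the
## fold-change / fold-difference arithmetic.

#' Select endogenous controls
#'
#' Candidates must be expressed in every sample (no Ct at the ceiling) and
#' must not be classed hemolysis-affected; indeterminate verdicts are
#' excluded unless explicitly whitelisted (the pool is padded with
#' whitelisted indeterminates when fewer than \code{minPool} candidates
#' remain, mirroring the practice of admitting a couple of assays with
#' non-definitive hemolysis relationships). Stability is then estimated with
#' [normFinderStability()]; the selected trio is the best pair plus the
#' candidate minimizing the trio's combined stability. A fourth control is
#' added only when it provides a significant reduction in variability: the
#' four-member combined stability must improve on the trio's, and the
#' pairwise-variation statistic
#' \eqn{V_3 = \mathrm{SD}_s(NF_3(s) - NF_4(s))} between the three- and
#' four-control normalization factors must exceed \code{vThreshold}
#' (otherwise the fourth leaves the factor essentially unchanged and is
#' unnecessary).
#'
#' @param matrix a ceilinged [CtMatrix-class] after QC.
#' @param groups group labels aligned with matrix rows (case/control by
#'   default in the pipeline).
#' @param verdicts per-assay hemolysis verdicts from [hemolysisScreen()].
#' @param whitelist assays whose indeterminate verdict is waived.
#' @param vThreshold pairwise-variation threshold for adding a fourth
#'   control (default 0.15, the conventional cut-off).
#' @param minPool preferred minimum candidate pool size (default 5).
#' @return a [ControlSet-class] with a replayable audit.
#' @export
selectControls <- function(matrix, groups, verdicts, whitelist = character(),
                           vThreshold = 0.15, minPool = 5L) {
  stopifnot(is(matrix, "CtMatrix"), !is.na(ctCeiling(matrix)))
  ct <- ctValues(matrix)
  assays <- colnames(ct)
  vclass <- stats::setNames(verdicts$class, verdicts$assay_id)[assays]

  expressedAll <- colSums(ct >= ctCeiling(matrix)) == 0L
  reason <- rep(NA_character_, length(assays))
  reason[!expressedAll] <- "not_expressed_in_all_samples"
  reason[is.na(reason) & vclass == "affected"] <- "hemolysis_affected"
  reason[is.na(reason) & vclass == "indeterminate" &
           !(assays %in% whitelist)] <- "hemolysis_indeterminate"
  eligible <- assays[is.na(reason)]
  exclusions <- data.frame(assay_id = assays[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)

  if (length(eligible) < 3L)
    stopf(paste0("fewer than 3 eligible control candidates (%d); exclusions: %s"),
          length(eligible),
          paste(sprintf("%s [%s]", exclusions$assay_id, exclusions$reason),
                collapse = "; "))
  if (length(eligible) < minPool)
    warnf("only %d eligible control candidates (recommended >= %d)",
          length(eligible), minPool)

  stab <- normFinderStability(ct[, eligible, drop = FALSE], groups,
                              ceiling = ctCeiling(matrix))
  pair <- bestPair(stab)
  rest <- setdiff(eligible, pair)
  trioRho <- vapply(rest, function(a) setStability(stab, c(pair, a)),
                    numeric(1))
  third <- rest[which.min(trioRho)]
  trio <- c(pair, third)

  selected <- trio
  v3 <- NA_real_
  addedFourth <- FALSE
  trioRhoSel <- setStability(stab, trio)
  quadRhoBest <- NA_real_
  rest4 <- setdiff(eligible, trio)
  if (length(rest4)) {
    quadRho <- vapply(rest4, function(a) setStability(stab, c(trio, a)),
                      numeric(1))
    fourth <- rest4[which.min(quadRho)]
    quadRhoBest <- min(quadRho)
    nf3 <- apply(ct[, trio, drop = FALSE], 1L, geomMean)
    nf4 <- apply(ct[, c(trio, fourth), drop = FALSE], 1L, geomMean)
    v3 <- stats::sd(nf3 - nf4)
    if (quadRhoBest < trioRhoSel && v3 > vThreshold) {
      selected <- c(trio, fourth)
      addedFourth <- TRUE
    }
  }

  new("ControlSet", assays = selected,
      audit = list(candidates = eligible, exclusions = exclusions,
                   stability = stabilityTable(stab), best_pair = pair,
                   trio_search = data.frame(assay_id = rest, rho = trioRho,
                                            row.names = NULL),
                   trio_rho = trioRhoSel, quad_rho = quadRhoBest,
                   v3 = v3, v_threshold = vThreshold,
                   added_fourth = addedFourth, whitelist = whitelist))
}

#' Comparative-Ct normalization
#'
#' Normalized expression \eqn{\Delta Ct^*(s,a) =
#' \mathrm{geomean}_{c}\, Ct(s,c) - Ct(s,a)} over the control assays, so
#' larger values mean higher abundance. The geometric average is applied
#' directly to the control Ct values and the whole sample set is normalized
#' in one pass. Control assays remain columns of the result but are excluded
#' from downstream testing and modeling by the pipeline.
#'
#' @param matrix a ceilinged [CtMatrix-class].
#' @param controls a [ControlSet-class] or character vector of control
#'   assays; every control must be expressed (below ceiling) in all samples.
#' @return a [NormalizedMatrix-class].
#' @export
normalizeCt <- function(matrix, controls) {
  stopifnot(is(matrix, "CtMatrix"))
  if (is(controls, "ControlSet")) controls <- controlsSelected(controls)
  ct <- ctValues(matrix)
  stopifnot(all(controls %in% colnames(ct)))
  if (!is.na(ctCeiling(matrix))) {
    bad <- controls[colSums(ct[, controls, drop = FALSE] >=
                              ctCeiling(matrix)) > 0L]
    if (length(bad))
      stopf("control assay(s) with ceiling values: %s",
            paste(bad, collapse = ", "))
  }
  nf <- apply(ct[, controls, drop = FALSE], 1L, geomMean)
  new("NormalizedMatrix", exprs = nf - ct, controlAssays = controls)
}

#' Fold change from normalized expression
#'
#' Per case sample, \eqn{FC = 2^{\Delta Ct^*_{case} -
#' \mathrm{median}(\Delta Ct^*_{control})}}; the reported per-miRNA statistic
#' is the median fold change over case samples.
#'
#' @param caseValues normalized expression of the case samples for one assay.
#' @param controlValues normalized expression of the control samples.
#' @return numeric vector of per-case fold changes.
#' @seealso [foldDifference()]
#' @export
foldChange <- function(caseValues, controlValues) {
  stopifnot(length(controlValues) >= 1L)
  2^(caseValues - stats::median(controlValues))
}

#' Fold difference (symmetric fold change)
#'
#' Equal to the fold change when it is at least 1, and to its negative
#' inverse otherwise, so downregulation reads as a negative fold and
#' \eqn{|FD| \ge 1} always.
#'
#' @param fc fold change(s).
#' @return fold difference(s).
#' @export
foldDifference <- function(fc) ifelse(fc >= 1, fc, -1 / fc)
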