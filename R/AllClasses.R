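#' @import methods
#' @importFrom stats median sd var quantile rnorm runif rbinom rexp pchisq
#'   pnorm qnorm wilcox.test shapiro.test p.adjust cor setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

## ---------------------------------------------------------------------------
## CtPlate: one PCR array (long format wells + NTC inter-plate calibrator)
## ---------------------------------------------------------------------------

#' Class "CtPlate": raw Ct values for one PCR array
#'
#' Holds the long-format well readings of a single RT-qPCR array together with
#' the no-template-control (NTC) replicates of the synthetic inter-plate
#' calibrator used to align plates.
#'
#' @slot plateId single character plate identifier.
#' @slot wells data.frame with columns \code{sample_id}, \code{assay_id},
#'   \code{ct} (cycles; \code{NA} when undetected) and \code{curve_ok}
#'   (logical amplification-curve review flag).
#' @slot ntcCalibrator numeric vector of calibrator Ct replicates
#'   (conventionally 6 per plate).
#'
#' @seealso [readPlates()], [ipcCorrect()]
#' @export
setClass("CtPlate",
  representation(plateId = "character", wells = "data.frame",
                 ntcCalibrator = "numeric"))

setValidity("CtPlate", function(object) {
  msg <- character()
  if (length(object@plateId) != 1L || is.na(object@plateId))
    msg <- c(msg, "plateId must be a single non-missing string")
  w <- object@wells
  need <- c("sample_id", "assay_id", "ct", "curve_ok")
  if (!all(need %in% names(w)))
    msg <- c(msg, paste("wells must have columns:", paste(need, collapse = ", ")))
  else {
    ct <- w$ct
    if (any(!is.na(ct) & (ct <= 0 | ct >= 50)))
      msg <- c(msg, "Ct values must lie in (0, 50) when present")
    key <- paste(w$sample_id, w$assay_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      msg <- c(msg, paste0("duplicated well (sample assay): ", dup))
    }
  }
  if (length(object@ntcCalibrator) < 1L || anyNA(object@ntcCalibrator))
    msg <- c(msg, "ntcCalibrator must be a non-empty numeric vector without NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn CtPlate plate identifier
#' @param object a \code{CtPlate}
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname CtPlate
#' @export
setMethod("plateId", "CtPlate", function(object) object@plateId)

#' @describeIn CtPlate well-level data.frame
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @rdname CtPlate
#' @export
setMethod("wells", "CtPlate", function(object) object@wells)

#' @describeIn CtPlate NTC calibrator replicates
#' @export
setGeneric("ntcCalibrator", function(object) standardGeneric("ntcCalibrator"))

#' @rdname CtPlate
#' @export
setMethod("ntcCalibrator", "CtPlate", function(object) object@ntcCalibrator)

setMethod("show", "CtPlate", function(object) {
  cat("CtPlate", object@plateId, "\n")
  cat("  wells:", nrow(object@wells), " (",
      length(unique(object@wells$sample_id)), "samples x",
      length(unique(object@wells$assay_id)), "assays )\n")
  cat("  NTC calibrator replicates:", length(object@ntcCalibrator),
      " mean =", round(mean(object@ntcCalibrator), 3), "\n")
})

## ---------------------------------------------------------------------------
## CtMatrix: samples x assays grid of (corrected) Ct values
## ---------------------------------------------------------------------------

#' Class "CtMatrix": samples-by-assays grid of Ct values
#'
#' Rows are samples, columns assays. Before [applyCeiling()] the matrix may
#' contain missing Ct values (undetected wells) and \code{ctCeiling()} is
#' \code{NA}; afterwards every undetected, above-ceiling, or curve-failed cell
#' is set to the ceiling exactly and flagged in \code{ceilingMask()}.
#'
#' @slot ct numeric matrix (samples x assays) of Ct values.
#' @slot curveOk logical matrix, same shape; amplification-curve review flag.
#' @slot ceilingMask logical matrix, same shape; TRUE where the cell was set
#'   to the ceiling.
#' @slot ceiling numeric(1); \code{NA} until the ceiling has been applied.
#'
#' @seealso [ipcCorrect()], [applyCeiling()]
#' @export
setClass("CtMatrix",
  representation(ct = "matrix", curveOk = "matrix", ceilingMask = "matrix",
                 ceiling = "numeric"))

setValidity("CtMatrix", function(object) {
  msg <- character()
  d <- dim(object@ct)
  if (!identical(dim(object@curveOk), d) || !identical(dim(object@ceilingMask), d))
    msg <- c(msg, "ct, curveOk and ceilingMask must share dimensions")
  if (is.null(rownames(object@ct)) || is.null(colnames(object@ct)))
    msg <- c(msg, "ct must have sample rownames and assay colnames")
  if (length(object@ceiling) != 1L)
    msg <- c(msg, "ceiling must be a single value (possibly NA)")
  else if (!is.na(object@ceiling)) {
    if (anyNA(object@ct))
      msg <- c(msg, "no missing Ct allowed once the ceiling is applied")
    else {
      if (any(object@ct > object@ceiling))
        msg <- c(msg, "all Ct values must be <= ceiling once applied")
      if (any(object@ct[object@ceilingMask] != object@ceiling))
        msg <- c(msg, "masked cells must equal the ceiling exactly")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CtMatrix the Ct value matrix (samples x assays)
#' @param object a \code{CtMatrix}
#' @export
setGeneric("ctValues", function(object) standardGeneric("ctValues"))

#' @rdname CtMatrix
#' @export
setMethod("ctValues", "CtMatrix", function(object) object@ct)

#' @describeIn CtMatrix logical mask of ceiling-imputed cells
#' @export
setGeneric("ceilingMask", function(object) standardGeneric("ceilingMask"))

#' @rdname CtMatrix
#' @export
setMethod("ceilingMask", "CtMatrix", function(object) object@ceilingMask)

#' @describeIn CtMatrix the Ct ceiling (NA before [applyCeiling()])
#' @export
setGeneric("ctCeiling", function(object) standardGeneric("ctCeiling"))

#' @rdname CtMatrix
#' @export
setMethod("ctCeiling", "CtMatrix", function(object) object@ceiling)

setMethod("show", "CtMatrix", function(object) {
  cat("CtMatrix:", nrow(object@ct), "samples x", ncol(object@ct), "assays\n")
  if (is.na(object@ceiling)) {
    cat("  ceiling: not applied;", sum(is.na(object@ct)), "undetected cells\n")
  } else {
    cat("  ceiling:", format(object@ceiling), "(",
        sum(object@ceilingMask), "cells at ceiling )\n")
  }
})

#' @export
setMethod("dim", "CtMatrix", function(x) dim(x@ct))

## ---------------------------------------------------------------------------
## QcReport
## ---------------------------------------------------------------------------

#' Class "QcReport": plate-calibration offsets and exclusion audit
#'
#' @slot plateOffsets named numeric; per-plate calibrator offset (Ct units)
#'   subtracted from every well of that plate.
#' @slot excludedSamples data.frame with columns \code{sample_id},
#'   \code{reason} (single primary machine-readable reason code per entry).
#' @slot excludedAssays data.frame with columns \code{assay_id}, \code{reason}.
#'
#' @export
setClass("QcReport",
  representation(plateOffsets = "numeric", excludedSamples = "data.frame",
                 excludedAssays = "data.frame"))

setValidity("QcReport", function(object) {
  msg <- character()
  if (length(object@plateOffsets) && is.null(names(object@plateOffsets)))
    msg <- c(msg, "plateOffsets must be named by plate")
  for (nm in c("excludedSamples", "excludedAssays")) {
    df <- slot(object, nm)
    idcol <- if (nm == "excludedSamples") "sample_id" else "assay_id"
    if (!all(c(idcol, "reason") %in% names(df)))
      msg <- c(msg, paste0(nm, " needs columns ", idcol, ", reason"))
    else if (nrow(df) && any(!nzchar(df$reason) | is.na(df$reason)))
      msg <- c(msg, paste0(nm, ": every exclusion needs one reason code"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn QcReport per-plate calibration offsets
#' @param object a \code{QcReport}
#' @export
setGeneric("plateOffsets", function(object) standardGeneric("plateOffsets"))

#' @rdname QcReport
#' @export
setMethod("plateOffsets", "QcReport", function(object) object@plateOffsets)

#' @describeIn QcReport excluded samples with reasons
#' @export
setGeneric("excludedSamples", function(object) standardGeneric("excludedSamples"))

#' @rdname QcReport
#' @export
setMethod("excludedSamples", "QcReport", function(object) object@excludedSamples)

#' @describeIn QcReport excluded assays with reasons
#' @export
setGeneric("excludedAssays", function(object) standardGeneric("excludedAssays"))

#' @rdname QcReport
#' @export
setMethod("excludedAssays", "QcReport", function(object) object@excludedAssays)

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n  plate offsets (Ct):",
      paste(sprintf("%s=%+.3f", names(object@plateOffsets), object@plateOffsets),
            collapse = ", "), "\n")
  cat("  excluded samples:", nrow(object@excludedSamples),
      " excluded assays:", nrow(object@excludedAssays), "\n")
})

## ---------------------------------------------------------------------------
## NormalizedMatrix
## ---------------------------------------------------------------------------

#' Class "NormalizedMatrix": control-normalized expression
#'
#' Normalized expression on the comparative-Ct scale:
#' \eqn{\Delta Ct^*(s,a) = \mathrm{geomean}_c Ct(s,c) - Ct(s,a)} over the
#' endogenous controls \eqn{c}, so larger values mean more abundant miRNA.
#'
#' @slot exprs numeric matrix (samples x assays) of normalized expression.
#' @slot controlAssays character; the endogenous-control assays used
#'   (excluded from downstream differential expression and modeling).
#'
#' @seealso [normalizeCt()], [selectControls()]
#' @export
setClass("NormalizedMatrix",
  representation(exprs = "matrix", controlAssays = "character"))

setValidity("NormalizedMatrix", function(object) {
  msg <- character()
  if (is.null(rownames(object@exprs)) || is.null(colnames(object@exprs)))
    msg <- c(msg, "exprs must have sample rownames and assay colnames")
  if (anyNA(object@exprs))
    msg <- c(msg, "normalized expression must not contain NA")
  if (length(object@controlAssays) < 1L)
    msg <- c(msg, "at least one control assay required")
  if (length(msg)) msg else TRUE
})

#' @describeIn NormalizedMatrix the normalized expression matrix
#' @param object a \code{NormalizedMatrix}
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname NormalizedMatrix
#' @export
setMethod("exprValues", "NormalizedMatrix", function(object) object@exprs)

#' @describeIn NormalizedMatrix the endogenous controls used
#' @export
setGeneric("controlAssays", function(object) standardGeneric("controlAssays"))

#' @rdname NormalizedMatrix
#' @export
setMethod("controlAssays", "NormalizedMatrix", function(object) object@controlAssays)

setMethod("show", "NormalizedMatrix", function(object) {
  cat("NormalizedMatrix:", nrow(object@exprs), "samples x",
      ncol(object@exprs), "assays\n")
  cat("  controls:", paste(object@controlAssays, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## StabilityResult / ControlSet
## ---------------------------------------------------------------------------

#' Class "StabilityResult": model-based control-gene stability estimates
#'
#' Output of [normFinderStability()]: per-candidate stability values (lower =
#' more stable) from the variance-decomposition model, with the intra-group
#' variance and inter-group difference components that compose them, and the
#' best candidate pair under the combined (averaged) stability.
#'
#' @slot stability data.frame with columns \code{assay_id}, \code{rho},
#'   \code{intra_var} (average within-group variance component) and
#'   \code{inter_diff} (average absolute shrunken group difference), sorted
#'   ascending by \code{rho}.
#' @slot dStar numeric matrix (candidates x groups) of shrunken group biases.
#' @slot dVar numeric matrix (candidates x groups) of posterior bias variances.
#' @slot bestPair character(2); the pair minimizing combined stability.
#' @slot groups character; group levels used.
#' @export
setClass("StabilityResult",
  representation(stability = "data.frame", dStar = "matrix", dVar = "matrix",
                 bestPair = "character", groups = "character"))

setValidity("StabilityResult", function(object) {
  msg <- character()
  st <- object@stability
  if (!all(c("assay_id", "rho", "intra_var", "inter_diff") %in% names(st)))
    msg <- c(msg, "stability needs columns assay_id, rho, intra_var, inter_diff")
  else {
    if (any(st$rho < 0)) msg <- c(msg, "stability values must be >= 0")
    if (is.unsorted(st$rho)) msg <- c(msg, "stability must be sorted ascending by rho")
  }
  if (length(object@bestPair) != 2L)
    msg <- c(msg, "bestPair must have exactly two members")
  if (length(msg)) msg else TRUE
})

#' @describeIn StabilityResult the ranked stability table
#' @param object a \code{StabilityResult}
#' @export
setGeneric("stabilityTable", function(object) standardGeneric("stabilityTable"))

#' @rdname StabilityResult
#' @export
setMethod("stabilityTable", "StabilityResult", function(object) object@stability)

#' @describeIn StabilityResult the best candidate pair
#' @export
setGeneric("bestPair", function(object) standardGeneric("bestPair"))

#' @rdname StabilityResult
#' @export
setMethod("bestPair", "StabilityResult", function(object) object@bestPair)

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult (", nrow(object@stability), "candidates,",
      length(object@groups), "groups )\n")
  print(head(object@stability, 5), row.names = FALSE)
  cat("  best pair:", paste(object@bestPair, collapse = " + "), "\n")
})

#' Class "ControlSet": selected endogenous controls with audit trail
#'
#' @slot assays character; the selected control assays (minimum three).
#' @slot audit list recording candidates considered, exclusions with reasons,
#'   the ranked stability table, the best pair, the trio search, and the
#'   pairwise-variation test for a fourth control, so the selection can be
#'   replayed.
#' @export
setClass("ControlSet",
  representation(assays = "character", audit = "list"))

setValidity("ControlSet", function(object) {
  if (length(object@assays) < 3L)
    "a control set requires at least three assays" else TRUE
})

#' @describeIn ControlSet the selected control assays
#' @param object a \code{ControlSet}
#' @export
setGeneric("controlsSelected", function(object) standardGeneric("controlsSelected"))

#' @rdname ControlSet
#' @export
setMethod("controlsSelected", "ControlSet", function(object) object@assays)

#' @describeIn ControlSet the selection audit trail
#' @export
setGeneric("selectionAudit", function(object) standardGeneric("selectionAudit"))

#' @rdname ControlSet
#' @export
setMethod("selectionAudit", "ControlSet", function(object) object@audit)

setMethod("show", "ControlSet", function(object) {
  cat("ControlSet:", paste(object@assays, collapse = ", "), "\n")
  if (!is.null(object@audit$v3))
    cat("  pairwise variation V3 =", round(object@audit$v3, 4),
        if (isTRUE(object@audit$added_fourth)) "(fourth control added)"
        else "(three controls sufficient)", "\n")
})

## ---------------------------------------------------------------------------
## DecisionTree
## ---------------------------------------------------------------------------

#' Class "DecisionTree": binary recursive-partitioning model
#'
#' A flat node-table representation of a CART-style tree. Classification
#' trees split on Gini impurity; survival trees on exponential-model deviance
#' (each node fits an event rate \eqn{\lambda =} events / total exposure and
#' leaves report the rate ratio against the root).
#'
#' Node table columns: \code{id}, \code{parent}, \code{left}, \code{right}
#' (child ids, \code{NA} for leaves), \code{var}, \code{threshold} (split:
#' left branch takes \code{x < threshold}), \code{depth}, \code{n}, plus
#' type-specific statistics (classification: \code{n_pos}, \code{n_neg},
#' \code{pred}, \code{prob_pos}, \code{risk}; survival: \code{events},
#' \code{exposure}, \code{rate}, \code{rate_ratio}, \code{risk}) and
#' \code{improve}, the split's impurity/deviance reduction.
#'
#' @slot type "classification" or "survival".
#' @slot nodes data.frame as described above.
#' @slot params list of growth parameters (minsplit, minbucket, cp, ...).
#' @slot pruneTrace data.frame; cost-complexity path with cross-validation
#'   errors (empty until [crossvalPrune()]).
#'
#' @seealso [growClassificationTree()], [growSurvivalTree()], [crossvalPrune()]
#' @export
setClass("DecisionTree",
  representation(type = "character", nodes = "data.frame", params = "list",
                 pruneTrace = "data.frame"))

setValidity("DecisionTree", function(object) {
  msg <- character()
  if (!object@type %in% c("classification", "survival"))
    msg <- c(msg, "type must be 'classification' or 'survival'")
  nd <- object@nodes
  base <- c("id", "parent", "left", "right", "var", "threshold", "depth", "n")
  if (!all(base %in% names(nd)))
    msg <- c(msg, paste("nodes must include columns:", paste(base, collapse = ", ")))
  else {
    leaves <- is.na(nd$left)
    if (!any(leaves)) msg <- c(msg, "tree must have at least one leaf")
    if (nd$id[1] != 1L) msg <- c(msg, "root must have id 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DecisionTree the flat node table
#' @param object a \code{DecisionTree}
#' @export
setGeneric("treeNodes", function(object) standardGeneric("treeNodes"))

#' @rdname DecisionTree
#' @export
setMethod("treeNodes", "DecisionTree", function(object) object@nodes)

#' @describeIn DecisionTree tree type ("classification"/"survival")
#' @export
setGeneric("treeType", function(object) standardGeneric("treeType"))

#' @rdname DecisionTree
#' @export
setMethod("treeType", "DecisionTree", function(object) object@type)

#' @describeIn DecisionTree the cost-complexity / cross-validation trace
#' @export
setGeneric("pruneTrace", function(object) standardGeneric("pruneTrace"))

#' @rdname DecisionTree
#' @export
setMethod("pruneTrace", "DecisionTree", function(object) object@pruneTrace)

#' Number of leaves of a tree
#' @param object a \code{DecisionTree}
#' @export
setGeneric("nLeaves", function(object) standardGeneric("nLeaves"))

#' @rdname nLeaves
#' @export
setMethod("nLeaves", "DecisionTree", function(object) sum(is.na(object@nodes$left)))

setMethod("show", "DecisionTree", function(object) {
  cat("DecisionTree (", object@type, "):", nrow(object@nodes), "nodes,",
      nLeaves(object), "leaves\n")
  cat(describeTree(object), sep = "\n")
})
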