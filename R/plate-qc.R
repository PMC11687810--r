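## Plate reading, inter-plate calibration, Ct ceiling, and the sample- and
## assay-level quality filters.
##
## Filter conventions: all filter statistics (means/SDs) are computed once on
## the full input set before any exclusion (single pass, order independent);
## SD = 0 or n = 1 passes everything; "expressed"/"detected" means Ct strictly
## below the ceiling after correction.

missingCtTokens <- c("", "Undetermined", "NA", ">35", "undetermined")

parseCt <- function(x, file) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  known <- x %in% missingCtTokens
  num <- suppressWarnings(as.numeric(x))
  bad <- !known & is.na(num)
  if (any(bad))
    stopf("malformed Ct value '%s' in %s (row %d)",
          x[bad][1L], file, which(bad)[1L])
  out[!known] <- num[!known]
  out
}

#' Read long-format plate export CSVs
#'
#' Each file must carry columns \code{plate_id}, \code{sample_id},
#' \code{assay_id}, \code{ct}; optional \code{curve_ok} (defaults to TRUE:
#' curve review is a manual step and this flag is its hook) and
#' \code{is_ntc_calibrator} marking the inter-plate calibrator NTC replicate
#' rows. Missing-Ct tokens accepted: empty field, \code{Undetermined},
#' \code{NA}, \code{>35}. Unknown columns are ignored with a warning;
#' duplicated sample/assay wells are an error.
#'
#' @param paths character vector of CSV paths.
#' @return list of [CtPlate-class] objects.
#' @export
readPlates <- function(paths) {
  lapply(paths, function(path) {
    if (!file.exists(path)) stopf("plate file not found: %s", path)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("plate_id", "sample_id", "assay_id", "ct")
    if (!all(need %in% names(raw)))
      stopf("%s: missing required columns %s", path,
            paste(setdiff(need, names(raw)), collapse = ", "))
    known <- c(need, "curve_ok", "is_ntc_calibrator")
    extra <- setdiff(names(raw), known)
    if (length(extra))
      warnf("%s: ignoring unknown columns %s", path,
            paste(extra, collapse = ", "))
    pid <- unique(raw$plate_id)
    if (length(pid) != 1L)
      stopf("%s: expected a single plate_id, found %d", path, length(pid))
    ct <- parseCt(raw$ct, path)
    curveOk <- if ("curve_ok" %in% names(raw))
      toupper(trimws(raw$curve_ok)) != "FALSE" else rep(TRUE, nrow(raw))
    isNtc <- if ("is_ntc_calibrator" %in% names(raw))
      toupper(trimws(raw$is_ntc_calibrator)) == "TRUE" else rep(FALSE, nrow(raw))

    w <- data.frame(sample_id = raw$sample_id[!isNtc],
                    assay_id = raw$assay_id[!isNtc],
                    ct = ct[!isNtc], curve_ok = curveOk[!isNtc],
                    stringsAsFactors = FALSE)
    key <- paste(w$sample_id, w$assay_id)
    if (anyDuplicated(key))
      stopf("%s: duplicated well for sample/assay '%s'", path,
            key[duplicated(key)][1L])
    ntc <- ct[isNtc]
    if (length(ntc) == 0L || anyNA(ntc))
      stopf("%s: plate has no usable NTC calibrator replicates", path)
    rownames(w) <- NULL
    new("CtPlate", plateId = pid, wells = w, ntcCalibrator = ntc)
  })
}

#' Read the per-sample metadata CSV
#'
#' Expected columns mirror the generator output: identity
#' (\code{sample_id}, \code{cohort}, \code{group}), absorbances (\code{a414},
#' \code{a375}), spike-in Cts (\code{spike_iso}, \code{spike_rt}), clinical
#' covariates (\code{age}, \code{sex}, \code{weight}, \code{location},
#' \code{alp}) and survival endpoints (\code{os_time}, \code{os_event},
#' \code{dfi_time}, \code{dfi_event}). Blank fields become \code{NA}.
#'
#' @param path CSV path.
#' @return data.frame of sample records.
#' @export
readSamples <- function(path) {
  if (!file.exists(path)) stopf("sample file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "cohort", "group", "a414", "a375",
            "spike_iso", "spike_rt")
  if (!all(need %in% names(raw)))
    stopf("%s: missing required columns %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  numCol <- function(nm) {
    if (!nm %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- trimws(raw[[nm]])
    out <- suppressWarnings(as.numeric(x))
    bad <- !(x == "" | x == "NA") & is.na(out)
    if (any(bad))
      stopf("%s: malformed numeric '%s' in column %s (row %d)",
            path, x[bad][1L], nm, which(bad)[1L])
    out
  }
  chrCol <- function(nm) {
    if (!nm %in% names(raw)) return(rep(NA_character_, nrow(raw)))
    x <- trimws(raw[[nm]]); x[x == ""] <- NA_character_; x
  }
  if (anyDuplicated(raw$sample_id))
    stopf("%s: duplicated sample_id '%s'", path,
          raw$sample_id[duplicated(raw$sample_id)][1L])
  data.frame(
    sample_id = raw$sample_id, cohort = chrCol("cohort"),
    group = chrCol("group"),
    a414 = numCol("a414"), a375 = numCol("a375"),
    spike_iso = numCol("spike_iso"), spike_rt = numCol("spike_rt"),
    age = numCol("age"), sex = chrCol("sex"), weight = numCol("weight"),
    location = chrCol("location"), alp = chrCol("alp"),
    os_time = numCol("os_time"), os_event = numCol("os_event"),
    dfi_time = numCol("dfi_time"), dfi_event = numCol("dfi_event"),
    stringsAsFactors = FALSE)
}

#' Inter-plate calibration
#'
#' The per-plate offset is the mean calibrator Ct of that plate minus the
#' grand mean of the per-plate calibrator means; every well's Ct is then
#' reduced by its plate's offset, after which all per-plate calibrator means
#' coincide with the grand mean. Missing Ct values are preserved.
#'
#' @param plates list of [CtPlate-class]; each sample must appear on exactly
#'   one plate.
#' @return list with \code{matrix} (a raw, un-ceilinged [CtMatrix-class]) and
#'   \code{report} (a [QcReport-class] carrying the offsets).
#' @export
ipcCorrect <- function(plates) {
  stopifnot(length(plates) >= 1L)
  ntcMeans <- vapply(plates, function(p) {
    if (length(ntcCalibrator(p)) < 1L)
      stopf("plate %s has no calibrator wells", plateId(p))
    mean(ntcCalibrator(p))
  }, numeric(1))
  names(ntcMeans) <- vapply(plates, plateId, character(1))
  offsets <- ntcMeans - mean(ntcMeans)

  allWells <- do.call(rbind, lapply(plates, function(p) {
    w <- wells(p); w$plate_id <- plateId(p); w
  }))
  dupSample <- tapply(allWells$plate_id, allWells$sample_id,
                      function(p) length(unique(p)))
  if (any(dupSample > 1L))
    stopf("sample '%s' appears on more than one plate",
          names(dupSample)[dupSample > 1L][1L])

  sampleIds <- unique(allWells$sample_id)
  assayIds <- unique(allWells$assay_id)
  ct <- matrix(NA_real_, length(sampleIds), length(assayIds),
               dimnames = list(sampleIds, assayIds))
  curveOk <- matrix(TRUE, length(sampleIds), length(assayIds),
                    dimnames = list(sampleIds, assayIds))
  idx <- cbind(match(allWells$sample_id, sampleIds),
               match(allWells$assay_id, assayIds))
  ct[idx] <- allWells$ct - offsets[allWells$plate_id]
  curveOk[idx] <- allWells$curve_ok

  mat <- new("CtMatrix", ct = ct, curveOk = curveOk,
             ceilingMask = matrix(FALSE, nrow(ct), ncol(ct),
                                  dimnames = dimnames(ct)),
             ceiling = NA_real_)
  report <- new("QcReport", plateOffsets = offsets,
                excludedSamples = data.frame(sample_id = character(),
                                             reason = character()),
                excludedAssays = data.frame(assay_id = character(),
                                            reason = character()))
  list(matrix = mat, report = report)
}

#' Apply the Ct ceiling
#'
#' Undetected (missing) Cts, values above the ceiling, and wells whose
#' amplification curve failed review are all set to exactly the ceiling and
#' flagged in the ceiling mask, giving a conservative baseline for
#' fold-change assessment.
#'
#' @param matrix a [CtMatrix-class] (typically IPC-corrected).
#' @param ceiling Ct cut-off (default 35.00).
#' @return the ceilinged [CtMatrix-class].
#' @export
applyCeiling <- function(matrix, ceiling = 35.00) {
  stopifnot(is(matrix, "CtMatrix"), length(ceiling) == 1L, ceiling > 0)
  ct <- ctValues(matrix)
  mask <- is.na(ct) | ct > ceiling | !matrix@curveOk
  ct[mask] <- ceiling
  new("CtMatrix", ct = ct, curveOk = matrix@curveOk,
      ceilingMask = mask | ceilingMask(matrix), ceiling = ceiling)
}

#' Spike-in efficiency filter
#'
#' A sample passes when both its isolation and reverse-transcription spike-in
#' Cts lie within mean +/- 2 SD of that spike-in across all samples (mean and
#' SD computed once on the full input set). Zero SD (all values identical) or
#' a single sample gives no evidence of deviation, so everything passes.
#' Missing spike-ins fail with reason \code{missing_spike}.
#'
#' @param samples sample metadata data.frame with \code{spike_iso},
#'   \code{spike_rt}.
#' @param nSd multiplier for the SD envelope (default 2).
#' @return data.frame \code{sample_id}, \code{pass}, \code{reason}.
#' @export
spikeInFilter <- function(samples, nSd = 2) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "spike_iso", "spike_rt") %in% names(samples)))
  inEnvelope <- function(x) {
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(TRUE, length(x)) & !is.na(x))
    !is.na(x) & abs(x - m) <= nSd * s
  }
  missing <- is.na(samples$spike_iso) | is.na(samples$spike_rt)
  ok <- inEnvelope(samples$spike_iso) & inEnvelope(samples$spike_rt) & !missing
  reason <- rep(NA_character_, nrow(samples))
  reason[!ok] <- "spike_out_of_range"
  reason[missing] <- "missing_spike"
  data.frame(sample_id = samples$sample_id, pass = ok, reason = reason,
             stringsAsFactors = FALSE)
}

#' Sample-level detection filter
#'
#' Per sample, the detection count is the number of assays with Ct strictly
#' below the ceiling. A sample passes when its count is at least the mean
#' count minus 2 SD (one-sided; computed once over all samples). Detection
#' count, rather than mean Ct, is used as the notion of "overall expression",
#' mirroring the assay-level filter.
#'
#' @param matrix a ceilinged [CtMatrix-class].
#' @param nSd SD multiplier (default 2).
#' @return data.frame \code{sample_id}, \code{detected}, \code{pass},
#'   \code{reason}.
#' @export
sampleDetectionFilter <- function(matrix, nSd = 2) {
  stopifnot(is(matrix, "CtMatrix"), !is.na(ctCeiling(matrix)))
  detected <- rowSums(ctValues(matrix) < ctCeiling(matrix))
  s <- stats::sd(detected)
  pass <- if (is.na(s) || s == 0) rep(TRUE, length(detected))
          else detected >= mean(detected) - nSd * s
  data.frame(sample_id = rownames(ctValues(matrix)), detected = detected,
             pass = pass,
             reason = ifelse(pass, NA_character_, "low_detection"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assay prevalence filter
#'
#' Per assay, prevalence is the number of samples expressing it (Ct strictly
#' below the ceiling). Assays with prevalence strictly below the mean
#' prevalence minus 2 SD (over assays) are dropped. With a single assay or
#' zero SD nothing is dropped.
#'
#' @param matrix a ceilinged [CtMatrix-class].
#' @param nSd SD multiplier (default 2).
#' @return data.frame \code{assay_id}, \code{prevalence}, \code{keep},
#'   \code{reason}.
#' @export
assayPrevalenceFilter <- function(matrix, nSd = 2) {
  stopifnot(is(matrix, "CtMatrix"), !is.na(ctCeiling(matrix)))
  prevalence <- colSums(ctValues(matrix) < ctCeiling(matrix))
  s <- stats::sd(prevalence)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(prevalence))
          else prevalence >= mean(prevalence) - nSd * s
  data.frame(assay_id = colnames(ctValues(matrix)), prevalence = prevalence,
             keep = keep,
             reason = ifelse(keep, NA_character_, "low_prevalence"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the complete plate QC stage
#'
#' Inter-plate calibration, Ct ceiling, spike-in filter, sample detection
#' filter and assay prevalence filter, in that order, each computed on the
#' full input set before any exclusion. Returns the filtered matrix and the
#' full audit.
#'
#' @param plates list of [CtPlate-class].
#' @param samples sample metadata data.frame.
#' @param ceiling Ct cut-off (default 35.00).
#' @param nSd SD multiplier shared by the filters (default 2).
#' @return list: \code{matrix} (filtered ceilinged [CtMatrix-class]),
#'   \code{report} ([QcReport-class]), \code{samples} (metadata restricted to
#'   passing samples).
#' @export
plateQc <- function(plates, samples, ceiling = 35.00, nSd = 2) {
  ipc <- ipcCorrect(plates)
  mat <- applyCeiling(ipc$matrix, ceiling)
  matIds <- rownames(ctValues(mat))
  if (!all(matIds %in% samples$sample_id))
    stopf("metadata missing for sample(s): %s",
          paste(head(setdiff(matIds, samples$sample_id), 3), collapse = ", "))
  samples <- samples[match(matIds, samples$sample_id), , drop = FALSE]

  spike <- spikeInFilter(samples, nSd)
  detect <- sampleDetectionFilter(mat, nSd)
  prev <- assayPrevalenceFilter(mat, nSd)

  exS <- rbind(
    data.frame(sample_id = spike$sample_id[!spike$pass],
               reason = spike$reason[!spike$pass]),
    data.frame(sample_id = detect$sample_id[!detect$pass & spike$pass],
               reason = detect$reason[!detect$pass & spike$pass]))
  exA <- data.frame(assay_id = prev$assay_id[!prev$keep],
                    reason = prev$reason[!prev$keep])

  keepS <- setdiff(matIds, exS$sample_id)
  keepA <- prev$assay_id[prev$keep]
  filtered <- new("CtMatrix",
                  ct = ctValues(mat)[keepS, keepA, drop = FALSE],
                  curveOk = mat@curveOk[keepS, keepA, drop = FALSE],
                  ceilingMask = ceilingMask(mat)[keepS, keepA, drop = FALSE],
                  ceiling = ctCeiling(mat))
  report <- new("QcReport", plateOffsets = plateOffsets(ipc$report),
                excludedSamples = exS, excludedAssays = exA)
  list(matrix = filtered, report = report,
       samples = samples[samples$sample_id %in% keepS, , drop = FALSE])
}

#' Serialize a QcReport to JSON
#' @param report a [QcReport-class].
#' @param path optional output path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
qcReportJson <- function(report, path = NULL) {
  obj <- list(plate_offsets = as.list(plateOffsets(report)),
              excluded_samples = excludedSamples(report),
              excluded_assays = excludedAssays(report))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
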