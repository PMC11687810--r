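## End-to-end orchestration: each stage consumes the previous stage's CSV /
## JSON artifacts inside a run directory and is independently invokable, so
## the pipeline can be driven as a whole or stage by stage (also from the
## thin command-line script shipped in inst/scripts).

pipelineStages <- c("simulate", "qc", "hemolysis", "normalize", "de",
                    "survival", "trees", "report")

#' Configure a pipeline run
#'
#' All analysis constants are surfaced here with their conventional
#' defaults so sensitivity analyses are one-line changes. The configuration
#' is validated before any stage executes.
#'
#' @param outDir run directory for all stage artifacts.
#' @param inputDir directory with plate CSVs (\code{plate*.csv}) and
#'   \code{samples.csv}; when NULL the simulate stage generates them from
#'   \code{cohort}.
#' @param cohort a [CohortConfig-class] for the simulate stage.
#' @param ceiling Ct cut-off (default 35.00).
#' @param nSd SD multiplier of the QC filters (default 2).
#' @param hemolysis named list of hemolysis thresholds (see
#'   [hemolysisScreen()]).
#' @param whitelist indeterminate-verdict assays admissible as control
#'   candidates.
#' @param vThreshold pairwise-variation threshold for a fourth control.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param minprop minimum group proportion for expression cutpoints.
#' @param horizons named fixed survival horizons in days.
#' @param tree list of tree growth parameters (minsplit, minbucket, cp, k).
#' @param trainControlFrac fraction of controls assigned to the diagnostic
#'   training set (remaining controls join the held-out test cohort).
#' @param seed master seed; every stochastic step derives a named sub-seed
#'   from it.
#' @return validated config (list of class \code{plasmirConfig}).
#' @export
pipelineConfig <- function(outDir,
                           inputDir = NULL,
                           cohort = cohortConfig(),
                           ceiling = 35.00,
                           nSd = 2,
                           hemolysis = list(),
                           whitelist = c("hsa-let-7c-5p", "cfa-miR-140"),
                           vThreshold = 0.15,
                           alpha = 0.05,
                           minprop = 0.2,
                           horizons = c(m6 = 183, y1 = 365, y2 = 730),
                           tree = list(),
                           trainControlFrac = 0.8,
                           seed = 1L) {
  treeDefaults <- list(minsplit = 20L, minbucket = 7L, cp = 0.01, k = 10L)
  treeDefaults[names(tree)] <- tree
  cfg <- list(outDir = outDir, inputDir = inputDir, cohort = cohort,
              ceiling = ceiling, nSd = nSd, hemolysis = hemolysis,
              whitelist = whitelist, vThreshold = vThreshold, alpha = alpha,
              minprop = minprop, horizons = horizons, tree = treeDefaults,
              trainControlFrac = trainControlFrac, seed = as.integer(seed))
  class(cfg) <- "plasmirConfig"
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (cfg$ceiling <= 0) stopf("config: ceiling must be positive")
  if (cfg$nSd <= 0) stopf("config: nSd must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("config: alpha must be in (0,1)")
  if (cfg$minprop <= 0 || cfg$minprop >= 0.5)
    stopf("config: minprop must lie in (0, 0.5)")
  if (any(cfg$horizons <= 0)) stopf("config: horizons must be positive")
  if (cfg$trainControlFrac <= 0 || cfg$trainControlFrac >= 1)
    stopf("config: trainControlFrac must lie in (0,1)")
  if (cfg$vThreshold <= 0) stopf("config: vThreshold must be positive")
  invisible(cfg)
}

stagePath <- function(cfg, ...) file.path(cfg$outDir, ...)

requireArtifact <- function(path, producedBy) {
  if (!file.exists(path))
    stopf("missing artifact '%s'; run the '%s' stage first",
          path, producedBy)
  path
}

logMsg <- function(cfg, ...) {
  line <- paste0(...)
  message("[plasmiR] ", line)
  cat(line, "\n", file = stagePath(cfg, "pipeline.log"), append = TRUE)
}

writeMatrixCsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

readMatrixCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

## ---------------------------------------------------------------------------
## Stages
## ---------------------------------------------------------------------------

stageSimulate <- function(cfg) {
  cohort <- cfg$cohort
  cohort@seed <- as.numeric(spawnSeeds(cfg$seed, 1L))
  res <- generateCohort(cohort)
  inDir <- stagePath(cfg, "input")
  writeFixture(res$plates, res$samples, inDir)
  jsonlite::write_json(
    res$truth[c("effects", "hemolysisCoupled", "survivalLinks",
                "lowPrevalenceAssays", "controlCandidates")],
    stagePath(cfg, "truth.json"), auto_unbox = TRUE, digits = NA)
  logMsg(cfg, "simulate: ", nrow(res$samples), " samples on ",
         length(res$plates), " plates")
  invisible(res)
}

inputFiles <- function(cfg) {
  dir <- cfg$inputDir %||% stagePath(cfg, "input")
  plates <- sort(list.files(dir, pattern = "^plate.*\\.csv$",
                            full.names = TRUE))
  if (!length(plates))
    stopf("no plate CSVs under '%s'; run the 'simulate' stage or point inputDir at plate exports", dir)
  list(plates = plates,
       samples = requireArtifact(file.path(dir, "samples.csv"), "simulate"))
}

stageQc <- function(cfg) {
  fin <- inputFiles(cfg)
  plates <- readPlates(fin$plates)
  samples <- readSamples(fin$samples)
  qc <- plateQc(plates, samples, ceiling = cfg$ceiling, nSd = cfg$nSd)
  writeMatrixCsv(ctValues(qc$matrix), stagePath(cfg, "ct_matrix.csv"))
  qcReportJson(qc$report, stagePath(cfg, "qc_report.json"))
  utils::write.csv(qc$samples, stagePath(cfg, "samples_qc.csv"),
                   row.names = FALSE, quote = FALSE)
  logMsg(cfg, "qc: kept ", nrow(ctValues(qc$matrix)), " samples x ",
         ncol(ctValues(qc$matrix)), " assays; excluded ",
         nrow(excludedSamples(qc$report)), " samples, ",
         nrow(excludedAssays(qc$report)), " assays")
  invisible(qc)
}

loadQc <- function(cfg) {
  ct <- readMatrixCsv(requireArtifact(stagePath(cfg, "ct_matrix.csv"), "qc"))
  samples <- utils::read.csv(
    requireArtifact(stagePath(cfg, "samples_qc.csv"), "qc"),
    stringsAsFactors = FALSE)
  mat <- new("CtMatrix", ct = ct,
             curveOk = matrix(TRUE, nrow(ct), ncol(ct), dimnames = dimnames(ct)),
             ceilingMask = ct >= cfg$ceiling, ceiling = cfg$ceiling)
  list(matrix = mat, samples = samples)
}

stageHemolysis <- function(cfg) {
  qc <- loadQc(cfg)
  hs <- hemolysisScreen(qc$matrix, qc$samples, thresholds = cfg$hemolysis)
  utils::write.csv(hs$statuses, stagePath(cfg, "hemolysis_statuses.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(hs$verdicts, stagePath(cfg, "hemolysis_verdicts.csv"),
                   row.names = FALSE, quote = FALSE)
  logMsg(cfg, "hemolysis: ",
         sum(hs$verdicts$class == "affected"), " affected / ",
         sum(hs$verdicts$class == "indeterminate"), " indeterminate / ",
         sum(hs$verdicts$class == "unaffected"), " unaffected assays; ",
         sum(!hs$statuses$admitted), " samples rejected")
  invisible(hs)
}

loadHemolysis <- function(cfg) {
  list(statuses = utils::read.csv(
         requireArtifact(stagePath(cfg, "hemolysis_statuses.csv"), "hemolysis"),
         stringsAsFactors = FALSE),
       verdicts = utils::read.csv(
         requireArtifact(stagePath(cfg, "hemolysis_verdicts.csv"), "hemolysis"),
         stringsAsFactors = FALSE))
}

stageNormalize <- function(cfg) {
  qc <- loadQc(cfg)
  hem <- loadHemolysis(cfg)
  keep <- hem$statuses$sample_id[hem$statuses$admitted]
  ct <- ctValues(qc$matrix)[rownames(ctValues(qc$matrix)) %in% keep, ,
                            drop = FALSE]
  mat <- new("CtMatrix", ct = ct,
             curveOk = matrix(TRUE, nrow(ct), ncol(ct), dimnames = dimnames(ct)),
             ceilingMask = ct >= cfg$ceiling, ceiling = cfg$ceiling)
  samples <- qc$samples[match(rownames(ct), qc$samples$sample_id), ]
  controls <- selectControls(mat, samples$group, hem$verdicts,
                             whitelist = cfg$whitelist,
                             vThreshold = cfg$vThreshold)
  normalized <- normalizeCt(mat, controls)
  writeMatrixCsv(exprValues(normalized),
                 stagePath(cfg, "normalized_matrix.csv"))
  aud <- selectionAudit(controls)
  utils::write.csv(aud$stability, stagePath(cfg, "stability.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(controls = controlsSelected(controls),
         best_pair = aud$best_pair, v3 = aud$v3,
         added_fourth = aud$added_fourth,
         exclusions = aud$exclusions),
    stagePath(cfg, "control_set.json"), auto_unbox = TRUE, digits = NA)
  logMsg(cfg, "normalize: controls ",
         paste(controlsSelected(controls), collapse = ", "))
  invisible(normalized)
}

loadNormalized <- function(cfg) {
  m <- readMatrixCsv(requireArtifact(stagePath(cfg, "normalized_matrix.csv"),
                                     "normalize"))
  ctrl <- jsonlite::read_json(
    requireArtifact(stagePath(cfg, "control_set.json"), "normalize"),
    simplifyVector = TRUE)$controls
  new("NormalizedMatrix", exprs = m, controlAssays = ctrl)
}

loadQcSamples <- function(cfg, normalized) {
  samples <- utils::read.csv(
    requireArtifact(stagePath(cfg, "samples_qc.csv"), "qc"),
    stringsAsFactors = FALSE)
  samples[match(rownames(exprValues(normalized)), samples$sample_id), ]
}

stageDe <- function(cfg) {
  normalized <- loadNormalized(cfg)
  samples <- loadQcSamples(cfg, normalized)
  cohorts <- sort(unique(samples$cohort[samples$group == "case"]))
  tables <- lapply(cohorts, function(ch) {
    tab <- deTable(normalized, samples, ch, alpha = cfg$alpha)
    utils::write.csv(tab, stagePath(cfg, sprintf("de_%s.csv", ch)),
                     row.names = FALSE, quote = FALSE)
    tab
  })
  names(tables) <- cohorts
  logMsg(cfg, "de: ",
         paste(sprintf("%s: %d significant", cohorts,
                       vapply(tables, function(t) sum(t$direction != "ns"),
                              integer(1))), collapse = "; "))
  invisible(tables)
}

survivalEndpoints <- function(cfg, samples) {
  eps <- list(
    os = list(time = samples$os_time, event = samples$os_event),
    dfi = list(time = samples$dfi_time, event = samples$dfi_event))
  for (h in names(cfg$horizons)) {
    tr <- applyHorizon(samples$os_time, samples$os_event, cfg$horizons[[h]])
    eps[[h]] <- tr
  }
  eps
}

stageSurvival <- function(cfg) {
  normalized <- loadNormalized(cfg)
  samples <- loadQcSamples(cfg, normalized)
  ex <- exprValues(normalized)
  assays <- setdiff(colnames(ex), controlAssays(normalized))
  cohorts <- sort(unique(samples$cohort[samples$group == "case"]))
  out <- list()
  for (ch in cohorts) {
    idx <- which(samples$cohort == ch & samples$group == "case")
    eps <- survivalEndpoints(cfg, samples[idx, ])
    for (ep in names(eps)) {
      keep <- !is.na(eps[[ep]]$time) & !is.na(eps[[ep]]$event)
      tm <- eps[[ep]]$time[keep]; ev <- eps[[ep]]$event[keep]
      rows <- lapply(assays, function(a) {
        x <- ex[idx[keep], a]
        res <- tryCatch({
          cutp <- maxSelectedCutpoint(x, tm, ev, minprop = cfg$minprop)
          lt <- logrankTest(tm, ev, cutp$groups)
          kmH <- kmEstimate(tm[cutp$groups == "high"],
                            ev[cutp$groups == "high"])
          kmL <- kmEstimate(tm[cutp$groups == "low"],
                            ev[cutp$groups == "low"])
          data.frame(assay_id = a, cutpoint = cutp$cutpoint,
                     statistic = cutp$statistic, chi2 = lt$chi2, p = lt$p,
                     n_high = sum(cutp$groups == "high"),
                     n_low = sum(cutp$groups == "low"),
                     median_high = kmH$median, median_low = kmL$median,
                     stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(assay_id = a, cutpoint = NA_real_, statistic = NA_real_,
                     chi2 = NA_real_, p = NA_real_, n_high = NA_integer_,
                     n_low = NA_integer_, median_high = NA_real_,
                     median_low = NA_real_, stringsAsFactors = FALSE))
        res
      })
      tab <- do.call(rbind, rows)
      tab <- tab[order(tab$p), ]
      utils::write.csv(tab,
                       stagePath(cfg, sprintf("survival_%s_%s.csv", ep, ch)),
                       row.names = FALSE, quote = FALSE)
      out[[paste(ep, ch, sep = "_")]] <- tab
    }
  }

  ## univariate Cox for clinical covariates (clinically annotated cohorts)
  cases <- samples[samples$group == "case" & !is.na(samples$os_time), ]
  clin <- cases[stats::complete.cases(cases[, c("age", "weight", "sex")]), ]
  covs <- list(age = clin$age, weight = clin$weight, sex = clin$sex,
               location = clin$location, alp = clin$alp)
  coxRows <- do.call(rbind, lapply(names(covs), function(v) {
    x <- covs[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 5L) return(NULL)
    do.call(rbind, lapply(c("os", "dfi"), function(ep) {
      tm <- if (ep == "os") clin$os_time else clin$dfi_time
      ev <- if (ep == "os") clin$os_event else clin$dfi_event
      okk <- ok & !is.na(tm) & !is.na(ev)
      fit <- tryCatch(coxUnivariate(x[okk], tm[okk], ev[okk]),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      cbind(data.frame(covariate = v, endpoint = ep,
                       stringsAsFactors = FALSE), fit)
    }))
  }))
  if (!is.null(coxRows))
    utils::write.csv(coxRows, stagePath(cfg, "cox_clinical.csv"),
                     row.names = FALSE, quote = FALSE)
  logMsg(cfg, "survival: cutpoint tables for ",
         length(out), " endpoint x cohort combinations")
  invisible(out)
}

stageTrees <- function(cfg) {
  normalized <- loadNormalized(cfg)
  samples <- loadQcSamples(cfg, normalized)
  hem <- loadHemolysis(cfg)
  ex <- exprValues(normalized)
  assays <- setdiff(colnames(ex), controlAssays(normalized))
  unaffected <- intersect(
    assays, hem$verdicts$assay_id[hem$verdicts$class == "unaffected"])
  seeds <- spawnSeeds(cfg$seed, 2L + length(cfg$horizons) + 3L)

  ## diagnostic tree: first two cohorts + most controls train; last cohort +
  ## held-out controls test
  cohorts <- sort(unique(samples$cohort[samples$group == "case"]))
  trainCohorts <- head(cohorts, max(1L, length(cohorts) - 1L))
  testCohorts <- setdiff(cohorts, trainCohorts)
  ctrlIds <- samples$sample_id[samples$group == "control"]
  nTrainCtrl <- round(cfg$trainControlFrac * length(ctrlIds))
  trainCtrl <- withSeed(seeds[1L], sample(ctrlIds, nTrainCtrl))
  trainIds <- c(samples$sample_id[samples$cohort %in% trainCohorts], trainCtrl)
  testIds <- setdiff(samples$sample_id, trainIds)
  trIdx <- match(trainIds, rownames(ex))
  teIdx <- match(testIds, rownames(ex))
  labels <- factor(samples$group, levels = c("control", "case"))

  diag <- growClassificationTree(ex[trIdx, assays, drop = FALSE],
                                 labels[trIdx], positive = "case",
                                 minsplit = cfg$tree$minsplit,
                                 minbucket = cfg$tree$minbucket,
                                 cp = cfg$tree$cp)
  diag <- crossvalPrune(diag, ex[trIdx, assays, drop = FALSE], labels[trIdx],
                        k = min(cfg$tree$k, length(trIdx)), seed = seeds[2L])
  treeToJson(diag, stagePath(cfg, "tree_diagnostic.json"))
  metrics <- rbind(
    data.frame(set = "train",
               as.data.frame(evaluateClassifier(
                 diag, ex[trIdx, assays, drop = FALSE],
                 labels[trIdx])[c("accuracy", "precision", "recall", "auc")])),
    data.frame(set = "test",
               as.data.frame(evaluateClassifier(
                 diag, ex[teIdx, assays, drop = FALSE],
                 labels[teIdx])[c("accuracy", "precision", "recall", "auc")])))
  utils::write.csv(metrics, stagePath(cfg, "diagnostic_metrics.csv"),
                   row.names = FALSE, quote = FALSE)

  ## prognostic survival trees on pooled cases, hemolysis-unaffected markers
  caseIdx <- which(samples$group == "case")
  eps <- survivalEndpoints(cfg, samples[caseIdx, ])
  sseed <- 2L
  for (ep in names(eps)) {
    sseed <- sseed + 1L
    keep <- !is.na(eps[[ep]]$time) & !is.na(eps[[ep]]$event)
    tm <- eps[[ep]]$time[keep]; ev <- eps[[ep]]$event[keep]
    Xs <- ex[caseIdx[keep], unaffected, drop = FALSE]
    tr <- tryCatch({
      t0 <- growSurvivalTree(Xs, tm, ev, minsplit = cfg$tree$minsplit,
                             minbucket = cfg$tree$minbucket, cp = cfg$tree$cp)
      crossvalPrune(t0, Xs, list(time = tm, event = ev),
                    k = min(cfg$tree$k, nrow(Xs)), seed = seeds[sseed])
    }, error = function(e) NULL)
    if (is.null(tr)) next
    treeToJson(tr, stagePath(cfg, sprintf("tree_%s.json", ep)))
    grp <- assignGroups(tr, Xs)
    cmp <- compareGroups(grp, tm, ev, tree = tr)
    utils::write.csv(cmp$groups,
                     stagePath(cfg, sprintf("tree_groups_%s.csv", ep)),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(cmp$pairwise))
      utils::write.csv(cmp$pairwise,
                       stagePath(cfg, sprintf("tree_pairwise_%s.csv", ep)),
                       row.names = FALSE, quote = FALSE)
  }

  ## multi-variable tree (markers + one-hot clinical covariates), cohorts
  ## with clinical annotation, overall survival
  clinIdx <- caseIdx[stats::complete.cases(
    samples[caseIdx, c("age", "weight", "sex", "alp")])]
  if (length(clinIdx) >= cfg$tree$minsplit) {
    cl <- samples[clinIdx, ]
    oneHot <- function(x, prefix) {
      lv <- sort(unique(x[!is.na(x)]))
      m <- vapply(lv, function(l) as.numeric(x == l), numeric(length(x)))
      colnames(m) <- paste0(prefix, "_", lv)
      m
    }
    Xc <- cbind(ex[clinIdx, unaffected, drop = FALSE],
                age = cl$age, weight = cl$weight,
                oneHot(cl$sex, "sex"), oneHot(cl$location, "loc"),
                oneHot(cl$alp, "alp"))
    keep <- !is.na(cl$os_time) & !is.na(cl$os_event)
    tr <- tryCatch({
      t0 <- growSurvivalTree(Xc[keep, , drop = FALSE], cl$os_time[keep],
                             cl$os_event[keep],
                             minsplit = cfg$tree$minsplit,
                             minbucket = cfg$tree$minbucket, cp = cfg$tree$cp)
      crossvalPrune(t0, Xc[keep, , drop = FALSE],
                    list(time = cl$os_time[keep], event = cl$os_event[keep]),
                    k = min(cfg$tree$k, sum(keep)),
                    seed = seeds[length(seeds)])
    }, error = function(e) NULL)
    if (!is.null(tr))
      treeToJson(tr, stagePath(cfg, "tree_multivariable_os.json"))
  }
  logMsg(cfg, "trees: diagnostic + ", length(eps), " prognostic endpoints")
  invisible(diag)
}

stageReport <- function(cfg) {
  lines <- c("# Pipeline report", "")
  addCsv <- function(lines, title, file, n = 10L) {
    path <- stagePath(cfg, file)
    if (!file.exists(path)) return(lines)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab <- head(tab, n)
    c(lines, paste("##", title), "",
      paste(colnames(tab), collapse = " | "),
      paste(rep("---", ncol(tab)), collapse = " | "),
      apply(tab, 1L, function(r) paste(r, collapse = " | ")), "")
  }
  qcPath <- stagePath(cfg, "qc_report.json")
  if (file.exists(qcPath)) {
    qc <- jsonlite::read_json(qcPath, simplifyVector = TRUE)
    lines <- c(lines, "## Quality control", "",
               paste0("- plate offsets: ",
                      paste(sprintf("%s: %+.3f", names(qc$plate_offsets),
                                    unlist(qc$plate_offsets)),
                            collapse = ", ")),
               paste0("- excluded samples: ",
                      if (is.data.frame(qc$excluded_samples))
                        nrow(qc$excluded_samples) else 0),
               paste0("- excluded assays: ",
                      if (is.data.frame(qc$excluded_assays))
                        nrow(qc$excluded_assays) else 0), "")
  }
  ctrlPath <- stagePath(cfg, "control_set.json")
  if (file.exists(ctrlPath)) {
    ctrl <- jsonlite::read_json(ctrlPath, simplifyVector = TRUE)
    lines <- c(lines, "## Endogenous controls", "",
               paste0("- selected: ", paste(ctrl$controls, collapse = ", ")),
               "")
  }
  for (f in sort(list.files(cfg$outDir, pattern = "^de_.*\\.csv$")))
    lines <- addCsv(lines, paste("Differential expression:", f), f)
  lines <- addCsv(lines, "Hemolysis verdicts", "hemolysis_verdicts.csv", 15L)
  lines <- addCsv(lines, "Diagnostic metrics", "diagnostic_metrics.csv")
  for (f in sort(list.files(cfg$outDir, pattern = "^tree_groups_.*\\.csv$")))
    lines <- addCsv(lines, paste("Survival tree groups:", f), f)
  writeLines(lines, stagePath(cfg, "report.md"))
  logMsg(cfg, "report: written")
  invisible(stagePath(cfg, "report.md"))
}

#' Run the pipeline
#'
#' Executes the requested stages in order inside the configured run
#' directory. Every stage writes its artifacts (CSV/JSON) there; re-running
#' with the same inputs and configuration reproduces identical files. A
#' failing stage halts with a stage-tagged error; artifacts of completed
#' stages are retained.
#'
#' @param config a [pipelineConfig()] object.
#' @param stages subset of
#'   \code{simulate, qc, hemolysis, normalize, de, survival, trees, report}
#'   (default: all, skipping simulate when \code{inputDir} is given).
#' @return invisibly, the run directory.
#' @export
runPipeline <- function(config, stages = NULL) {
  validatePipelineConfig(config)
  if (is.null(stages)) {
    stages <- pipelineStages
    if (!is.null(config$inputDir)) stages <- setdiff(stages, "simulate")
  }
  stopifnot(all(stages %in% pipelineStages))
  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  if (file.exists(stagePath(config, "pipeline.log")))
    file.remove(stagePath(config, "pipeline.log"))
  cfgOut <- config[setdiff(names(config), "cohort")]
  cfgOut$horizons <- as.list(config$horizons)
  yaml::write_yaml(cfgOut, stagePath(config, "config.yaml"))
  for (st in pipelineStages[pipelineStages %in% stages]) {
    fn <- switch(st, simulate = stageSimulate, qc = stageQc,
                 hemolysis = stageHemolysis, normalize = stageNormalize,
                 de = stageDe, survival = stageSurvival, trees = stageTrees,
                 report = stageReport)
    tryCatch(fn(config), error = function(e)
      stopf("stage '%s' failed: %s", st, conditionMessage(e)))
  }
  invisible(config$outDir)
}
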