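writePlateCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

plateDf <- function(plate = "p1", samples = c("s1", "s2"),
                    assays = c("a1", "a2"), ct = NULL, ntc = rep(20, 6)) {
  g <- expand.grid(sample_id = samples, assay_id = assays,
                   stringsAsFactors = FALSE)
  g$ct <- if (is.null(ct)) round(runif(nrow(g), 20, 30), 2) else ct
  rbind(
    data.frame(plate_id = plate, g, curve_ok = "TRUE",
               is_ntc_calibrator = "FALSE"),
    data.frame(plate_id = plate, sample_id = "NTC", assay_id = "UniSp3",
               ct = ntc, curve_ok = "TRUE", is_ntc_calibrator = "TRUE"))
}

test_that("plate reader handles missing-Ct tokens and rejects bad rows", {
  dir <- withr::local_tempdir()
  df <- plateDf(ct = c("21.5", "Undetermined", "", ">35"))
  p <- readPlates(writePlateCsv(df, file.path(dir, "p1.csv")))[[1]]
  expect_equal(wells(p)$ct, c(21.5, NA, NA, NA))

  dup <- rbind(df, df[1, ])
  writePlateCsv(dup, file.path(dir, "dup.csv"))
  expect_error(readPlates(file.path(dir, "dup.csv")), "duplicated well")

  bad <- df; bad$ct[1] <- "oops"
  writePlateCsv(bad, file.path(dir, "bad.csv"))
  expect_error(readPlates(file.path(dir, "bad.csv")), "malformed Ct.*bad.csv")

  extra <- cbind(df, junk = 1)
  expect_warning(readPlates(writePlateCsv(extra, file.path(dir, "ex.csv"))),
                 "unknown columns")

  nontc <- df[df$is_ntc_calibrator == "FALSE", ]
  writePlateCsv(nontc, file.path(dir, "nontc.csv"))
  expect_error(readPlates(file.path(dir, "nontc.csv")), "calibrator")
})

test_that("inter-plate calibration reproduces the subtract-the-offset rule", {
  dir <- withr::local_tempdir()
  ## calibrator means {20, 21, 22} -> offsets {-1, 0, +1}
  mk <- function(id, ntcMean, ct) {
    new("CtPlate", plateId = id,
        wells = data.frame(sample_id = paste0(id, "_s"), assay_id = "a1",
                           ct = ct, curve_ok = TRUE),
        ntcCalibrator = rep(ntcMean, 6))
  }
  plates <- list(mk("p1", 20, 25), mk("p2", 21, 25), mk("p3", 22, 30))
  res <- ipcCorrect(plates)
  expect_equal(unname(plateOffsets(res$report)), c(-1, 0, 1))
  ## raw Ct 30.0 on the third plate -> 29.0
  expect_equal(unname(ctValues(res$matrix)["p3_s", "a1"]), 29)
  ## corrected calibrator means coincide: exact by construction
  expect_equal(mean(ntcCalibrator(plates[[3]])) - plateOffsets(res$report)[["p3"]],
               mean(c(20, 21, 22)))

  ## single plate -> offset 0, Cts unchanged
  solo <- ipcCorrect(plates[1])
  expect_equal(unname(plateOffsets(solo$report)), 0)
  expect_equal(unname(ctValues(solo$matrix)["p1_s", "a1"]), 25)

  ## permuting plate order gives the identical corrected matrix
  perm <- ipcCorrect(plates[c(3, 1, 2)])
  ids <- rownames(ctValues(res$matrix))
  expect_equal(ctValues(perm$matrix)[ids, , drop = FALSE],
               ctValues(res$matrix))

  ## a sample on two plates is rejected
  plates2 <- list(mk("p1", 20, 25), mk("p2", 21, 25))
  plates2[[2]]@wells$sample_id <- "p1_s"
  expect_error(ipcCorrect(plates2), "more than one plate")
})

test_that("the Ct ceiling imputes undetected, high and curve-failed wells", {
  ct <- matrix(c(36.2, 34.99, NA, 30), 2, 2,
               dimnames = list(c("s1", "s2"), c("a1", "a2")))
  m <- new("CtMatrix", ct = ct,
           curveOk = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2,
                            dimnames = dimnames(ct)),
           ceilingMask = matrix(FALSE, 2, 2, dimnames = dimnames(ct)),
           ceiling = NA_real_)
  out <- applyCeiling(m, 35.00)
  expect_equal(unname(ctValues(out)), matrix(c(35, 34.99, 35, 35), 2, 2))
  expect_equal(unname(ceilingMask(out)),
               matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(ctCeiling(out), 35)
})

test_that("spike-in filter applies the two-SD envelope on the full set", {
  base <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     spike_iso = rep(19, 20), spike_rt = rep(21, 20))
  ## all identical -> degenerate interval at the mean, everything passes
  expect_true(all(spikeInFilter(base)$pass))

  ## one gross outlier fails alone (envelope recomputed with it included)
  set.seed(1)
  varied <- base
  varied$spike_iso <- rnorm(20, 19, 0.1)
  m <- mean(varied$spike_iso); s <- stats::sd(varied$spike_iso)
  varied$spike_iso[7] <- m + 10 * s
  out <- spikeInFilter(varied)
  expect_equal(out$sample_id[!out$pass], "s07")
  expect_equal(out$reason[!out$pass], "spike_out_of_range")

  ## single sample passes; missing spike fails with its own reason
  expect_true(spikeInFilter(base[1, ])$pass)
  miss <- base; miss$spike_rt[3] <- NA
  out <- spikeInFilter(miss)
  expect_equal(out$reason[3], "missing_spike")
  expect_false(out$pass[3])
})

test_that("sample detection filter drops only clearly low-detection samples", {
  ct <- matrix(25, 10, 20)
  m <- makeCtMatrix(ct)
  expect_true(all(sampleDetectionFilter(m)$pass))

  ct[3, 3:20] <- 35  # detects 2 of 20 where others detect all
  out <- sampleDetectionFilter(makeCtMatrix(ct))
  expect_equal(sum(!out$pass), 1L)
  expect_false(out$pass[3])
  expect_equal(out$reason[3], "low_detection")

  ## threshold exactly met passes (>=, not >)
  det <- out$detected
  thr <- mean(det) - 2 * stats::sd(det)
  expect_true(all(out$pass[det >= thr]))
})

test_that("assay prevalence filter drops the planted low-prevalence assays", {
  cohort <- generateCohort(cohortConfig(seed = 21))
  qcIn <- ipcCorrect(cohort$plates)
  mat <- applyCeiling(qcIn$matrix)
  out <- assayPrevalenceFilter(mat)
  expect_setequal(out$assay_id[!out$keep], cohort$truth$lowPrevalenceAssays)
  ## uniform prevalence -> nothing dropped; single assay kept (SD undefined)
  expect_true(all(assayPrevalenceFilter(makeCtMatrix(matrix(25, 8, 5)))$keep))
  expect_true(all(assayPrevalenceFilter(makeCtMatrix(matrix(25, 8, 1)))$keep))
})

test_that("filters are idempotent and order independent", {
  cohort <- generateCohort(smallCohortConfig(13))
  qc1 <- plateQc(cohort$plates, cohort$samples)
  ## applying the filters again to the filtered matrix excludes nothing new
  expect_true(all(sampleDetectionFilter(qc1$matrix)$pass))
  expect_true(all(assayPrevalenceFilter(qc1$matrix)$keep))
  ## shuffling the sample metadata rows leaves the partition unchanged
  shuffled <- cohort$samples[rev(seq_len(nrow(cohort$samples))), ]
  qc2 <- plateQc(cohort$plates, shuffled)
  expect_setequal(rownames(ctValues(qc1$matrix)), rownames(ctValues(qc2$matrix)))
  expect_equal(excludedSamples(qc1$report)$sample_id,
               excludedSamples(qc2$report)$sample_id)
})
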