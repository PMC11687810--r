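test_that("generation is deterministic given the config seed", {
  a <- generateCohort(smallCohortConfig(7))
  b <- generateCohort(smallCohortConfig(7))
  expect_identical(lapply(a$plates, wells), lapply(b$plates, wells))
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$survivalGroups, b$truth$survivalGroups)
  c <- generateCohort(smallCohortConfig(8))
  expect_false(identical(a$samples, c$samples))
})

test_that("generation leaves the global RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(generateCohort(smallCohortConfig(7)))
  expect_identical(before, .Random.seed)
})

test_that("each sample appears on exactly one plate", {
  cohort <- generateCohort(smallCohortConfig(7))
  byPlate <- lapply(cohort$plates, function(p) unique(wells(p)$sample_id))
  all <- unlist(byPlate)
  expect_false(anyDuplicated(all) > 0)
  expect_setequal(all, cohort$samples$sample_id)
})

test_that("hemolysis-coupled assays have Ct decreasing in 414 nm absorbance", {
  cohort <- generateCohort(cohortConfig(seed = 11))
  ct <- do.call(rbind, lapply(cohort$plates, function(p) wells(p)))
  a414 <- stats::setNames(cohort$samples$a414, cohort$samples$sample_id)
  for (a in c("miR-16-5p", "miR-451a")) {
    sub <- ct[ct$assay_id == a, ]
    expect_lt(stats::cor(sub$ct, a414[sub$sample_id]), -0.4)
  }
})

test_that("NTC calibrator wells carry the plate offset", {
  cfg <- smallCohortConfig(3)
  cohort <- generateCohort(cfg)
  means <- vapply(cohort$plates, function(p) mean(ntcCalibrator(p)), numeric(1))
  expect_equal(means - 20, cfg@plateOffsets, tolerance = 0.1)
})

test_that("inconsistent configs are rejected with a message", {
  expect_error(cohortConfig(nAssays = 5, lowPrevalenceAssays = 6),
               "low-prevalence")
  expect_error(cohortConfig(censorRate = 1.2), "censorRate")
  expect_error(cohortConfig(nPlates = 3), "plateOffsets")
})

test_that("write/read round-trips the generated structures exactly", {
  cohort <- generateCohort(smallCohortConfig(5))
  dir <- withr::local_tempdir()
  paths <- writeFixture(cohort$plates, cohort$samples, dir)
  plates2 <- readPlates(paths$plates)
  samples2 <- readSamples(paths$samples)
  for (i in seq_along(cohort$plates)) {
    expect_identical(plateId(plates2[[i]]), plateId(cohort$plates[[i]]))
    expect_equal(wells(plates2[[i]]), wells(cohort$plates[[i]]))
    expect_equal(ntcCalibrator(plates2[[i]]),
                 ntcCalibrator(cohort$plates[[i]]))
  }
  expect_equal(samples2, cohort$samples)
})

test_that("repeated writes of the same cohort are byte-identical", {
  cohort <- generateCohort(smallCohortConfig(42))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFixture(cohort$plates, cohort$samples, d1)
  writeFixture(cohort$plates, cohort$samples, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("an empty cohort writes header-only CSVs", {
  cohort <- generateCohort(smallCohortConfig(5))
  dir <- withr::local_tempdir()
  paths <- writeFixture(list(), cohort$samples[0, ], dir)
  expect_length(readLines(paths$samples), 1L)
})

test_that("planted high/low groups obey the exponential hazard link", {
  ## event-rate ratio between planted groups converges to exp(coefficient)
  cfg <- cohortConfig(
    nCasesPerCohort = c(big = 1000), nControls = 10, nPlates = 1,
    plateOffsets = 0, censorRate = 0,
    survivalLinks = c("miR-214-3p" = log(2)), seed = 99)
  cohort <- generateCohort(cfg)
  cases <- cohort$samples[cohort$samples$group == "case", ]
  H <- cohort$truth$survivalGroups[cases$sample_id, "miR-214-3p"]
  rate <- function(sel) sum(cases$os_event[sel]) / sum(cases$os_time[sel])
  ratio <- rate(H == 1) / rate(H == 0)
  expect_lt(abs(ratio / 2 - 1), 0.1)
})

test_that("null configuration yields uniform raw DE p-values", {
  ## pooled raw rank-sum p-values across 50 null seeds pass a KS uniformity
  ## check
  ps <- unlist(lapply(1:50, function(s) {
    cohort <- generateCohort(nullCohortConfig(1000 + s))
    res <- runThroughNormalization(cohort)
    tab <- deTable(res$normalized, res$samples, "cohort1")
    tab$raw_p
  }))
  ## discrete ties at small n make exact KS conservative; jitter within the
  ## attainable p-grid is avoided by testing distributional uniformity coarsely
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps < 0.5), 0.4)
  expect_lt(mean(ps < 0.05), 0.10)
})
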