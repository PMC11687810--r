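## Build a ceilinged CtMatrix + verdicts where eligibility is unrestricted
unrestrictedVerdicts <- function(assays) {
  data.frame(assay_id = assays, r2 = 0.01, p = 0.8, class = "unaffected",
             reason = NA_character_, stringsAsFactors = FALSE)
}

test_that("a dominant trio is selected and matches exhaustive enumeration", {
  set.seed(11)
  n <- 40
  stable <- sapply(1:3, function(i) rnorm(n, 22 + i, 0.2))
  noisy <- sapply(1:2, function(i) rnorm(n, 26 + i, 1.5))
  mat <- cbind(stable, noisy)
  colnames(mat) <- c("s1", "s2", "s3", "n1", "n2")
  groups <- rep(c("case", "control"), each = n / 2)
  ctrl <- suppressWarnings(
    selectControls(makeCtMatrix(mat), groups, unrestrictedVerdicts(colnames(mat))))
  expect_setequal(controlsSelected(ctrl)[1:3], c("s1", "s2", "s3"))

  ## exhaustive trio enumeration oracle over the same stability fit
  stab <- normFinderStability(mat, groups)
  trios <- utils::combn(colnames(mat), 3)
  rhos <- apply(trios, 2, function(tr) setStability(stab, tr))
  expect_setequal(controlsSelected(ctrl)[1:3], trios[, which.min(rhos)])
})

test_that("a fourth control that leaves the factor unchanged is not added", {
  set.seed(12)
  n <- 30
  base <- rnorm(n)  # shared sample effect
  mat <- cbind(c1 = 20 + base + rnorm(n, 0, 0.1),
               c2 = 22 + base + rnorm(n, 0, 0.1),
               c3 = 24 + base + rnorm(n, 0, 0.1),
               c4 = 22 + base + rnorm(n, 0, 0.1))
  ctrl <- suppressWarnings(
    selectControls(makeCtMatrix(mat), rep(c("a", "b"), each = n / 2),
                   unrestrictedVerdicts(colnames(mat))))
  expect_length(controlsSelected(ctrl), 3L)
  expect_false(selectionAudit(ctrl)$added_fourth)
  expect_lt(selectionAudit(ctrl)$v3, 0.15)
})

test_that("eligibility rules exclude ceiling, affected and indeterminate assays", {
  set.seed(13)
  n <- 20
  mat <- sapply(1:6, function(i) rnorm(n, 24, 0.3))
  colnames(mat) <- paste0("a", 1:6)
  mat[5, "a4"] <- 36  # saturated in one sample
  verd <- unrestrictedVerdicts(colnames(mat))
  verd$class[verd$assay_id == "a5"] <- "affected"
  verd$class[verd$assay_id == "a6"] <- "indeterminate"
  ctrl <- suppressWarnings(
    selectControls(makeCtMatrix(mat), rep(c("x", "y"), each = n / 2), verd))
  expect_setequal(controlsSelected(ctrl), c("a1", "a2", "a3"))
  ex <- selectionAudit(ctrl)$exclusions
  expect_equal(ex$reason[ex$assay_id == "a4"], "not_expressed_in_all_samples")
  expect_equal(ex$reason[ex$assay_id == "a5"], "hemolysis_affected")
  expect_equal(ex$reason[ex$assay_id == "a6"], "hemolysis_indeterminate")

  ## whitelisting waives the indeterminate verdict
  ctrl2 <- suppressWarnings(
    selectControls(makeCtMatrix(mat), rep(c("x", "y"), each = n / 2), verd,
                   whitelist = "a6"))
  expect_true("a6" %in% selectionAudit(ctrl2)$candidates)

  ## under three eligible candidates is a hard error listing reasons
  verd$class[verd$assay_id %in% c("a1", "a2")] <- "affected"
  expect_error(
    suppressWarnings(selectControls(makeCtMatrix(mat),
                                    rep(c("x", "y"), each = n / 2), verd)),
    "hemolysis_affected")
})

test_that("the planted stable trio is recovered across seeds", {
  ## full study-sized cohorts; the candidate panel is whitelisted so that
  ## chance indeterminate verdicts do not mask the stability ranking itself
  hits <- vapply(1:40, function(s) {
    cohort <- generateCohort(cohortConfig(seed = 400 + s))
    res <- runThroughNormalization(
      cohort, whitelist = c(cohort$truth$controlCandidates,
                            cohort$truth$whitelistCandidates))
    setequal(controlsSelected(res$controls), cohort$truth$controlCandidates)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("comparative-Ct normalization is exact and shift invariant", {
  ct <- matrix(c(20, 25, 22.360679774997898,
                 21, 26, 23.360679774997898), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("c1", "c2", "t")))
  norm <- normalizeCt(makeCtMatrix(ct), c("c1", "c2"))
  ## geometric mean of {20, 25} = sqrt(500) = 22.3607 -> target normalizes to 0
  expect_equal(unname(exprValues(norm)["s1", "t"]), 0, tolerance = 1e-12)
  ## adding a constant to every Ct of a sample is absorbed almost exactly:
  ## the literal geometric average of Ct values is shift equivariant only to
  ## first order (the arithmetic average would be exact), but for control Cts
  ## in the low twenties the residual is below 0.01 cycles
  expect_equal(unname(exprValues(norm)["s2", "t"]), 0, tolerance = 0.01)
  ## a target equal to a sole control normalizes to exactly 0
  solo <- normalizeCt(makeCtMatrix(ct), "c1")
  expect_equal(unname(exprValues(solo)[, "c1"]), c(0, 0))
  ## a control at the ceiling violates the contract
  bad <- ct; bad["s1", "c1"] <- 35
  expect_error(normalizeCt(makeCtMatrix(bad), c("c1", "c2")), "ceiling")
})

test_that("fold-change / fold-difference arithmetic follows the conventions", {
  expect_equal(foldDifference(1), 1)
  expect_equal(foldDifference(0.25), -4)
  expect_equal(foldDifference(4), 4)
  ## |FD| >= 1 and sign matches FC >= 1, over a sweep
  fc <- c(0.01, 0.2, 0.5, 0.99, 1, 1.5, 8)
  fd <- foldDifference(fc)
  expect_true(all(abs(fd) >= 1))
  expect_equal(fd > 0, fc >= 1)
  ## cases uniformly 2.37 Ct above the control median -> median FD 5.16
  ctrlVals <- c(-0.3, 0, 0.4)
  caseVals <- 0 + 2.37
  fcs <- foldChange(rep(caseVals, 5), ctrlVals)
  expect_equal(stats::median(foldDifference(fcs)), 2^2.37, tolerance = 1e-12)
  expect_equal(round(stats::median(foldDifference(fcs)), 2), 5.17)
})
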