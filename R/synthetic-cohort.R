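## Synthetic multi-cohort plasma miRNA RT-qPCR study generator.
##
## The generator emulates the statistical structure the downstream pipeline
## assumes: several case cohorts against one control group, a fixed assay
## panel with a handful of near-undetectable assays, plate-specific
## calibration offsets carried by NTC calibrator wells, hemolysis-coupled
## assays whose Ct falls linearly with 414 nm absorbance, planted
## case/control expression shifts, and exponential proportional-hazards
## survival tied to planted high/low expressor subgroups.

#' Class "CohortConfig": parameters of the synthetic study
#'
#' See [cohortConfig()] for field semantics and defaults.
#' @export
setClass("CohortConfig",
  representation(
    nCasesPerCohort = "numeric", nControls = "numeric", nAssays = "numeric",
    nPlates = "numeric", plateOffsets = "numeric",
    plantedEffects = "numeric", hemolysisCoupled = "numeric",
    survivalLinks = "numeric", censorRate = "numeric",
    baselineCtMean = "numeric", baselineCtSd = "numeric",
    lowPrevalenceAssays = "numeric", seed = "numeric",
    expressionHeterogeneity = "numeric", sampleShiftSd = "numeric",
    osMedianDays = "numeric", dfiMedianDays = "numeric",
    hemolysisFractions = "numeric",
    controlCandidates = "character", whitelistCandidates = "character",
    ntcMean = "numeric", ntcSd = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (any(object@nCasesPerCohort <= 0) || object@nControls <= 0 ||
      object@nAssays <= 0 || object@nPlates <= 0)
    msg <- c(msg, "all counts must be positive")
  if (object@censorRate < 0 || object@censorRate >= 1)
    msg <- c(msg, "censorRate must lie in [0, 1)")
  if (any(object@baselineCtSd <= 0))
    msg <- c(msg, "all Ct noise SDs must be positive")
  if (object@lowPrevalenceAssays > object@nAssays)
    msg <- c(msg, "more low-prevalence assays than assays in the panel")
  if (length(object@plateOffsets) != object@nPlates)
    msg <- c(msg, "plateOffsets must have one entry per plate")
  if (sum(object@lowPrevalenceAssays, length(object@controlCandidates),
          length(object@whitelistCandidates)) > object@nAssays)
    msg <- c(msg, "special assay roles exceed the panel size")
  if (length(msg)) msg else TRUE
})

#' Configure a synthetic plasma miRNA study
#'
#' Defaults describe a three-cohort canine osteosarcoma-style study: case
#' cohorts of 35, 13 and 13 dogs against 21 healthy controls, a 56-assay
#' custom panel with 6 near-undetectable assays, four PCR arrays with distinct
#' calibration offsets, erythrocyte-derived assays coupled to hemolysis, one
#' planted diagnostic/prognostic marker (miR-214-3p analogue) upregulated by
#' 2.37 cycles in cases (fold-difference about 5.2) whose high-expressing
#' tumours carry a log 2.9 excess hazard, and right-censored exponential
#' survival.
#'
#' @param nCasesPerCohort named counts of cases per cohort.
#' @param nControls number of healthy controls.
#' @param nAssays panel size.
#' @param nPlates number of PCR arrays; samples are dealt round-robin.
#' @param plateOffsets per-plate calibration offset (Ct units) carried by
#'   every well and by the NTC calibrator replicates.
#' @param plantedEffects named Ct shifts applied to cases (negative =
#'   upregulated, i.e. fewer cycles).
#' @param hemolysisCoupled named slopes (Ct per absorbance unit at 414 nm;
#'   negative = released by hemolysis).
#' @param survivalLinks named log hazard ratios of the planted high- vs
#'   low-expressing subgroups.
#' @param censorRate expected fraction of cases censored for each endpoint.
#' @param baselineCtMean optional named per-assay baseline Ct means; drawn
#'   from the seed when empty.
#' @param baselineCtSd per-well Gaussian Ct noise SD (scalar; control
#'   candidates use tighter SDs set internally).
#' @param lowPrevalenceAssays how many assays sit near/above the detection
#'   limit.
#' @param seed integer master seed; all generation is deterministic given it.
#' @param expressionHeterogeneity Ct separation between the high- and
#'   low-expressing case subgroups of survival-linked assays (2.4 cycles,
#'   about five-fold, consistent with observed dichotomized expression
#'   differences in plasma panels).
#' @param sampleShiftSd SD of the per-sample global Ct shift (isolation /
#'   input efficiency); removed by control normalization.
#' @param osMedianDays,dfiMedianDays baseline (low-risk) median survival for
#'   the overall-survival and disease-free-interval endpoints.
#' @param hemolysisFractions mixture weights for clean / hemolyzed / lipemic
#'   samples.
#' @param controlCandidates assay names generated as highly stable
#'   endogenous-control candidates (no group effect, low variance).
#' @param whitelistCandidates assays generated stable but mildly
#'   hemolysis-coupled (non-definitive verdicts; used to pad the candidate
#'   pool).
#' @param ntcMean,ntcSd calibrator NTC replicate mean Ct and replicate SD.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(seed = 7)
#' cohort <- generateCohort(cfg)
#' length(cohort$plates)
#' @export
cohortConfig <- function(
    nCasesPerCohort = c(cohort1 = 35, cohort2 = 13, cohort3 = 13),
    nControls = 21,
    nAssays = 56,
    nPlates = 4,
    plateOffsets = c(-0.4, 0.15, 0.3, -0.05),
    plantedEffects = c("miR-214-3p" = -2.37),
    hemolysisCoupled = c("miR-16-5p" = -3.0, "miR-92a-3p" = -3.0,
                         "miR-451a" = -3.5, "miR-505-5p" = -2.5,
                         "hsa-let-7c-5p" = -0.8, "cfa-miR-140" = -0.8),
    survivalLinks = c("miR-214-3p" = log(2.9)),
    censorRate = 0.15,
    baselineCtMean = numeric(),
    baselineCtSd = 0.8,
    lowPrevalenceAssays = 6,
    seed = 1L,
    expressionHeterogeneity = 2.4,
    sampleShiftSd = 0.3,
    osMedianDays = 400,
    dfiMedianDays = 330,
    hemolysisFractions = c(clean = 0.70, hemolyzed = 0.20, lipemic = 0.10),
    controlCandidates = c("cfa-miR-23b", "rno-miR-223-3p", "hsa-miR-27b-3p"),
    whitelistCandidates = c("hsa-let-7c-5p", "cfa-miR-140"),
    ntcMean = 20, ntcSd = 0.05) {
  if (is.null(names(nCasesPerCohort)))
    names(nCasesPerCohort) <- paste0("cohort", seq_along(nCasesPerCohort))
  new("CohortConfig",
      nCasesPerCohort = nCasesPerCohort, nControls = nControls,
      nAssays = nAssays, nPlates = nPlates, plateOffsets = plateOffsets,
      plantedEffects = plantedEffects, hemolysisCoupled = hemolysisCoupled,
      survivalLinks = survivalLinks, censorRate = censorRate,
      baselineCtMean = baselineCtMean, baselineCtSd = baselineCtSd,
      lowPrevalenceAssays = lowPrevalenceAssays, seed = seed,
      expressionHeterogeneity = expressionHeterogeneity,
      sampleShiftSd = sampleShiftSd, osMedianDays = osMedianDays,
      dfiMedianDays = dfiMedianDays, hemolysisFractions = hemolysisFractions,
      controlCandidates = controlCandidates,
      whitelistCandidates = whitelistCandidates,
      ntcMean = ntcMean, ntcSd = ntcSd)
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:",
      paste(object@nCasesPerCohort, collapse = "/"), "cases vs",
      object@nControls, "controls;",
      object@nAssays, "assays on", object@nPlates, "plates; seed",
      object@seed, "\n")
  cat("  planted effects:", length(object@plantedEffects),
      " hemolysis-coupled:", length(object@hemolysisCoupled),
      " survival links:", length(object@survivalLinks), "\n")
})

## Named assay panel mirroring a canine plasma custom array; the first entries
## are real plasma miRNA names (planted marker, candidate tree variables,
## erythrocyte miRNAs, endogenous-control candidates, low-prevalence assays),
## padded with generic simulated assay names up to the panel size.
panelAssayNames <- function(config) {
  named <- unique(c(
    names(config@plantedEffects), names(config@survivalLinks),
    "miR-214-3p", "miR-221", "miR-1307-3p", "miR-28-3p", "miR-222-3p",
    "miR-92b-3p", "miR-23a", "miR-133b", "miR-145-5p", "miR-133-3p",
    "miR-133c", "miR-378a-3p", "miR-30a", "miR-143-3p", "miR-125a",
    names(config@hemolysisCoupled),
    config@controlCandidates, "miR-191", config@whitelistCandidates,
    "miR-433-3p", "miR-210", "miR-589", "miR-551a", "miR-138b", "miR-802"))
  if (length(named) > config@nAssays)
    stopf("panel size %d cannot hold the %d named assays",
          config@nAssays, length(named))
  pad <- config@nAssays - length(named)
  c(named, if (pad > 0) sprintf("miR-sim-%02d", seq_len(pad)))
}

fmtNum <- function(x, digits) as.numeric(sprintf(paste0("%.", digits, "f"), x))

## Standard normal truncated at +/- bound: spike-in technical variation is
## bounded in practice; heavy tails are what the spike QC filter exists to
## catch, and the emulated study reports no spike failures.
truncStdNorm <- function(n, bound) {
  stats::qnorm(runif(n, stats::pnorm(-bound), stats::pnorm(bound)))
}

#' Generate a synthetic study cohort
#'
#' Draws plates, sample metadata and survival outcomes from the configured
#' model, together with a ground-truth record for recovery tests. Generation
#' is fully deterministic given \code{config} (including its seed) and leaves
#' the global RNG state untouched.
#'
#' The data model per well:
#' \deqn{Ct_{sa} = \mu_a + g_s + o_{p(s)} + \beta^{case}_a 1[s\ case]
#'   + \gamma_a A414_s \pm h_a/2 + \varepsilon_{sa}}
#' with per-assay baseline \eqn{\mu_a}, per-sample efficiency shift
#' \eqn{g_s}, plate offset \eqn{o_p}, planted case shift \eqn{\beta^{case}},
#' hemolysis coupling \eqn{\gamma_a} against the latent 414 nm absorbance,
#' and the high/low expressor separation \eqn{h_a} for survival-linked
#' assays (high/low drawn Bernoulli(1/2) within cases). Survival times are
#' exponential proportional hazards on the high/low indicators with
#' independent exponential censoring. Wells beyond 40 cycles are reported
#' undetected (missing Ct).
#'
#' @param config a [CohortConfig-class].
#' @return list with elements \code{plates} (list of [CtPlate-class]),
#'   \code{samples} (data.frame of per-sample records) and \code{truth}
#'   (ground-truth list: planted effects, coupling slopes, survival
#'   coefficients and high/low groups, latent hemolysis levels, assay roles).
#' @export
generateCohort <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    assays <- panelAssayNames(config)
    nA <- length(assays)
    lowPrev <- intersect(
      c("miR-433-3p", "miR-210", "miR-589", "miR-551a", "miR-138b", "miR-802"),
      assays)
    lowPrev <- head(c(lowPrev, setdiff(rev(assays), lowPrev)),
                    config@lowPrevalenceAssays)

    ## per-assay baselines and noise
    baseline <- if (length(config@baselineCtMean)) {
      stopifnot(all(assays %in% names(config@baselineCtMean)))
      config@baselineCtMean[assays]
    } else {
      b <- stats::setNames(runif(nA, 22, 31), assays)
      b[config@controlCandidates] <- runif(length(config@controlCandidates), 20, 24)
      b[config@whitelistCandidates] <- runif(length(config@whitelistCandidates), 20, 24)
      b[lowPrev] <- runif(length(lowPrev), 38, 42)
      b
    }
    assaySd <- stats::setNames(rep(config@baselineCtSd[1], nA), assays)
    assaySd[config@controlCandidates] <- 0.2
    assaySd[config@whitelistCandidates] <- 0.6

    ## samples
    cohorts <- rep(names(config@nCasesPerCohort), config@nCasesPerCohort)
    cohorts <- c(cohorts, rep("control", config@nControls))
    n <- length(cohorts)
    ids <- sprintf("S%03d", seq_len(n))
    isCase <- cohorts != "control"
    plate <- ((seq_len(n) - 1L) %% config@nPlates) + 1L

    ## latent hemolysis
    hClass <- sample(names(config@hemolysisFractions), n, replace = TRUE,
                     prob = config@hemolysisFractions)
    a414 <- numeric(n)
    a414[hClass == "clean"] <- runif(sum(hClass == "clean"), 0.05, 0.2)
    a414[hClass == "hemolyzed"] <- runif(sum(hClass == "hemolyzed"), 0.2, 1.2)
    a414[hClass == "lipemic"] <- runif(sum(hClass == "lipemic"), 0.25, 0.9)
    ratio <- rnorm(n, 1.6, 0.08)
    ratio[hClass == "lipemic"] <- runif(sum(hClass == "lipemic"), 1.05, 1.35)
    a414 <- fmtNum(a414, 4)
    a375 <- fmtNum(a414 / ratio, 4)

    gShift <- rnorm(n, 0, config@sampleShiftSd)

    ## planted high/low expressor groups (cases only) for survival links
    linked <- names(config@survivalLinks)
    H <- matrix(0L, n, length(linked), dimnames = list(ids, linked))
    if (length(linked))
      H[isCase, ] <- matrix(rbinom(sum(isCase) * length(linked), 1L, 0.5),
                            sum(isCase), length(linked))

    ## Ct matrix (samples x assays)
    ct <- matrix(rnorm(n * nA, 0, 1), n, nA, dimnames = list(ids, assays))
    ct <- sweep(ct, 2L, assaySd, `*`)
    ct <- sweep(ct, 2L, baseline, `+`)
    ct <- ct + gShift + config@plateOffsets[plate]
    for (a in names(config@plantedEffects))
      ct[isCase, a] <- ct[isCase, a] + config@plantedEffects[[a]]
    for (a in names(config@hemolysisCoupled))
      ct[, a] <- ct[, a] + config@hemolysisCoupled[[a]] * a414
    for (a in linked)
      ct[isCase, a] <- ct[isCase, a] -
        config@expressionHeterogeneity * (H[isCase, a] - 0.5)
    ct <- fmtNum(ct, 2)
    dim(ct) <- c(n, nA); dimnames(ct) <- list(ids, assays)
    ct[ct > 40] <- NA  # undetected beyond 40 cycles

    ## survival endpoints (cases only)
    eta <- if (length(linked)) drop(H %*% config@survivalLinks) else rep(0, n)
    drawEndpoint <- function(baselineMedian) {
      lam0 <- log(2) / baselineMedian
      rate <- lam0 * exp(eta)
      tEvent <- rexp(n, rate)
      cr <- config@censorRate
      tCens <- if (cr > 0) rexp(n, mean(rate) * cr / (1 - cr)) else rep(Inf, n)
      time <- pmax(1, ceiling(pmin(tEvent, tCens)))
      list(time = ifelse(isCase, time, NA_real_),
           event = ifelse(isCase, as.integer(tEvent <= tCens), NA_integer_))
    }
    os <- drawEndpoint(config@osMedianDays)
    dfi <- drawEndpoint(config@dfiMedianDays)

    ## clinical covariates
    age <- fmtNum(pmin(13, pmax(2, rnorm(n, 8, 2))), 2)
    age[!isCase] <- fmtNum(pmin(10, pmax(1.2, rnorm(sum(!isCase), 4.6, 1.8))), 2)
    sex <- sample(c("male_neutered", "female_spayed", "male_intact",
                    "female_intact"), n, replace = TRUE,
                  prob = c(0.47, 0.46, 0.035, 0.035))
    weight <- fmtNum(pmin(70, pmax(20, rnorm(n, 36, 8))), 1)
    location <- ifelse(isCase,
                       sample(c("radius", "humerus", "femur", "tibia", "ulna"),
                              n, replace = TRUE,
                              prob = c(0.35, 0.2, 0.2, 0.15, 0.1)),
                       NA_character_)
    alp <- ifelse(isCase,
                  sample(c("above", "within", "below"), n, replace = TRUE,
                         prob = c(0.3, 0.65, 0.05)),
                  NA_character_)

    samples <- data.frame(
      sample_id = ids, cohort = cohorts,
      group = ifelse(isCase, "case", "control"),
      a414 = a414, a375 = a375,
      spike_iso = fmtNum(19 + 0.15 * truncStdNorm(n, 1.0), 2),
      spike_rt = fmtNum(21 + 0.12 * truncStdNorm(n, 1.0), 2),
      age = age, sex = sex, weight = weight,
      location = location, alp = alp,
      os_time = os$time, os_event = os$event,
      dfi_time = dfi$time, dfi_event = dfi$event,
      stringsAsFactors = FALSE)

    ## plates
    plates <- lapply(seq_len(config@nPlates), function(p) {
      onPlate <- ids[plate == p]
      w <- expand.grid(sample_id = onPlate, assay_id = assays,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      w <- w[order(match(w$sample_id, onPlate), match(w$assay_id, assays)), ]
      w$ct <- ct[cbind(w$sample_id, w$assay_id)]
      w$curve_ok <- TRUE
      rownames(w) <- NULL
      new("CtPlate", plateId = sprintf("plate%d", p), wells = w,
          ntcCalibrator = fmtNum(
            rnorm(6, config@ntcMean + config@plateOffsets[p], config@ntcSd), 2))
    })

    truth <- list(
      effects = config@plantedEffects,
      hemolysisCoupled = config@hemolysisCoupled,
      survivalLinks = config@survivalLinks,
      expressionHeterogeneity = config@expressionHeterogeneity,
      survivalGroups = H[isCase, , drop = FALSE],
      sampleHemolysis = data.frame(sample_id = ids, a414 = a414,
                                   latent_class = hClass,
                                   stringsAsFactors = FALSE),
      linearPredictor = stats::setNames(eta[isCase], ids[isCase]),
      lowPrevalenceAssays = lowPrev,
      controlCandidates = config@controlCandidates,
      whitelistCandidates = config@whitelistCandidates,
      baselineCt = baseline, assaySd = assaySd,
      plateAssignment = stats::setNames(sprintf("plate%d", plate), ids))

    list(plates = plates, samples = samples, truth = truth)
  })
}

#' Write a generated cohort as CSV fixtures
#'
#' Emits one long-format plate CSV per array (columns \code{plate_id},
#' \code{sample_id}, \code{assay_id}, \code{ct}, \code{curve_ok},
#' \code{is_ntc_calibrator}; undetected wells have an empty Ct field) plus a
#' sample metadata CSV, in the exact dialect read back by [readPlates()] and
#' [readSamples()]. Numeric fields are written at generator precision, so a
#' generate/write/read cycle reproduces the structures exactly and repeated
#' writes of the same objects are byte-identical.
#'
#' @param plates list of [CtPlate-class].
#' @param samples sample metadata data.frame as from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named \code{plates}, \code{samples}).
#' @export
writeFixture <- function(plates, samples, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", dir)
  num <- function(x, d) ifelse(is.na(x), "", sprintf(paste0("%.", d, "f"), x))
  int <- function(x) ifelse(is.na(x), "", sprintf("%d", as.integer(x)))
  chr <- function(x) ifelse(is.na(x), "", x)

  platePaths <- vapply(plates, function(pl) {
    w <- wells(pl)
    out <- data.frame(
      plate_id = rep(plateId(pl), nrow(w) + length(ntcCalibrator(pl))),
      sample_id = c(w$sample_id, rep("NTC", length(ntcCalibrator(pl)))),
      assay_id = c(w$assay_id, rep("UniSp3", length(ntcCalibrator(pl)))),
      ct = c(num(w$ct, 2), num(ntcCalibrator(pl), 2)),
      curve_ok = c(as.character(w$curve_ok),
                   rep("TRUE", length(ntcCalibrator(pl)))),
      is_ntc_calibrator = c(rep("FALSE", nrow(w)),
                            rep("TRUE", length(ntcCalibrator(pl)))),
      stringsAsFactors = FALSE)
    if (nrow(w) == 0L) out <- out[rep(FALSE, nrow(out)), , drop = FALSE]
    path <- file.path(dir, paste0(plateId(pl), ".csv"))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    path
  }, character(1))

  s <- samples
  out <- data.frame(
    sample_id = chr(s$sample_id), cohort = chr(s$cohort), group = chr(s$group),
    a414 = num(s$a414, 4), a375 = num(s$a375, 4),
    spike_iso = num(s$spike_iso, 2), spike_rt = num(s$spike_rt, 2),
    age = num(s$age, 2), sex = chr(s$sex), weight = num(s$weight, 1),
    location = chr(s$location), alp = chr(s$alp),
    os_time = int(s$os_time), os_event = int(s$os_event),
    dfi_time = int(s$dfi_time), dfi_event = int(s$dfi_event),
    stringsAsFactors = FALSE)
  samplePath <- file.path(dir, "samples.csv")
  utils::write.csv(out, samplePath, row.names = FALSE, quote = FALSE)

  invisible(list(plates = platePaths, samples = samplePath))
}
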