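## Shared fixtures and independent oracles for the test suite.
## Oracles deliberately use a different computational route than the package
## (explicit loops, survival::survdiff, grid search) so that agreement is a
## genuine cross-check.

## A small but fully featured synthetic study (two case cohorts + controls)
smallCohortConfig <- function(seed, ...) {
  cohortConfig(
    nCasesPerCohort = c(cohort1 = 14, cohort2 = 10),
    nControls = 12,
    nAssays = 32,
    nPlates = 2,
    plateOffsets = c(-0.3, 0.2),
    seed = seed,
    ...)
}

## A configuration with nothing planted (null study)
nullCohortConfig <- function(seed, ...) {
  cohortConfig(
    nCasesPerCohort = c(cohort1 = 20),
    nControls = 20,
    nAssays = 56,
    nPlates = 2,
    plateOffsets = c(0, 0),
    plantedEffects = stats::setNames(numeric(), character()),
    hemolysisCoupled = stats::setNames(numeric(), character()),
    survivalLinks = stats::setNames(numeric(), character()),
    seed = seed,
    ...)
}

## Build a ceilinged CtMatrix directly from a plain matrix
makeCtMatrix <- function(ct, ceiling = 35) {
  if (is.null(rownames(ct))) rownames(ct) <- sprintf("S%02d", seq_len(nrow(ct)))
  if (is.null(colnames(ct))) colnames(ct) <- sprintf("a%02d", seq_len(ncol(ct)))
  mask <- ct >= ceiling
  ct[mask] <- ceiling
  new("CtMatrix", ct = ct,
      curveOk = matrix(TRUE, nrow(ct), ncol(ct), dimnames = dimnames(ct)),
      ceilingMask = mask, ceiling = ceiling)
}

## Run QC + hemolysis + normalization on a generated cohort, in memory
runThroughNormalization <- function(cohort, whitelist = NULL) {
  qc <- plateQc(cohort$plates, cohort$samples)
  hs <- hemolysisScreen(qc$matrix, qc$samples)
  if (is.null(whitelist))
    whitelist <- cohort$truth$whitelistCandidates
  ctrl <- suppressWarnings(
    selectControls(qc$matrix, qc$samples$group, hs$verdicts,
                   whitelist = whitelist))
  norm <- normalizeCt(qc$matrix, ctrl)
  list(qc = qc, hemolysis = hs, controls = ctrl, normalized = norm,
       samples = qc$samples)
}

## Random instance for stability-oracle comparisons
randomStabilityInstance <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(3:10, 1)
    n <- sample(8:30, 1)
    nGroups <- sample(2:3, 1)
    groups <- sample(rep(letters[seq_len(nGroups)], length.out = n))
    mat <- matrix(rnorm(n * k, mean = runif(k, 20, 30),
                        sd = runif(k, 0.2, 1.5)),
                  n, k, byrow = TRUE,
                  dimnames = list(NULL, paste0("g", seq_len(k))))
    ## group-dependent biases on a few genes
    shift <- sample(seq_len(k), 2)
    for (s in shift)
      mat[, s] <- mat[, s] + 0.8 * (groups == "a")
    list(mat = mat, groups = groups)
  })
}


## ----- independent oracles --------------------------------------------------

## NormFinder oracle: explicit loops following the documented formulas
normFinderOracle <- function(mat, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  G <- length(lev)
  k <- ncol(mat)
  zbar <- s2 <- matrix(0, k, G)
  ng <- numeric(G)
  for (gi in seq_len(G)) {
    y <- mat[groups == lev[gi], , drop = FALSE]
    ng[gi] <- nrow(y)
    for (j in seq_len(nrow(y))) y[j, ] <- y[j, ] - mean(y[j, ])
    for (i in seq_len(k)) {
      zbar[i, gi] <- mean(y[, i])
      s2[i, gi] <- sum((y[, i] - zbar[i, gi])^2) / (ng[gi] - 1)
    }
  }
  sigma2 <- matrix(0, k, G)
  for (gi in seq_len(G)) for (i in seq_len(k)) {
    sigma2[i, gi] <- if (k >= 3)
      max(0, (s2[i, gi] - mean(s2[, gi]) / (k - 1)) * k / (k - 2))
    else max(0, s2[i, gi])
  }
  dhat <- zbar - rowMeans(zbar)
  v <- matrix(0, k, G)
  for (gi in seq_len(G)) for (i in seq_len(k)) {
    acc <- ((G - 1) / G)^2 * sigma2[i, gi] / ng[gi]
    for (go in seq_len(G)) if (go != gi)
      acc <- acc + sigma2[i, go] / ng[go] / G^2
    v[i, gi] <- acc
  }
  gamma2 <- max(0, (sum(dhat^2) - sum(v)) / (k * (G - 1)))
  rho <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(G)) {
      shr <- if (gamma2 == 0) 0 else gamma2 / (gamma2 + v[i, gi])
      dstar <- dhat[i, gi] * shr
      w <- v[i, gi] * shr
      acc <- acc + abs(dstar) + sqrt(w + sigma2[i, gi] / ng[gi])
    }
    rho[i] <- acc / G
  }
  stats::setNames(rho, colnames(mat))
}

## Maximally selected cutpoint oracle: enumerate admissible midpoints and
## score each split with survival::survdiff
cutpointOracle <- function(x, time, event, minprop = 0.2) {
  n <- length(x)
  u <- sort(unique(x))
  cuts <- (u[-1] + u[-length(u)]) / 2
  minCount <- max(1L, as.integer(ceiling(minprop * n - 1e-9)))
  best <- NULL
  for (cp in cuts) {
    nl <- sum(x < cp)
    if (min(nl, n - nl) < minCount) next
    g <- factor(x > cp)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    stat <- sqrt(sd$chisq)
    if (is.null(best) || stat > best$stat + 1e-12)
      best <- list(cut = cp, stat = stat)
  }
  best
}

## Cox partial likelihood (Efron) evaluated on a beta grid
coxGridOracle <- function(x, time, event, grid = seq(-8, 8, by = 5e-4)) {
  ll <- vapply(grid, function(b)
    plasmiR:::coxScalarLoglik(b, x, time, event)$loglik, numeric(1))
  grid[which.max(ll)]
}

## Exact two-sided rank-sum p by enumeration of all label assignments
rankSumEnumOracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
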