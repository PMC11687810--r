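## Survival machinery: product-limit estimation, log-rank tests with
## pairwise Bonferroni, maximally selected cutpoint dichotomization, fixed
## survival horizons, and univariate Cox regression (Newton iterations with
## Efron tie handling).

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with the median defined as the smallest observed
#' time at which the survivor function drops to 0.5 or below (undefined when
#' it never does).
#'
#' @param time follow-up times (days).
#' @param event event indicators (1 = event, 0 = censored).
#' @return list: \code{table} (data.frame \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{surv} at distinct event times)
#'   and \code{median} (NA when undefined).
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time >= 0), all(event %in% c(0, 1)))
  o <- order(time)
  time <- time[o]; event <- event[o]
  tu <- sort(unique(time[event == 1]))
  nRisk <- vapply(tu, function(t) sum(time >= t), numeric(1))
  nEvent <- vapply(tu, function(t) sum(time == t & event == 1), numeric(1))
  nCens <- vapply(tu, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  med <- if (length(surv) && any(surv <= 0.5)) tu[which(surv <= 0.5)[1L]]
         else NA_real_
  list(table = data.frame(time = tu, n_risk = nRisk, n_event = nEvent,
                          n_censor = nCens, surv = surv),
       median = med)
}

## Core two-group log-rank quantities: O - E and V for the "in" group.
logrankOEV <- function(time, event, inGroup) {
  tu <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tu) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & inGroup)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & inGroup)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  c(OminusE = O - E, V = V)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square on one degree of freedom.
#' Groups with no at-risk overlap (zero variance) give \code{p = NaN} with a
#' warning.
#'
#' @param time,event follow-up and event indicator.
#' @param group two-level grouping aligned with \code{time}.
#' @return list: \code{chi2}, \code{p}, \code{z} (standardized statistic for
#'   the first group level; positive when that group has excess events).
#' @export
logrankTest <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stopf("logrankTest() needs exactly two groups")
  oev <- logrankOEV(time, event, group == levels(group)[1L])
  if (oev["V"] <= 0) {
    warnf("log-rank variance is zero (no at-risk overlap); p is NaN")
    return(list(chi2 = NaN, p = NaN, z = NaN))
  }
  chi2 <- unname(oev["OminusE"]^2 / oev["V"])
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       z = unname(oev["OminusE"] / sqrt(oev["V"])))
}

#' Pairwise log-rank tests with Bonferroni correction
#'
#' One log-rank test per pair of groups; each raw p is multiplied by the
#' number of pairs and capped at 1.
#'
#' @param time,event follow-up and event indicator.
#' @param group grouping with at least two levels.
#' @return data.frame \code{group1}, \code{group2}, \code{chi2},
#'   \code{raw_p}, \code{adj_p}.
#' @export
pairwiseLogrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  lev <- levels(group)
  stopifnot(length(lev) >= 2L)
  prs <- utils::combn(lev, 2L)
  nPairs <- ncol(prs)
  rows <- lapply(seq_len(nPairs), function(i) {
    sel <- group %in% prs[, i]
    lt <- logrankTest(time[sel], event[sel], group[sel])
    data.frame(group1 = prs[1L, i], group2 = prs[2L, i], chi2 = lt$chi2,
               raw_p = lt$p, adj_p = pmin(1, lt$p * nPairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximally selected log-rank cutpoint
#'
#' Candidate cutpoints are midpoints between consecutive distinct sorted
#' expression values whose induced split leaves at least a fraction
#' \code{minprop} of the samples on each side (side counts of at least the
#' smallest integer >= \code{minprop * n}); the returned cutpoint
#' maximizes the absolute standardized log-rank statistic (ties broken
#' toward the smaller cutpoint). "High" is the more-abundant side (expression
#' above the cutpoint). No small-sample selection correction is applied; the
#' downstream reported p is the ordinary log-rank on the categorized groups,
#' with the usual optimism of optimally selected cutpoints.
#'
#' @param x normalized expression values.
#' @param time,event follow-up and event indicator aligned with \code{x}.
#' @param minprop minimum proportion of samples per side (default 0.2).
#' @return list: \code{cutpoint}, \code{statistic} (signed standardized
#'   log-rank statistic of the high group at the optimum), \code{groups}
#'   (factor \code{high}/\code{low} per sample), \code{minprop},
#'   \code{candidates} (data.frame of candidate cutpoints and statistics).
#' @export
maxSelectedCutpoint <- function(x, time, event, minprop = 0.2) {
  n <- length(x)
  stopifnot(n == length(time), n == length(event), minprop > 0, minprop < 0.5)
  if (n < ceiling(1 / minprop))
    stopf("need at least %d samples for minprop = %.2f",
          ceiling(1 / minprop), minprop)
  cuts <- midpointsBetween(x)
  minCount <- max(1L, as.integer(ceiling(minprop * n - 1e-9)))
  cuts <- cuts[vapply(cuts, function(cp) {
    nl <- sum(x < cp); min(nl, n - nl) >= minCount
  }, logical(1))]
  if (!length(cuts)) stopf("no admissible cutpoint")
  zs <- vapply(cuts, function(cp) {
    oev <- logrankOEV(time, event, x > cp)
    if (oev["V"] <= 0) return(0)
    unname(oev["OminusE"] / sqrt(oev["V"]))
  }, numeric(1))
  best <- which.max(abs(zs))  # first max = smallest cutpoint on ties
  groups <- factor(ifelse(x > cuts[best], "high", "low"),
                   levels = c("low", "high"))
  list(cutpoint = cuts[best], statistic = zs[best], groups = groups,
       minprop = minprop,
       candidates = data.frame(cutpoint = cuts, statistic = zs))
}

#' Administrative censoring at a fixed horizon
#'
#' Fixed-horizon endpoints (for example 183-, 365- and 730-day survival) are
#' encoded by censoring events beyond the horizon at the horizon, which makes
#' event status monotone across increasing horizons.
#'
#' @param time,event follow-up and event indicator.
#' @param horizon horizon in days.
#' @return list \code{time}, \code{event} after truncation.
#' @export
applyHorizon <- function(time, event, horizon) {
  stopifnot(horizon > 0)
  over <- time > horizon
  list(time = pmin(time, horizon),
       event = ifelse(over, 0, event))
}

## ---------------------------------------------------------------------------
## Univariate Cox regression (scalar covariate, Efron ties)
## ---------------------------------------------------------------------------

coxScalarLoglik <- function(beta, x, time, event) {
  s <- exp(beta * x)
  tu <- sort(unique(time[event == 1]))
  ll <- 0; grad <- 0; info <- 0
  for (t in tu) {
    R <- time >= t
    D <- time == t & event == 1
    d <- sum(D)
    sR <- sum(s[R]); sRx <- sum(s[R] * x[R]); sRxx <- sum(s[R] * x[R]^2)
    sD <- sum(s[D]); sDx <- sum(s[D] * x[D]); sDxx <- sum(s[D] * x[D]^2)
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1L) {
      A <- sR - (l / d) * sD
      B <- sRx - (l / d) * sDx
      C <- sRxx - (l / d) * sDxx
      ll <- ll - log(A)
      grad <- grad + sum(x[D]) / d - B / A
      info <- info + C / A - (B / A)^2
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

coxNewtonScalar <- function(x, time, event, tol = 1e-9, maxIter = 60L) {
  beta <- 0
  cur <- coxScalarLoglik(beta, x, time, event)
  flag <- "ok"
  for (it in seq_len(maxIter)) {
    if (!is.finite(cur$info) || cur$info <= 0) break
    step <- cur$grad / cur$info
    newBeta <- beta + step
    nxt <- coxScalarLoglik(newBeta, x, time, event)
    halvings <- 0L
    while ((!is.finite(nxt$loglik) || nxt$loglik < cur$loglik) &&
           halvings < 30L) {   # damped Newton: halve until the likelihood rises
      step <- step / 2
      newBeta <- beta + step
      nxt <- coxScalarLoglik(newBeta, x, time, event)
      halvings <- halvings + 1L
    }
    beta <- newBeta; cur <- nxt
    if (abs(cur$grad) < tol || abs(step) < 1e-12) break
    if (abs(beta) > 15) { flag <- "separation"; break }
  }
  se <- if (flag == "separation" || !is.finite(cur$info) || cur$info <= 0)
    Inf else sqrt(1 / cur$info)
  list(beta = beta, se = se, loglik = cur$loglik, flag = flag)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood maximization by damped Newton iterations with Efron
#' tie handling. Numeric covariates give a single hazard ratio per unit.
#' Categorical covariates are expanded one-versus-rest, one fit per category
#' (so a variable with n categories yields n hazard ratios); categories with
#' a single sample are reported inestimable. Monotone likelihood (perfect
#' separation) is flagged and the confidence interval reported unbounded.
#'
#' @param x covariate (numeric, or factor/character for categorical).
#' @param time,event follow-up and event indicator.
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per fit: \code{level} (\code{NA} for a
#'   numeric covariate), \code{n}, \code{events}, \code{beta}, \code{se},
#'   \code{hr}, \code{lo}, \code{hi}, \code{p}, \code{flag}.
#' @export
coxUnivariate <- function(x, time, event, conf = 0.95) {
  keep <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  stopifnot(length(x) >= 2L, sum(event) >= 1L)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  fitRow <- function(xv, level) {
    if (stats::sd(xv) == 0)
      return(data.frame(level = level, n = length(xv), events = sum(event),
                        beta = NA_real_, se = NA_real_, hr = NA_real_,
                        lo = NA_real_, hi = NA_real_, p = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    fit <- coxNewtonScalar(xv, time, event)
    wald <- if (is.finite(fit$se)) fit$beta / fit$se else NA_real_
    data.frame(level = level, n = length(xv), events = sum(event),
               beta = fit$beta, se = fit$se, hr = exp(fit$beta),
               lo = exp(fit$beta - z * fit$se),
               hi = exp(fit$beta + z * fit$se),
               p = if (is.na(wald)) NA_real_ else
                 2 * stats::pnorm(-abs(wald)),
               flag = fit$flag, stringsAsFactors = FALSE)
  }
  if (is.numeric(x)) {
    if (stats::sd(x) == 0) stopf("covariate is constant")
    out <- fitRow(x, NA_character_)
  } else {
    x <- as.factor(x)
    out <- do.call(rbind, lapply(levels(x), function(lv) {
      if (sum(x == lv) < 2L)
        return(data.frame(level = lv, n = sum(x == lv), events = NA_real_,
                          beta = NA_real_, se = NA_real_, hr = NA_real_,
                          lo = NA_real_, hi = NA_real_, p = NA_real_,
                          flag = "inestimable", stringsAsFactors = FALSE))
      fitRow(as.numeric(x == lv), lv)
    }))
  }
  rownames(out) <- NULL
  out
}
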