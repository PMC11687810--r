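test_that("product-limit estimation reproduces hand-computed curves", {
  ## times {1, 2+, 3}: S = 2/3 on [1,3), 0 at 3; median = 3
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$table$time, c(1, 3))
  expect_equal(km$table$surv, c(2 / 3, 0))
  expect_equal(km$median, 3)
  ## no events: S identically 1, median undefined
  km0 <- kmEstimate(c(5, 8, 2), c(0, 0, 0))
  expect_equal(nrow(km0$table), 0L)
  expect_true(is.na(km0$median))
  ## all events at distinct times: empirical survivor function
  km1 <- kmEstimate(1:5, rep(1, 5))
  expect_equal(km1$table$surv, (4:0) / 5)
  ## S is non-increasing and starts below 1 only after the first event
  set.seed(8)
  tm <- rexp(40, 0.01); ev <- rbinom(40, 1, 0.7)
  km2 <- kmEstimate(tm, ev)
  expect_true(all(diff(km2$table$surv) <= 1e-12))
  expect_true(all(km2$table$surv <= 1))
})

test_that("log-rank matches the hand toy and survdiff on random data", {
  ## A = events at {1,2}, B = events at {3,4}: O_A = 2, E_A = 5/6, V = 17/36
  lt <- logrankTest(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lt$chi2, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-12)
  expect_equal(round(lt$chi2, 2), 2.88)
  ## identical groups: chi2 = 0, p = 1
  lt0 <- logrankTest(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lt0$chi2, 0)
  expect_equal(lt0$p, 1)
  ## symmetric in group order, invariant to time-unit rescaling
  set.seed(9)
  tm <- round(rexp(30, 0.01)) + 1; ev <- rbinom(30, 1, 0.8)
  gr <- rep(c("x", "y"), 15)
  a <- logrankTest(tm, ev, gr)
  b <- logrankTest(tm, ev, factor(gr, levels = c("y", "x")))
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$z, -b$z)
  expect_equal(logrankTest(tm * 7, ev, gr)$chi2, a$chi2)
  ## survdiff cross-check on 20 random censored datasets
  skip_if_not_installed("survival")
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(10:60, 1)
      tm <- round(rexp(n, 0.01)) + 1
      ev <- rbinom(n, 1, 0.75)
      gr <- sample(c("a", "b"), n, replace = TRUE)
    })
    if (length(unique(gr)) < 2 || sum(ev) == 0) next
    mine <- logrankTest(tm, ev, gr)
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ gr)
    expect_equal(mine$chi2, unname(ref$chisq), tolerance = 1e-9)
  }
})

test_that("pairwise log-rank applies the Bonferroni factor per pair", {
  set.seed(10)
  tm <- round(rexp(48, 0.01)) + 1; ev <- rbinom(48, 1, 0.8)
  gr <- rep(c("g1", "g2", "g3", "g4"), each = 12)
  pw <- pairwiseLogrank(tm, ev, gr)
  expect_equal(nrow(pw), 6L)
  expect_equal(pw$adj_p, pmin(1, pw$raw_p * 6))
})

test_that("the maximally selected cutpoint equals exhaustive enumeration", {
  skip_if_not_installed("survival")
  for (seed in 1:30) {
    withr::with_seed(seed, {
      n <- sample(12:60, 1)
      x <- round(rnorm(n), 2)
      tm <- round(rexp(n, 0.01)) + 1
      ev <- rbinom(n, 1, 0.8)
    })
    if (sum(ev) < 2 || length(unique(x)) < 3) next
    mine <- maxSelectedCutpoint(x, tm, ev)
    oracle <- cutpointOracle(x, tm, ev)
    expect_equal(mine$cutpoint, oracle$cut)
    expect_equal(abs(mine$statistic), oracle$stat, tolerance = 1e-9)
  }
})

test_that("cutpoint admissibility and grouping follow the minprop contract", {
  ## expression 1..6 at minprop 0.2: exactly 3 admissible midpoints
  x <- 1:6
  tm <- c(60, 50, 40, 30, 20, 10); ev <- rep(1, 6)
  res <- maxSelectedCutpoint(x, tm, ev, minprop = 0.2)
  expect_equal(nrow(res$candidates), 3L)
  expect_equal(res$candidates$cutpoint, c(2.5, 3.5, 4.5))
  ## anti-monotone survival: the selection equals the brute-force maximizer
  expect_equal(res$cutpoint, cutpointOracle(x, tm, ev)$cut)
  expect_equal(levels(res$groups), c("low", "high"))
  expect_true(all(res$groups[x > res$cutpoint] == "high"))
  ## tied expression values are never split
  x2 <- c(1, 2, 2, 2, 2, 3, 3, 3, 4, 5)
  res2 <- maxSelectedCutpoint(x2, round(rexp(10, 0.01)) + 1,
                              rep(1, 10))
  expect_false(any(abs(res2$candidates$cutpoint - 2) < 1e-9 &
                     res2$candidates$cutpoint != 2))
  expect_true(all(res2$candidates$cutpoint %in% c(1.5, 2.5, 3.5, 4.5)))
  ## degenerate input errors
  expect_error(maxSelectedCutpoint(rep(1, 10), 1:10, rep(1, 10)),
               "no admissible cutpoint")
  expect_error(maxSelectedCutpoint(1:3, 1:3, rep(1, 3)), "at least")
})

test_that("a planted two-group hazard structure is recovered by the cutpoint", {
  hits <- vapply(1:60, function(seed) {
    withr::with_seed(seed, {
      n <- 60
      high <- rbinom(n, 1, 0.5)
      x <- rnorm(n, 0, 0.8) + 3.2 * high
      tm <- ceiling(rexp(n, 0.002 * 3^high))
      ev <- rep(1, n)
    })
    res <- maxSelectedCutpoint(x, tm, ev)
    ## recovered when the induced grouping disagrees with the planted
    ## high/low labels on no more than 10% of samples
    mean((res$groups == "high") != (high == 1)) <= 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("fixed-horizon censoring is monotone across horizons", {
  set.seed(11)
  tm <- ceiling(rexp(200, 1 / 400)); ev <- rbinom(200, 1, 0.85)
  h1 <- applyHorizon(tm, ev, 183)
  h2 <- applyHorizon(tm, ev, 365)
  h3 <- applyHorizon(tm, ev, 730)
  ## an event by 183 days is an event at every later horizon
  expect_true(all(h2$event[h1$event == 1] == 1))
  expect_true(all(h3$event[h2$event == 1] == 1))
  expect_true(all(h1$time <= 183))
})

test_that("Cox estimates match a grid-search partial-likelihood maximizer", {
  ## fixed toy with ties to exercise the Efron terms
  x <- c(1, 0, 1, 0, 1, 0)
  tm <- c(2, 2, 4, 5, 6, 7)
  ev <- c(1, 1, 1, 0, 1, 1)
  fit <- coxUnivariate(x, tm, ev)
  expect_equal(fit$beta, coxGridOracle(x, tm, ev), tolerance = 1e-3)
  ## larger tied toy
  x2 <- c(0, 0, 1, 1, 1, 0, 1, 0, 1, 1)
  tm2 <- c(3, 3, 3, 5, 5, 8, 8, 9, 10, 12)
  ev2 <- c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1)
  fit2 <- coxUnivariate(x2, tm2, ev2)
  expect_equal(fit2$beta, coxGridOracle(x2, tm2, ev2), tolerance = 1e-3)
})

test_that("Cox agrees with coxph (Efron ties) on random censored data", {
  skip_if_not_installed("survival")
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(20:80, 1)
      x <- rnorm(n)
      tm <- ceiling(rexp(n, 0.01 * exp(0.4 * x)))
      ev <- rbinom(n, 1, 0.8)
    })
    if (sum(ev) < 3) next
    mine <- coxUnivariate(x, tm, ev)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "efron")
    expect_equal(mine$beta, unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(mine$se, unname(sqrt(stats::vcov(ref)[1, 1])),
                 tolerance = 1e-6)
  }
})

test_that("Cox is calibrated under the null and under a planted hazard", {
  ## covariate independent of survival at n = 1000: HR within a sanity band
  withr::with_seed(5, {
    x <- rnorm(1000)
    tm <- ceiling(rexp(1000, 1 / 300)); ev <- rbinom(1000, 1, 0.85)
  })
  expect_true(coxUnivariate(x, tm, ev)$hr > 0.85 &&
                coxUnivariate(x, tm, ev)$hr < 1.18)
  ## planted HR = 2 (binary), n = 200 x 100 reps: mean beta within 5% of
  ## log 2 and CI coverage in [90%, 98%]
  res <- vapply(1:100, function(seed) {
    withr::with_seed(3000 + seed, {
      x <- rbinom(200, 1, 0.5)
      tm <- ceiling(rexp(200, 0.005 * 2^x))
      cn <- ceiling(rexp(200, 0.001))
      ev <- as.integer(tm <= cn); tt <- pmin(tm, cn)
    })
    fit <- coxUnivariate(x, tt, ev)
    c(beta = fit$beta, covered = fit$lo <= 2 && 2 <= fit$hi)
  }, numeric(2))
  expect_lt(abs(mean(res["beta", ]) / log(2) - 1), 0.05)
  expect_gte(mean(res["covered", ]), 0.90)
  expect_lte(mean(res["covered", ]), 0.98)
})

test_that("categorical covariates yield one-vs-rest rows with flags", {
  set.seed(12)
  g <- sample(c("humerus", "radius", "femur"), 60, replace = TRUE)
  tm <- ceiling(rexp(60, 1 / 300 * ifelse(g == "humerus", 2.5, 1)))
  ev <- rbinom(60, 1, 0.85)
  fit <- coxUnivariate(g, tm, ev)
  expect_equal(nrow(fit), 3L)
  expect_setequal(fit$level, c("humerus", "radius", "femur"))
  expect_true(all(fit$lo <= fit$hr & fit$hr <= fit$hi, na.rm = TRUE))
  ## a single-sample category is inestimable
  g2 <- c(g[-1], "ulna")
  fit2 <- coxUnivariate(g2, tm, ev)
  expect_equal(fit2$flag[fit2$level == "ulna"], "inestimable")
  ## perfect separation is flagged with an unbounded CI
  xs <- as.numeric(seq_len(20) > 10)
  tms <- c(seq(100, 1000, length.out = 10), seq(1, 10, length.out = 10))
  fit3 <- coxUnivariate(xs, tms, rep(1, 20))
  expect_equal(fit3$flag, "separation")
  expect_true(!is.finite(fit3$se) || fit3$hi == Inf)
})
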