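test_that("classification growth handles separable and degenerate inputs", {
  set.seed(20)
  x <- matrix(c(runif(20, -2, -0.5), runif(20, 0.5, 2)), ncol = 1,
              dimnames = list(NULL, "m1"))
  y <- rep(c("control", "case"), each = 20)
  tr <- growClassificationTree(x, y)
  expect_equal(nLeaves(tr), 2L)
  expect_equal(treeNodes(tr)$var[1], "m1")
  pred <- plasmiR:::predictClassification(tr, x)
  expect_equal(mean(pred$pred == y), 1)
  ## pure-class input collapses to a single leaf
  pure <- growClassificationTree(x, rep("case", 40))
  expect_equal(nrow(treeNodes(pure)), 1L)
  ## empty input errors
  expect_error(growClassificationTree(x[0, , drop = FALSE], character()),
               "empty")
})

test_that("the root split agrees with rpart on random two-class data", {
  skip_if_not_installed("rpart")
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 120
      X <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("v", 1:4)))
      y <- factor(ifelse(X[, 2] + rnorm(n, 0, 0.8) > 0, "case", "control"))
    })
    mine <- growClassificationTree(X, y)
    ref <- rpart::rpart(y ~ ., data = data.frame(X, y),
                        method = "class",
                        control = rpart::rpart.control(minsplit = 20,
                                                       minbucket = 7,
                                                       cp = 0.01,
                                                       maxsurrogate = 0,
                                                       maxcompete = 0))
    refVar <- as.character(ref$frame$var[1])
    refCut <- ref$splits[1, "index"]
    expect_equal(treeNodes(mine)$var[1], refVar)
    expect_equal(treeNodes(mine)$threshold[1], unname(refCut),
                 tolerance = 1e-9)
  }
})

test_that("survival trees split on planted rate structure", {
  withr::with_seed(21, {
    n <- 200
    marker <- c(rnorm(n / 2, 0), rnorm(n / 2, 4))
    rate <- ifelse(marker > 2, 1.0, 0.1)
    tm <- rexp(n, rate) + 0.01
    X <- cbind(m = marker, noise = rnorm(n))
  })
  tr <- growSurvivalTree(X, tm, rep(1, n))
  nd <- treeNodes(tr)
  expect_equal(nd$var[1], "m")
  children <- nd[!is.na(nd$parent) & nd$parent == 1, ]
  rr <- max(children$rate) / min(children$rate)
  expect_lt(abs(rr / 10 - 1), 0.3)
  ## no events is an error
  expect_error(growSurvivalTree(X, tm, rep(0, n)), "no events")
})

test_that("cost-complexity path is nested with strictly decreasing sizes", {
  withr::with_seed(22, {
    X <- matrix(rnorm(100 * 5), 100, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- factor(ifelse(X[, 1] + 0.6 * X[, 2] + rnorm(100) > 0,
                       "case", "control"))
  })
  tr <- growClassificationTree(X, y, cp = 0.001)
  path <- costComplexityPath(tr)
  sizes <- vapply(path, `[[`, numeric(1), "size")
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  expect_true(all(diff(sizes) < 0))
  expect_true(all(diff(alphas) >= 0))
  expect_equal(sizes[length(sizes)], 1)
  ## every path tree is a node-subset of the grown tree
  for (p in path)
    expect_true(all(p$nodes$id %in% treeNodes(tr)$id))
})

test_that("cross-validated pruning returns a subtree with a full trace", {
  withr::with_seed(23, {
    X <- matrix(rnorm(120 * 6), 120, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- factor(ifelse(X[, 3] + rnorm(120, 0, 0.7) > 0, "case", "control"))
  })
  grown <- growClassificationTree(X, y, cp = 0.001)
  pruned <- crossvalPrune(grown, X, y, k = 10, seed = 5)
  expect_true(all(treeNodes(pruned)$id %in% treeNodes(grown)$id))
  tr <- pruneTrace(pruned)
  expect_equal(sum(tr$chosen), 1L)
  expect_lte(tr$cv_error[tr$chosen], tr$cv_error[1] + 1e-12)
  ## resubstitution accuracy is non-increasing under pruning
  accOf <- function(t) mean(plasmiR:::predictClassification(t, X)$pred == y)
  expect_lte(accOf(pruned), accOf(grown) + 1e-12)
  ## pruning is deterministic given the seed
  pruned2 <- crossvalPrune(grown, X, y, k = 10, seed = 5)
  expect_identical(treeNodes(pruned), treeNodes(pruned2))
  ## k beyond n errors; a root-only tree passes through unchanged
  expect_error(crossvalPrune(grown, X, y, k = 500), "exceed")
  rootOnly <- growClassificationTree(X, y, cp = 10)
  out <- crossvalPrune(rootOnly, X, y, k = 10, seed = 1)
  expect_equal(nrow(treeNodes(out)), 1L)
  expect_equal(nrow(pruneTrace(out)), 1L)
})

test_that("noise-only survival covariates usually prune to the root", {
  roots <- vapply(1:10, function(seed) {
    withr::with_seed(600 + seed, {
      n <- 60
      X <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("v", 1:10)))
      tm <- ceiling(rexp(n, 1 / 300)); ev <- rbinom(n, 1, 0.85)
    })
    tr <- tryCatch(growSurvivalTree(X, tm, ev), error = function(e) NULL)
    if (is.null(tr)) return(TRUE)
    pr <- crossvalPrune(tr, X, list(time = tm, event = ev), k = 10,
                        seed = seed)
    nrow(treeNodes(pr)) == 1L
  }, logical(1))
  expect_gte(mean(roots), 0.6)
})

test_that("classifier metrics reproduce confusion-count arithmetic", {
  m <- confusionMetrics(tp = 12, fn = 1, fp = 2, tn = 2)
  expect_equal(round(m$accuracy, 3), 0.824)   # 14/17
  expect_equal(round(m$recall, 3), 0.923)     # 12/13
  expect_equal(round(m$precision, 3), 0.857)  # 12/14
  ## AUC: perfect ranking -> 1; constant scores on balanced labels -> 0.5
  expect_equal(aucRank(1:10, rep(c(FALSE, TRUE), each = 5)), 1)
  expect_equal(aucRank(rep(0.5, 10), rep(c(FALSE, TRUE), each = 5)), 0.5)
  expect_true(is.na(aucRank(1:5, rep(TRUE, 5))))
})

test_that("evaluateClassifier scores a fitted tree on held-out data", {
  withr::with_seed(24, {
    x <- matrix(c(rnorm(30, -2), rnorm(30, 2)), ncol = 1,
                dimnames = list(NULL, "m"))
    y <- rep(c("control", "case"), each = 30)
    xt <- matrix(c(rnorm(10, -2), rnorm(10, 2)), ncol = 1,
                 dimnames = list(NULL, "m"))
    yt <- rep(c("control", "case"), each = 10)
  })
  tr <- growClassificationTree(x, y)
  ev <- evaluateClassifier(tr, xt, yt)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$confusion$tp + ev$confusion$fn, 10)
})

test_that("group assignment is deterministic and comparisons follow the pairs", {
  withr::with_seed(25, {
    n <- 120
    X <- cbind(m1 = rnorm(n) + rep(c(0, 3), each = n / 2),
               m2 = rnorm(n))
    tm <- ceiling(rexp(n, 1 / 300 * ifelse(X[, "m1"] > 1.5, 3, 1)))
    ev <- rep(1, n)
  })
  tr <- growSurvivalTree(X, tm, ev)
  g1 <- assignGroups(tr, X)
  g2 <- assignGroups(tr, X)
  expect_identical(g1, g2)
  cmp <- compareGroups(g1, tm, ev, tree = tr)
  k <- nlevels(droplevels(g1))
  expect_equal(nrow(cmp$pairwise), choose(k, 2))
  expect_equal(cmp$pairwise$adj_p,
               pmin(1, cmp$pairwise$raw_p * choose(k, 2)))
  ## single-leaf tree: one group, no comparisons
  rootOnly <- growSurvivalTree(X, tm, ev, cp = 10)
  cmp1 <- compareGroups(assignGroups(rootOnly, X), tm, ev, tree = rootOnly)
  expect_equal(nrow(cmp1$groups), 1L)
  expect_null(cmp1$pairwise)
})

test_that("a planted two-marker diagnostic structure is recovered in order", {
  withr::with_seed(26, {
    n <- 120
    X <- matrix(rnorm(n * 8, 0, 0.8), n, 8,
                dimnames = list(NULL, paste0("m", 1:8)))
    case <- rep(c(TRUE, FALSE), each = n / 2)
    X[case, "m3"] <- X[case, "m3"] + 2.4   # dominant marker
    X[case, "m5"] <- X[case, "m5"] + 1.6   # secondary marker
    y <- factor(ifelse(case, "case", "control"))
  })
  tr <- crossvalPrune(growClassificationTree(X, y), X, y, k = 10, seed = 2)
  nd <- treeNodes(tr)
  expect_equal(nd$var[1], "m3")
  expect_true(all(stats::na.omit(nd$var) %in% c("m3", "m5")))
})

test_that("missing predictor values are routed to the majority branch", {
  withr::with_seed(27, {
    x <- matrix(c(rnorm(30, -2), rnorm(30, 2)), ncol = 1,
                dimnames = list(NULL, "m"))
    y <- rep(c("control", "case"), each = 30)
  })
  tr <- growClassificationTree(x, y)
  xm <- matrix(NA_real_, 1, 1, dimnames = list(NULL, "m"))
  expect_warning(g <- assignGroups(tr, xm), "majority branch")
  expect_length(g, 1L)
})
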