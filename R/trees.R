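## CART-style recursive partitioning: classification trees (Gini) for
## diagnosis and survival trees (exponential-model deviance) for prognosis,
## grown unrestricted over the marker panel and pruned by cross-validated
## cost-complexity.

defaultTreeParams <- function(...) {
  p <- list(minsplit = 20L, minbucket = 7L, cp = 0.01)
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

## Gini "impurity mass" of a node: n * (1 - sum p_c^2)
giniMass <- function(n, nPos) (n^2 - nPos^2 - (n - nPos)^2) / n

## Exponential-model deviance of a node (delta in {0,1}):
##   D = 2 * sum_i [ delta_i log(delta_i / (lambda t_i)) + (lambda t_i - delta_i) ]
## with lambda = sum(delta)/sum(t); the (lambda t - delta) terms sum to 0 at
## the node's own MLE rate.
expDeviance <- function(d, totTime, sumLogTimeEvents) {
  if (d == 0) return(0)
  -2 * d * log(d / totTime) - 2 * sumLogTimeEvents
}

## Best split of one node for one variable (vectorized over candidate cuts).
## Returns c(threshold, improve) or NULL.
bestSplitVar <- function(xv, type, yPos, d, tm, minbucket, parentCrit) {
  xv <- unname(xv)
  o <- order(xv)
  xs <- xv[o]
  n <- length(xs)
  cutIdx <- which(xs[-n] < xs[-1L])           # left block = 1..i
  cutIdx <- cutIdx[cutIdx >= minbucket & (n - cutIdx) >= minbucket]
  if (!length(cutIdx)) return(NULL)
  if (type == "classification") {
    cumPos <- cumsum(yPos[o])
    nL <- cutIdx
    posL <- cumPos[cutIdx]
    totPos <- cumPos[n]
    critL <- giniMass(nL, posL)
    critR <- giniMass(n - nL, totPos - posL)
  } else {
    cumD <- cumsum(d[o]); cumT <- cumsum(tm[o])
    logt <- ifelse(d[o] == 1, log(tm[o]), 0)
    cumLt <- cumsum(logt)
    dL <- cumD[cutIdx]; tL <- cumT[cutIdx]; ltL <- cumLt[cutIdx]
    dR <- cumD[n] - dL; tR <- cumT[n] - tL; ltR <- cumLt[n] - ltL
    devPart <- function(dd, tt, lt)
      ifelse(dd == 0, 0, -2 * dd * log(dd / tt) - 2 * lt)
    critL <- devPart(dL, tL, ltL)
    critR <- devPart(dR, tR, ltR)
  }
  improve <- parentCrit - critL - critR
  best <- which.max(improve)
  c(threshold = (xs[cutIdx[best]] + xs[cutIdx[best] + 1L]) / 2,
    improve = improve[best])
}

## Shared grower. type = "classification" | "survival".
growTreeInternal <- function(type, X, yPos = NULL, time = NULL, event = NULL,
                             params) {
  n <- nrow(X)
  vars <- colnames(X)
  rows <- list()
  counter <- new.env(parent = emptyenv())
  counter$nextId <- 1L

  nodeStats <- function(idx) {
    if (type == "classification") {
      np <- sum(yPos[idx]); nn <- length(idx) - np
      list(crit = giniMass(length(idx), np), risk = min(np, nn),
           n_pos = np, n_neg = nn,
           prob_pos = np / length(idx), pred = np >= nn)
    } else {
      d <- sum(event[idx]); tt <- sum(time[idx])
      slt <- sum(ifelse(event[idx] == 1, log(time[idx]), 0))
      dev <- expDeviance(d, tt, slt)
      list(crit = dev, risk = dev, events = d, exposure = tt,
           rate = d / tt)
    }
  }

  rootCrit <- nodeStats(seq_len(n))$crit

  build <- function(idx, parent, depth) {
    id <- counter$nextId
    counter$nextId <- id + 1L
    st <- nodeStats(idx)
    row <- list(id = id, parent = parent, left = NA_integer_,
                right = NA_integer_, var = NA_character_,
                threshold = NA_real_, depth = depth, n = length(idx),
                improve = NA_real_, risk = st$risk)
    if (type == "classification") {
      row$n_pos <- st$n_pos; row$n_neg <- st$n_neg
      row$prob_pos <- st$prob_pos; row$pred <- st$pred
    } else {
      row$events <- st$events; row$exposure <- st$exposure
      row$rate <- st$rate
    }

    pure <- if (type == "classification") st$risk == 0 else st$crit <= 0
    canSplit <- length(idx) >= params$minsplit && !pure
    bestVar <- NULL
    if (canSplit) {
      bestImp <- 0
      for (v in vars) {
        sp <- bestSplitVar(X[idx, v], type, yPos[idx], event[idx], time[idx],
                           params$minbucket, st$crit)
        if (!is.null(sp) && sp["improve"] > bestImp &&
            sp["improve"] > params$cp * rootCrit) {
          bestImp <- sp["improve"]
          bestVar <- list(var = v, threshold = unname(sp["threshold"]),
                          improve = unname(sp["improve"]))
        }
      }
    }
    rows[[id]] <<- row
    if (!is.null(bestVar)) {
      leftIdx <- idx[X[idx, bestVar$var] < bestVar$threshold]
      rightIdx <- idx[X[idx, bestVar$var] >= bestVar$threshold]
      rows[[id]]$var <<- bestVar$var
      rows[[id]]$threshold <<- bestVar$threshold
      rows[[id]]$improve <<- bestVar$improve
      rows[[id]]$left <<- build(leftIdx, id, depth + 1L)
      rows[[id]]$right <<- build(rightIdx, id, depth + 1L)
    }
    id
  }
  build(seq_len(n), NA_integer_, 0L)

  nodes <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (type == "survival")
    nodes$rate_ratio <- nodes$rate / nodes$rate[1L]
  new("DecisionTree", type = type, nodes = nodes, params = params,
      pruneTrace = data.frame())
}

coerceTreeMatrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Grow a classification tree
#'
#' Binary recursive partitioning minimizing Gini impurity; deterministic
#' given the data. A split must improve the Gini criterion by more than
#' \code{cp} times the root impurity and respect \code{minsplit} /
#' \code{minbucket}.
#'
#' @param X numeric matrix or data.frame of predictors (samples x
#'   variables).
#' @param labels two-level factor/character class labels.
#' @param positive the positive class (defaults to \code{"case"} when
#'   present, else the second level).
#' @param minsplit,minbucket,cp growth parameters (defaults 20, 7, 0.01).
#' @return a [DecisionTree-class] of type "classification".
#' @export
growClassificationTree <- function(X, labels, positive = NULL,
                                   minsplit = 20L, minbucket = 7L,
                                   cp = 0.01) {
  X <- coerceTreeMatrix(X)
  if (nrow(X) == 0L) stopf("empty predictor matrix")
  labels <- as.factor(labels)
  stopifnot(nrow(X) == length(labels))
  if (nlevels(droplevels(labels)) > 2L)
    stopf("only two-class problems are supported")
  if (is.null(positive))
    positive <- if ("case" %in% levels(labels)) "case"
                else levels(labels)[nlevels(labels)]
  stopifnot(positive %in% levels(labels))
  negative <- setdiff(levels(droplevels(labels)), positive)
  negative <- if (length(negative)) negative else paste0("not_", positive)
  params <- defaultTreeParams(minsplit = minsplit, minbucket = minbucket,
                              cp = cp, positive = positive,
                              negative = negative)
  growTreeInternal("classification", X, yPos = labels == positive,
                   params = params)
}

#' Grow a survival tree
#'
#' Recursive partitioning with exponential-model deviance splitting: each
#' node fits an event rate \eqn{\lambda =} events / total exposure and the
#' chosen split maximizes the deviance reduction
#' \eqn{D_{parent} - (D_{left} + D_{right})}. Leaves report the rate ratio
#' against the root — the tree's "hazard ratio" per group.
#'
#' @param X numeric matrix or data.frame of predictors.
#' @param time,event follow-up (days) and event indicator; at least one
#'   event is required.
#' @param minsplit,minbucket,cp growth parameters (defaults 20, 7, 0.01).
#' @return a [DecisionTree-class] of type "survival".
#' @export
growSurvivalTree <- function(X, time, event, minsplit = 20L, minbucket = 7L,
                             cp = 0.01) {
  X <- coerceTreeMatrix(X)
  if (nrow(X) == 0L) stopf("empty predictor matrix")
  stopifnot(nrow(X) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1L) stopf("no events; cannot grow a survival tree")
  params <- defaultTreeParams(minsplit = minsplit, minbucket = minbucket,
                              cp = cp)
  growTreeInternal("survival", X, time = time, event = event,
                   params = params)
}

## ---------------------------------------------------------------------------
## Cost-complexity pruning
## ---------------------------------------------------------------------------

## Leaf ids under each node, on the flat table
subtreeLeaves <- function(nodes, id) {
  nd <- nodes[nodes$id == id, ]
  if (is.na(nd$left)) return(id)
  c(subtreeLeaves(nodes, nd$left), subtreeLeaves(nodes, nd$right))
}

dropSubtree <- function(nodes, id) {
  nd <- nodes[nodes$id == id, ]
  if (!is.na(nd$left)) {
    nodes <- dropSubtree(nodes, nd$left)
    nodes <- dropSubtree(nodes, nd$right)
    nodes <- nodes[!nodes$id %in% c(nd$left, nd$right), , drop = FALSE]
    i <- which(nodes$id == id)
    nodes$left[i] <- NA_integer_
    nodes$right[i] <- NA_integer_
    nodes$var[i] <- NA_character_
    nodes$threshold[i] <- NA_real_
    nodes$improve[i] <- NA_real_
  }
  nodes
}

#' Weakest-link cost-complexity path
#'
#' The nested sequence of subtrees obtained by repeatedly collapsing the
#' internal node with the smallest per-leaf risk reduction
#' \eqn{g(t) = (R(t) - R(T_t)) / (|T_t| - 1)}, from the full tree down to
#' the root, with the complexity value \eqn{\alpha} at which each subtree
#' becomes optimal. Risk is the misclassification count (classification) or
#' the exponential deviance (survival).
#'
#' @param tree a [DecisionTree-class].
#' @return list of entries \code{alpha}, \code{nodes} (pruned node table),
#'   \code{size} (leaves), \code{risk} (resubstitution risk); sizes strictly
#'   decreasing.
#' @export
costComplexityPath <- function(tree) {
  nodes <- treeNodes(tree)
  path <- list()
  alpha <- 0
  repeat {
    leaves <- nodes$id[is.na(nodes$left)]
    path[[length(path) + 1L]] <- list(
      alpha = alpha, nodes = nodes, size = length(leaves),
      risk = sum(nodes$risk[nodes$id %in% leaves]))
    internal <- nodes$id[!is.na(nodes$left)]
    if (!length(internal)) break
    g <- vapply(internal, function(id) {
      lv <- subtreeLeaves(nodes, id)
      (nodes$risk[nodes$id == id] - sum(nodes$risk[nodes$id %in% lv])) /
        (length(lv) - 1L)
    }, numeric(1))
    alpha <- max(min(g), alpha)   # weakest link; keep alphas non-decreasing
    for (id in internal[g <= min(g) + 1e-12])
      if (id %in% nodes$id && !is.na(nodes$left[nodes$id == id]))
        nodes <- dropSubtree(nodes, id)
  }
  path
}

## The path subtree optimal at complexity alpha
pruneAtAlpha <- function(path, alpha) {
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  path[[max(which(alphas <= alpha + 1e-12))]]
}

withNodes <- function(tree, nodes, trace = NULL) {
  new("DecisionTree", type = treeType(tree), nodes = nodes,
      params = tree@params,
      pruneTrace = trace %||% tree@pruneTrace)
}

## ---------------------------------------------------------------------------
## Prediction / routing
## ---------------------------------------------------------------------------

routeRows <- function(tree, X) {
  X <- coerceTreeMatrix(X)
  nodes <- treeNodes(tree)
  need <- unique(stats::na.omit(nodes$var))
  if (!all(need %in% colnames(X)))
    stopf("predictor matrix lacks variable(s): %s",
          paste(setdiff(need, colnames(X)), collapse = ", "))
  warned <- FALSE
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    repeat {
      nd <- nodes[nodes$id == id, ]
      if (is.na(nd$left)) return(id)
      xv <- X[i, nd$var]
      if (is.na(xv)) {   # surrogate-free default: follow the larger child
        if (!warned) { warnf("missing value routed to the majority branch")
                       warned <<- TRUE }
        nl <- nodes$n[nodes$id == nd$left]
        nr <- nodes$n[nodes$id == nd$right]
        id <- if (nl >= nr) nd$left else nd$right
      } else id <- if (xv < nd$threshold) nd$left else nd$right
    }
  }, integer(1))
}

#' Assign samples to tree leaves
#'
#' Deterministic routing of each row to its leaf; missing predictor values
#' follow the larger child with a warning.
#'
#' @param tree a [DecisionTree-class].
#' @param X predictor matrix/data.frame containing the tree's variables.
#' @return factor of leaf labels (\code{node<id>}), levels in node order.
#' @export
assignGroups <- function(tree, X) {
  leafIds <- treeNodes(tree)$id[is.na(treeNodes(tree)$left)]
  ids <- routeRows(tree, X)
  factor(paste0("node", ids), levels = paste0("node", sort(leafIds)))
}

predictClassification <- function(tree, X) {
  stopifnot(treeType(tree) == "classification")
  nodes <- treeNodes(tree)
  ids <- routeRows(tree, X)
  i <- match(ids, nodes$id)
  data.frame(
    leaf = ids,
    prob_pos = nodes$prob_pos[i],
    pred = ifelse(nodes$pred[i], tree@params$positive,
                  tree@params$negative),
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Cross-validated pruning
## ---------------------------------------------------------------------------

#' Cross-validated cost-complexity pruning
#'
#' Builds the weakest-link path of the grown tree, estimates the
#' out-of-sample error of each complexity value by k-fold cross-validation
#' (re-growing the tree within each training fold and pruning it at the
#' geometric means of consecutive path alphas), and returns the subtree at
#' the complexity with the minimum CV error, ties resolved toward the
#' smaller tree. Classification error is the misclassification rate;
#' survival error is the held-out mean exponential deviance under the
#' training-fold leaf rates (floored at half an event over the training
#' exposure so that a zero-rate leaf cannot produce an infinite deviance).
#'
#' @param tree a grown [DecisionTree-class].
#' @param X the training predictors the tree was grown on.
#' @param outcome for classification trees, the label vector; for survival
#'   trees, a list \code{list(time =, event =)}.
#' @param k number of folds (default 10; must not exceed the sample count).
#' @param seed integer seed for the fold assignment.
#' @return the pruned [DecisionTree-class], with the path and CV errors in
#'   \code{pruneTrace()} (columns \code{alpha}, \code{cp} — alpha relative
#'   to the root risk —, \code{size}, \code{resub_error}, \code{cv_error},
#'   \code{cv_se}, \code{chosen}).
#' @export
crossvalPrune <- function(tree, X, outcome, k = 10L, seed = 1L) {
  X <- coerceTreeMatrix(X)
  n <- nrow(X)
  if (k > n) stopf("k = %d folds exceed the %d samples", k, n)
  type <- treeType(tree)
  if (type == "classification") {
    labels <- as.factor(outcome)
    yPos <- labels == tree@params$positive
  } else {
    time <- outcome$time; event <- outcome$event
  }
  path <- costComplexityPath(tree)
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  m <- length(path)
  rootRisk <- path[[m]]$risk

  perSampleLoss <- function(nodes, Xtest, idxTest, rateFloor = NULL) {
    fitted <- withNodes(tree, nodes)
    ids <- routeRows(fitted, Xtest)
    i <- match(ids, nodes$id)
    if (type == "classification") {
      predPos <- nodes$pred[i]
      as.numeric(predPos != yPos[idxTest])
    } else {
      lam <- nodes$rate[i]
      if (!is.null(rateFloor)) lam <- pmax(lam, rateFloor)
      mu <- lam * time[idxTest]
      d <- event[idxTest]
      2 * (ifelse(d == 1, -log(mu), 0) + (mu - d))
    }
  }

  if (m == 1L) {
    trace <- data.frame(alpha = 0, cp = NA_real_, size = path[[1L]]$size,
                        resub_error = path[[1L]]$risk / n,
                        cv_error = NA_real_, cv_se = NA_real_, chosen = TRUE)
    return(withNodes(tree, path[[1L]]$nodes, trace))
  }

  betas <- c(sqrt(alphas[-m] * alphas[-1L]), Inf)
  folds <- withSeed(seed, sample(rep(seq_len(k), length.out = n)))
  lossMat <- matrix(NA_real_, n, m)
  for (f in seq_len(k)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    foldTree <- if (type == "classification") {
      growTreeInternal("classification", X[trainIdx, , drop = FALSE],
                       yPos = yPos[trainIdx], params = tree@params)
    } else {
      growTreeInternal("survival", X[trainIdx, , drop = FALSE],
                       time = time[trainIdx], event = event[trainIdx],
                       params = tree@params)
    }
    foldPath <- costComplexityPath(foldTree)
    floorRate <- if (type == "survival") 0.5 / sum(time[trainIdx]) else NULL
    for (j in seq_len(m)) {
      sub <- pruneAtAlpha(foldPath, betas[j])
      lossMat[testIdx, j] <- perSampleLoss(sub$nodes,
                                           X[testIdx, , drop = FALSE],
                                           testIdx, floorRate)
    }
  }
  cvErr <- colMeans(lossMat)
  cvSe <- apply(lossMat, 2L, stats::sd) / sqrt(n)
  best <- which(cvErr <= min(cvErr) + 1e-12)
  chosen <- best[length(best)]          # path sizes decrease: last = smallest
  trace <- data.frame(
    alpha = alphas,
    cp = if (rootRisk > 0) alphas / rootRisk else NA_real_,
    size = vapply(path, `[[`, numeric(1), "size"),
    resub_error = vapply(path, `[[`, numeric(1), "risk") / n,
    cv_error = cvErr, cv_se = cvSe,
    chosen = seq_len(m) == chosen)
  withNodes(tree, path[[chosen]]$nodes, trace)
}

## ---------------------------------------------------------------------------
## Evaluation
## ---------------------------------------------------------------------------

#' Classifier metrics from confusion counts
#'
#' Accuracy, precision and recall with the case group as the positive class.
#'
#' @param tp,fn,fp,tn confusion counts (positives = cases).
#' @return list \code{accuracy}, \code{precision}, \code{recall}.
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  list(accuracy = (tp + tn) / (tp + fn + fp + tn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic of the
#' scores (ties mid-ranked). Undefined (NA) for single-class labels.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param positive logical; TRUE for positives.
#' @return AUC in [0, 1], or NA.
#' @export
aucRank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classification tree on test data
#'
#' Accuracy, precision and recall (positive class = the tree's positive
#' class) and the rank AUC of the leaf class-probability scores.
#'
#' @param tree a fitted classification [DecisionTree-class].
#' @param X test predictors.
#' @param labels test labels.
#' @return list: \code{accuracy}, \code{precision}, \code{recall},
#'   \code{auc}, \code{confusion} (list tp/fn/fp/tn).
#' @export
evaluateClassifier <- function(tree, X, labels) {
  stopifnot(treeType(tree) == "classification")
  pred <- predictClassification(tree, X)
  pos <- as.character(labels) == tree@params$positive
  predPos <- pred$pred == tree@params$positive
  tp <- sum(predPos & pos); fp <- sum(predPos & !pos)
  fn <- sum(!predPos & pos); tn <- sum(!predPos & !pos)
  m <- confusionMetrics(tp, fn, fp, tn)
  c(m, list(auc = aucRank(pred$prob_pos, pos),
            confusion = list(tp = tp, fn = fn, fp = fp, tn = tn)))
}

#' Compare survival between tree groups
#'
#' Kaplan-Meier summary per group (size, events, median survival), all
#' pairwise log-rank tests with Bonferroni adjustment, and per-pair hazard
#' ratios. The per-group HR against the whole cohort can be taken as the
#' tree's leaf rate ratio (\code{hrMethod = "rate_ratio"}, reading it off
#' the fitted tree passed via \code{tree}) or from a Cox fit on the leaf
#' indicator (\code{hrMethod = "cox"}).
#'
#' @param groups factor of group labels per sample (e.g. [assignGroups()]).
#' @param time,event follow-up and event indicator.
#' @param tree optional fitted survival [DecisionTree-class] (for
#'   \code{hrMethod = "rate_ratio"}).
#' @param hrMethod "rate_ratio" (default) or "cox".
#' @return list: \code{groups} (data.frame with \code{group}, \code{n},
#'   \code{events}, \code{median}, \code{hr}), \code{pairwise} (data.frame
#'   from [pairwiseLogrank()] plus per-pair Cox HR and CI).
#' @export
compareGroups <- function(groups, time, event, tree = NULL,
                          hrMethod = c("rate_ratio", "cox")) {
  hrMethod <- match.arg(hrMethod)
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  perGroup <- do.call(rbind, lapply(lev, function(g) {
    sel <- groups == g
    km <- kmEstimate(time[sel], event[sel])
    hr <- if (hrMethod == "rate_ratio" && !is.null(tree) &&
              grepl("^node", g)) {
      nd <- treeNodes(tree)
      nd$rate_ratio[nd$id == as.integer(sub("node", "", g))]
    } else {
      fit <- coxUnivariate(as.numeric(sel), time, event)
      fit$hr[1L]
    }
    data.frame(group = g, n = sum(sel), events = sum(event[sel]),
               median = km$median, hr = hr, stringsAsFactors = FALSE)
  }))
  pw <- if (length(lev) >= 2L) {
    pw0 <- pairwiseLogrank(time, event, groups)
    hrci <- t(vapply(seq_len(nrow(pw0)), function(i) {
      sel <- groups %in% c(pw0$group1[i], pw0$group2[i])
      fit <- coxUnivariate(as.numeric(groups[sel] == pw0$group1[i]),
                           time[sel], event[sel])
      c(fit$hr[1L], fit$lo[1L], fit$hi[1L])
    }, numeric(3)))
    cbind(pw0, data.frame(hr = hrci[, 1L], hr_lo = hrci[, 2L],
                          hr_hi = hrci[, 3L]))
  } else NULL
  list(groups = perGroup, pairwise = pw)
}

## ---------------------------------------------------------------------------
## Rendering / serialization
## ---------------------------------------------------------------------------

#' Render a tree as indented text
#' @param tree a [DecisionTree-class].
#' @return character vector, one line per node.
#' @export
describeTree <- function(tree) {
  nodes <- treeNodes(tree)
  fmtNode <- function(id, prefix) {
    nd <- nodes[nodes$id == id, ]
    stats <- if (treeType(tree) == "classification")
      sprintf("n=%d case=%d control=%d pred=%s", nd$n, nd$n_pos, nd$n_neg,
              if (nd$pred) tree@params$positive else tree@params$negative)
    else
      sprintf("n=%d events=%d rate_ratio=%.2f", nd$n, nd$events,
              nd$rate_ratio)
    line <- if (is.na(nd$left)) sprintf("%s* leaf [%s]", prefix, stats)
            else sprintf("%s%s < %.4g | >= ... [%s]", prefix, nd$var,
                         nd$threshold, stats)
    out <- line
    if (!is.na(nd$left)) {
      out <- c(out, fmtNode(nd$left, paste0("  ", prefix)),
               fmtNode(nd$right, paste0("  ", prefix)))
    }
    out
  }
  fmtNode(1L, "")
}

#' Serialize a tree to JSON
#' @param tree a [DecisionTree-class].
#' @param path optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
treeToJson <- function(tree, path = NULL) {
  obj <- list(type = treeType(tree), params = tree@params,
              nodes = treeNodes(tree), prune_trace = pruneTrace(tree))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
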