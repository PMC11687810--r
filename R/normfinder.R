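## Model-based endogenous-control stability estimation.
##
## Variance-decomposition model on log-scale input (Ct values are already on
## a log2-like scale). For candidate gene i, group g, sample j:
##
##   y_igj = alpha_i + d_ig + b_gj + e_igj,   e_igj ~ (0, sigma2_ig)
##
## where b_gj is a sample effect, alpha_i the gene level, and d_ig the
## group-dependent bias (sum over groups of d_ig = 0 per gene). Estimation:
##
##   z_igj   = y_igj - mean_i(y_igj)          (remove the sample effect)
##   zbar_ig = mean_j(z_igj)
##   s2_ig   = sum_j (z_igj - zbar_ig)^2 / (n_g - 1)
##   sigma2_ig = max(0, (s2_ig - mean_i(s2_ig)/(k-1)) * k/(k-2))   [k >= 3]
##     (unbiased for sigma2 after the sample-mean subtraction; for k = 2 the
##      raw s2 is used)
##   dhat_ig = zbar_ig - mean_g(zbar_ig)
##   v_ig    = ((G-1)/G)^2 sigma2_ig/n_g + (1/G^2) sum_{g'!=g} sigma2_ig'/n_g'
##   gamma2  = max(0, (sum_ig dhat^2 - sum_ig v_ig) / (k (G-1)))
##   dstar_ig = dhat_ig * gamma2 / (gamma2 + v_ig)       (shrunken bias)
##   w_ig     = v_ig * gamma2 / (gamma2 + v_ig)          (posterior variance)
##
## Stability (lower = more stable), combining bias magnitude and variance:
##
##   rho_i = mean_g ( |dstar_ig| + sqrt(w_ig + sigma2_ig / n_g) )
##
## and for a candidate set S (pair, trio, ...) the combined stability of the
## averaged normalization factor:
##
##   rho_S = mean_g ( mean_{i in S} |dstar_ig|
##                    + sqrt(sum_{i in S} (w_ig + sigma2_ig/n_g)) / |S| )
##
## The bias term averages |dstar| over members rather than taking the bias of
## the averaged factor, so two oppositely biased genes cannot masquerade as a
## stable pair by cancellation.

normFinderComponents <- function(mat, groups) {
  k <- ncol(mat)
  lev <- levels(groups)
  G <- length(lev)
  s2 <- sigma2 <- zbar <- matrix(NA_real_, k, G,
                                 dimnames = list(colnames(mat), lev))
  ng <- stats::setNames(as.numeric(table(groups)[lev]), lev)
  for (g in lev) {
    y <- mat[groups == g, , drop = FALSE]
    z <- y - rowMeans(y)
    zbar[, g] <- colMeans(z)
    s2[, g] <- apply(z, 2L, stats::var)
  }
  if (k >= 3L) {
    for (g in lev)
      sigma2[, g] <- pmax(0, (s2[, g] - mean(s2[, g]) / (k - 1)) * k / (k - 2))
  } else sigma2 <- pmax(s2, 0)
  dhat <- zbar - rowMeans(zbar)
  v <- matrix(NA_real_, k, G, dimnames = dimnames(dhat))
  for (g in lev) {
    others <- setdiff(lev, g)
    v[, g] <- ((G - 1) / G)^2 * sigma2[, g] / ng[g] +
      rowSums(sigma2[, others, drop = FALSE] /
                rep(ng[others], each = k)) / G^2
  }
  gamma2 <- max(0, (sum(dhat^2) - sum(v)) / (k * (G - 1)))
  shrink <- gamma2 / (gamma2 + v)
  shrink[gamma2 == 0] <- 0
  dStar <- dhat * shrink
  w <- v * shrink
  list(ng = ng, s2 = s2, sigma2 = sigma2, dhat = dhat, v = v,
       gamma2 = gamma2, dStar = dStar, w = w)
}

#' Model-based stability of endogenous-control candidates
#'
#' Decomposes each candidate's Ct values into intra-group variance and
#' shrunken inter-group bias under a two-way gene-by-sample model, and scores
#' each candidate with a stability value (lower = more stable) combining the
#' two components; the formulation is documented in the package vignette.
#' Also reports the candidate pair whose averaged normalization factor has
#' the smallest combined stability.
#'
#' @param mat numeric matrix, samples x candidate assays (Ct values); at
#'   least two candidates.
#' @param groups factor/character of group labels aligned with rows; at least
#'   two groups with two samples each.
#' @param ceiling optional Ct ceiling; candidates touching it in any sample
#'   are a precondition violation and raise an error naming them.
#' @return a [StabilityResult-class].
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(40, 25, 0.5), 20, 2,
#'             dimnames = list(NULL, c("c1", "c2")))
#' m <- cbind(m, c3 = rnorm(20, 25, 0.5) + rep(c(0, 2), each = 10))
#' normFinderStability(m, rep(c("case", "control"), each = 10))
#' @export
normFinderStability <- function(mat, groups, ceiling = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("candidate", seq_len(ncol(mat)))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stopf("need at least two groups with two samples each")
  if (!is.null(ceiling)) {
    atCeiling <- colnames(mat)[apply(mat >= ceiling, 2L, any)]
    if (length(atCeiling))
      stopf("candidate(s) not expressed in all samples (Ct at ceiling): %s",
            paste(atCeiling, collapse = ", "))
  }
  comp <- normFinderComponents(mat, groups)
  perGene <- abs(comp$dStar) + sqrt(comp$w + comp$sigma2 / rep(comp$ng, each = nrow(comp$w)))
  rho <- rowMeans(perGene)
  st <- data.frame(assay_id = colnames(mat), rho = rho,
                   intra_var = rowMeans(comp$sigma2),
                   inter_diff = rowMeans(abs(comp$dStar)),
                   stringsAsFactors = FALSE, row.names = NULL)
  st <- st[order(st$rho, st$assay_id), , drop = FALSE]
  rownames(st) <- NULL

  varTerm <- comp$w + comp$sigma2 / rep(comp$ng, each = nrow(comp$w))
  pairs <- utils::combn(colnames(mat), 2L)
  pairRho <- apply(pairs, 2L, function(pr)
    combinedStabilityInternal(comp$dStar[pr, , drop = FALSE],
                              varTerm[pr, , drop = FALSE]))
  best <- pairs[, which.min(pairRho)]

  new("StabilityResult", stability = st, dStar = comp$dStar, dVar = varTerm,
      bestPair = best, groups = levels(groups))
}

combinedStabilityInternal <- function(dStar, varTerm) {
  m <- nrow(dStar)
  mean(colMeans(abs(dStar)) + sqrt(colSums(varTerm)) / m)
}

#' Combined stability of a candidate set
#'
#' Stability (lower = better) of the normalization factor formed by averaging
#' the member candidates, from a fitted [StabilityResult-class].
#'
#' @param stability a [StabilityResult-class].
#' @param members character; candidate assays in the set.
#' @return the combined stability value.
#' @export
setStability <- function(stability, members) {
  stopifnot(is(stability, "StabilityResult"),
            all(members %in% rownames(stability@dStar)))
  combinedStabilityInternal(stability@dStar[members, , drop = FALSE],
                            stability@dVar[members, , drop = FALSE])
}
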