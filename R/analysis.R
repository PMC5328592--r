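## Balance-space distances and the balance-variance vs phylogenetic-depth
## analysis: conditional balance values on non-zero counts, log-log
## regression of variance on mean tip depth, and a tip-label permutation
## null for the slope.

#' Euclidean distance between samples in balance space
#'
#' Because the balance coordinates form an orthonormal (Cartesian) system,
#' plain Euclidean distance is the natural metric; with unit taxon weights
#' and no branch weighting it equals the Aitchison distance between the
#' underlying compositions, and the squared distance decomposes additively
#' over balances.
#'
#' @param x a \linkS4class{PhyloBalances} or a sample x balance matrix.
#' @return symmetric \code{N x N} matrix with zero diagonal.
#' @export
philrDistance <- function(x) {
  m <- if (is(x, "PhyloBalances")) x@balances else as.matrix(x)
  if (any(!is.finite(m))) stop("balance table contains non-finite values")
  as.matrix(stats::dist(m, method = "euclidean"))
}

## ---- conditional balance machinery --------------------------------------

## Precompute the pieces shared by the observed statistic and every
## permutation: masked log counts, non-zero indicators, clade membership
## matrices and the per-node unit-norm scaling.
#' @noRd
.condEngine <- function(counts, theta) {
  counts <- counts[, colnames(theta), drop = FALSE]
  Z <- counts > 0
  L <- log(counts)
  L[!Z] <- 0
  Mp <- t(theta == 1) * 1
  Mm <- t(theta == -1) * 1
  nPlus <- colSums(Mp)
  nMinus <- colSums(Mm)
  list(L = L, Z = Z * 1, Mp = Mp, Mm = Mm,
       scale = sqrt(nPlus * nMinus / (nPlus + nMinus)))
}

## Balance matrix (N x D-1) with NA where a sample does not qualify at a
## node (no non-zero count in one of the two child clades). `perm` permutes
## tip columns, which is equivalent to permuting tip labels on the fixed
## topology.
#' @noRd
.condBalances <- function(eng, perm = NULL) {
  L <- eng$L; Z <- eng$Z
  if (!is.null(perm)) {
    L <- L[, perm, drop = FALSE]
    Z <- Z[, perm, drop = FALSE]
  }
  np <- Z %*% eng$Mp
  nm <- Z %*% eng$Mm
  b <- (L %*% eng$Mp) / np - (L %*% eng$Mm) / nm
  b <- sweep(b, 2L, eng$scale, "*")
  b[np == 0 | nm == 0] <- NA_real_
  b
}

#' Balance values conditioned on non-zero counts
#'
#' Computes unweighted balances directly from raw counts without zero
#' replacement: at internal node \code{i} a sample qualifies iff it has at
#' least one non-zero count in each of the node's two child clades, and
#' the balance is the scaled log-ratio of the geometric means over the
#' non-zero components only (closure cancels in the ratio, so raw counts
#' can be used directly). Balances qualifying in fewer than
#' \code{minSamples} samples are dropped. On a fully dense table this
#' reproduces \code{philrTransform} with unit weights, no branch
#' weighting and zero pseudocount.
#'
#' @param counts raw sample x taxon count matrix (no pseudocount).
#' @param tree rooted binary \code{phylo} whose tips match the taxa.
#' @param minSamples minimum number of qualifying samples per retained
#'   balance (>= 2, since a variance is needed downstream; default 40).
#' @return list with \code{balances} (N x (D-1) matrix, NA where a sample
#'   does not qualify), \code{kept} (names of retained balances) and
#'   \code{nQualifying} (qualifying-sample count per balance).
#' @export
conditionalBalanceValues <- function(counts, tree, minSamples = 40) {
  if (minSamples < 2) stop("minSamples must be >= 2 (variance is undefined ",
                           "on fewer than 2 samples)")
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  tree <- resolveMultichotomies(tree)
  theta <- buildSignMatrix(tree)
  if (!setequal(colnames(counts), colnames(theta)))
    stop("taxa and tree tips do not match exactly; ",
         "use matchTableTree() first")
  eng <- .condEngine(counts, theta)
  b <- .condBalances(eng)
  rownames(b) <- rownames(counts)
  colnames(b) <- rownames(theta)
  nq <- stats::setNames(as.integer(colSums(!is.na(b))), colnames(b))
  list(balances = b, kept = colnames(b)[nq >= minSamples], nQualifying = nq)
}

## closed-form OLS slope/intercept of y on x (identical to lm)
#' @noRd
.olsLine <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  beta <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(beta = beta, alpha = my - beta * mx)
}

#' Fit the log-log regression of balance variance on phylogenetic depth
#'
#' Ordinary least squares of \code{log(var)} on \code{log(d)}, where
#' \code{d} is a balance's mean phylogenetic distance to its descendant
#' tips: \code{log var(y*) = beta log d + alpha}. A positive slope means
#' neighboring clades covary more (balances vary less) close to the tips.
#' Zero-variance or zero-depth balances cannot enter the log-log fit and
#' are excluded with a report.
#'
#' @param variances named per-balance variances.
#' @param depths per-balance mean tip depths, aligned to \code{variances}.
#' @return object of class \code{varianceDepthFit}: list with \code{beta},
#'   \code{alpha}, \code{points} (the log-log point cloud),
#'   \code{nBalances} and the underlying \code{lm} fit.
#' @export
fitVarianceDepth <- function(variances, depths) {
  if (length(variances) != length(depths))
    stop("variances and depths must align")
  ok <- is.finite(variances) & is.finite(depths) & variances > 0 & depths > 0
  if (sum(!ok) > 0)
    message("fitVarianceDepth: excluded ", sum(!ok),
            " balances with zero/non-finite variance or depth")
  if (sum(ok) < 3) stop("fewer than 3 usable balances for the fit")
  pts <- data.frame(logDepth = log(depths[ok]), logVariance = log(variances[ok]))
  if (!is.null(names(variances))) rownames(pts) <- names(variances)[ok]
  model <- stats::lm(logVariance ~ logDepth, data = pts)
  cf <- stats::coef(model)
  structure(list(beta = unname(cf["logDepth"]),
                 alpha = unname(cf["(Intercept)"]),
                 points = pts, nBalances = sum(ok), model = model),
            class = "varianceDepthFit")
}

#' @export
print.varianceDepthFit <- function(x, ...) {
  cat("Balance variance vs phylogenetic depth (log-log OLS)\n")
  cat(sprintf("  beta = %.4f, alpha = %.4f over %d balances\n",
              x$beta, x$alpha, x$nBalances))
  invisible(x)
}

#' Tip-label permutation test for the variance-depth slope
#'
#' Tests the null hypothesis that balance variance is independent of
#' phylogenetic depth (slope beta = 0 in the log-log regression). The null
#' distribution of beta is generated by permuting tip labels on the fixed
#' topology -- equivalently, permuting the taxon columns of the count
#' table -- and recomputing the conditional balances, their variances and
#' the fit for each draw. Because only labels move, every permutation sees
#' exactly the per-taxon count vectors of the observed data, so any bias
#' from zero handling is identical in the observed and null statistics.
#' The two-tailed p-value uses the add-one estimator
#' \code{(1 + #(|beta_null| >= |beta_obs|)) / (1 + n)} so it is never
#' exactly zero.
#'
#' @param counts raw sample x taxon count matrix (no pseudocount).
#' @param tree rooted binary \code{phylo} with branch lengths.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param minSamples conditioning threshold per balance (default 40).
#' @return object of class \code{betaPermutation}: list with
#'   \code{betaObserved}, \code{alphaObserved}, \code{p}, \code{betaNull},
#'   \code{seed}, \code{nPerm}, \code{nBalances} (balances in the observed
#'   fit) and \code{depths}/\code{variances} used.
#' @seealso \code{\link{adjustGroupPvalues}} for FDR correction across
#'   several groups (e.g. body sites).
#' @export
permutationTestBeta <- function(counts, tree, nPerm = 999, seed = 1,
                                minSamples = 40) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  tree <- resolveMultichotomies(tree)
  theta <- buildSignMatrix(tree)
  if (!setequal(colnames(counts), colnames(theta)))
    stop("taxa and tree tips do not match exactly; ",
         "use matchTableTree() first")
  geom <- nodeGeometry(tree)
  depths <- stats::setNames(geom$meanTipDepth, geom$balance)
  eng <- .condEngine(counts, theta)

  betaOf <- function(b) {
    nq <- colSums(!is.na(b))
    ## column variances with NA removal, vectorized around the column means
    ## for numerical stability in the permutation loop
    mu <- colSums(b, na.rm = TRUE) / nq
    dev <- sweep(b, 2L, mu, "-")
    v <- colSums(dev * dev, na.rm = TRUE) / pmax(nq - 1L, 1L)
    v[nq < 2L] <- NA_real_
    ok <- nq >= minSamples & is.finite(v) & v > 0 & depths > 0
    if (sum(ok) < 3) return(c(beta = NA_real_, alpha = NA_real_, n = sum(ok)))
    c(.olsLine(log(depths[ok]), log(v[ok])), n = sum(ok))
  }

  obs <- betaOf(.condBalances(eng))
  if (is.na(obs["beta"]))
    stop("fewer than 3 balances pass the conditioning rule in the ",
         "observed data; lower minSamples or filter less aggressively")
  D <- ncol(eng$L)
  betaNull <- withr::with_seed(seed, vapply(seq_len(nPerm), function(r) {
    betaOf(.condBalances(eng, perm = sample.int(D)))[["beta"]]
  }, numeric(1)))
  nBad <- sum(is.na(betaNull))
  if (nBad > nPerm / 2)
    stop("degenerate fits in ", nBad, " of ", nPerm, " permutations ",
         "(fewer than 3 usable balances); the conditioning threshold is ",
         "too strict for this table")
  valid <- betaNull[!is.na(betaNull)]
  p <- (1 + sum(abs(valid) >= abs(obs[["beta"]]))) / (1 + length(valid))
  structure(list(betaObserved = obs[["beta"]],
                 alphaObserved = obs[["alpha"]],
                 p = p, betaNull = betaNull, seed = seed, nPerm = nPerm,
                 nBalances = unname(obs[["n"]])),
            class = "betaPermutation")
}

#' @export
print.betaPermutation <- function(x, ...) {
  cat("Tip-label permutation test for the variance-depth slope\n")
  cat(sprintf("  observed beta = %.4f over %d balances\n",
              x$betaObserved, x$nBalances))
  cat(sprintf("  two-tailed p = %.4g (%d permutations, seed %d)\n",
              x$p, x$nPerm, x$seed))
  invisible(x)
}

#' FDR correction across groups
#'
#' Benjamini-Hochberg adjustment of permutation p-values when the
#' variance-depth test is run on several groups (e.g. body sites).
#'
#' @param p numeric vector of p-values (optionally named by group).
#' @return adjusted p-values.
#' @export
adjustGroupPvalues <- function(p) stats::p.adjust(p, method = "BH")
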