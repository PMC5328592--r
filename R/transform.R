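## Core Aitchison-geometry algebra: closure, weighted clr, contrast matrix,
## forward phylogenetic ILR and its exact inverse. All logs are natural.

#' Closure: normalize parts to unit sum
#'
#' @param v non-negative numeric vector, or matrix with samples as rows
#'   (each row closed independently).
#' @return object of the same shape with (row) sums equal to 1.
#' @examples
#' closure(c(4, 2, 2))
#' @export
closure <- function(v) {
  if (is.matrix(v)) {
    s <- rowSums(v)
    if (any(v < 0) || any(s <= 0))
      stop("closure needs non-negative rows with positive sums")
    return(v / s)
  }
  if (any(v < 0) || sum(v) <= 0)
    stop("closure needs a non-negative vector with positive sum")
  v / sum(v)
}

#' Weighted geometric mean over a subset of parts
#'
#' \eqn{\exp(\sum_{j \in S} p_j \log y_j / \sum_{j \in S} p_j)}; with unit
#' weights this is the ordinary geometric mean.
#'
#' @param y strictly positive numeric vector (named or not).
#' @param subset indices or names selecting a nonempty subset of \code{y}.
#' @param p positive weights aligned to \code{y} (default unit weights).
#' @return positive scalar.
#' @export
weightedGMean <- function(y, subset, p = rep(1, length(y))) {
  if (length(subset) == 0L) stop("empty subset")
  if (is.character(subset)) subset <- match(subset, names(y))
  if (anyNA(subset)) stop("subset selects components absent from y")
  ys <- y[subset]; ps <- p[subset]
  if (length(ys) == 0L || anyNA(ys)) stop("subset selects nothing")
  if (any(ys <= 0)) stop("nonpositive component in geometric mean")
  exp(sum(ps * log(ys)) / sum(ps))
}

#' Weighted centered log-ratio transform
#'
#' \code{clrp(y)_j = log(y_j) - sum_k p_k log(y_k) / sum_k p_k}, i.e. the
#' log of each part relative to the weighted geometric mean of all parts.
#' Computed by log-space subtraction (never via products) so it is stable
#' for tables with tens of thousands of taxa.
#'
#' @param y strictly positive vector, or matrix with samples as rows.
#' @param p positive taxon weights (default unit).
#' @return same shape as \code{y}; each (row) vector satisfies
#'   \code{sum(p * clr) == 0}.
#' @export
clrp <- function(y, p = NULL) {
  vec <- !is.matrix(y)
  ym <- if (vec) matrix(y, nrow = 1, dimnames = list(NULL, names(y))) else y
  if (is.null(p)) p <- rep(1, ncol(ym))
  if (any(ym <= 0)) stop("clr needs strictly positive input")
  ly <- log(ym)
  ctr <- as.vector(ly %*% p) / sum(p)
  out <- ly - ctr
  if (vec) out[1, ] else out
}

#' Build the contrast matrix of the weighted ILR basis
#'
#' Row \code{i} of \eqn{\Psi} is built from row \code{i} of the sign matrix:
#' entries \eqn{+s_i/n_i^+} on the +1 clade, \eqn{-s_i/n_i^-} on the -1
#' clade and 0 elsewhere, where \eqn{n_i^\pm = \sum_{\theta_{ij}=\pm1} p_j}
#' and \eqn{s_i = \sqrt{n_i^+ n_i^- / (n_i^+ + n_i^-)}} is the scaling that
#' gives each basis element unit norm in the weighted inner product, so
#' that \code{Psi \%*\% diag(p) \%*\% t(Psi)} is the identity and each row
#' has weighted sum zero.
#'
#' @param theta sign matrix from \code{\link{buildSignMatrix}}.
#' @param p positive taxon weights aligned to the columns of \code{theta}.
#' @return \code{(D-1) x D} contrast matrix with the dimnames of
#'   \code{theta}.
#' @export
buildContrastMatrix <- function(theta, p = rep(1, ncol(theta))) {
  if (length(p) != ncol(theta))
    stop("weights length must match the number of taxa")
  if (any(p <= 0)) stop("taxon weights must be strictly positive")
  nPlus <- as.vector((theta == 1) %*% p)
  nMinus <- as.vector((theta == -1) %*% p)
  s <- sqrt(nPlus * nMinus / (nPlus + nMinus))
  psi <- (theta == 1) * (s / nPlus) - (theta == -1) * (s / nMinus)
  dimnames(psi) <- dimnames(theta)
  psi
}

#' Build a weighted phylogenetic ILR basis
#'
#' Canonicalizes (and if needed binarizes) the tree, derives the sign
#' matrix, taxon weights, contrast matrix, per-node geometry and
#' branch-length factors, and bundles them as a
#' \linkS4class{PhyloILRBasis}.
#'
#' @param tree rooted \code{phylo} whose tips are the taxa.
#' @param counts optional raw count matrix (samples x taxa) needed when
#'   \code{taxonScheme = "gm_norm"}.
#' @param taxonScheme \code{"uniform"}, \code{"gm_norm"} or \code{"user"}.
#' @param branchScheme \code{"none"}, \code{"sum"} or \code{"sqrt_sum"}.
#' @param weights user-supplied positive weights (named by taxon) when
#'   \code{taxonScheme = "user"}.
#' @param blEpsilon epsilon floor passed to \code{\link{branchFactor}}.
#' @param ... further arguments to the \code{\link{taxonWeights}} matrix
#'   method (e.g. \code{norm}).
#' @return a \linkS4class{PhyloILRBasis}.
#' @examples
#' fx <- toy3()
#' b <- buildBasis(fx$tree, taxonScheme = "uniform", branchScheme = "none")
#' @export
buildBasis <- function(tree, counts = NULL,
                       taxonScheme = c("uniform", "gm_norm", "user"),
                       branchScheme = c("none", "sqrt_sum", "sum"),
                       weights = NULL, blEpsilon = 0, ...) {
  taxonScheme <- match.arg(taxonScheme)
  branchScheme <- match.arg(branchScheme)
  tree <- resolveMultichotomies(tree)
  theta <- buildSignMatrix(tree)
  taxa <- colnames(theta)
  p <- switch(taxonScheme,
    uniform = stats::setNames(rep(1, length(taxa)), taxa),
    gm_norm = {
      if (is.null(counts))
        stop("taxonScheme 'gm_norm' needs the raw count matrix")
      w <- taxonWeights(counts[, taxa, drop = FALSE], scheme = "gm_norm", ...)
      w[taxa]
    },
    user = {
      if (is.null(weights)) stop("taxonScheme 'user' needs 'weights'")
      if (is.null(names(weights))) stop("user weights must be named by taxon")
      if (!all(taxa %in% names(weights)))
        stop("user weights missing taxa: ",
             paste(setdiff(taxa, names(weights)), collapse = ", "))
      weights[taxa]
    })
  if (any(!is.finite(p)) || any(p <= 0))
    stop("taxon weights must be finite and strictly positive")
  psi <- buildContrastMatrix(theta, p)
  geom <- if (.hasBranchLengths(tree)) nodeGeometry(tree) else
    data.frame(balance = character(), node = integer(), dPlus = numeric(),
               dMinus = numeric(), meanTipDepth = numeric())
  bf <- if (branchScheme == "none") {
    stats::setNames(rep(1, nrow(theta)), rownames(theta))
  } else {
    if (nrow(geom) == 0L)
      stop("branch weighting needs a tree with branch lengths")
    f <- branchFactor(geom$dPlus, geom$dMinus, branchScheme,
                      epsilon = blEpsilon)
    if (any(f == 0))
      stop("zero branch factor under scheme '", branchScheme,
           "'; supply blEpsilon > 0 or use branchScheme = 'none'")
    stats::setNames(f, geom$balance)
  }
  new("PhyloILRBasis", tree = tree, theta = theta, psi = psi,
      weights = p, geometry = geom, taxonScheme = taxonScheme,
      branchScheme = branchScheme, branchFactors = bf)
}

#' Phylogenetic ILR transform of a count table
#'
#' Transforms an \code{N x D} sample-by-taxon table into \code{N x (D-1)}
#' balance coordinates. Per sample: add the pseudocount, close to relative
#' abundances \code{x}, shift by the taxon weights (\code{y = x / p}) and
#' project onto the weighted ILR basis,
#' \code{y* = clrp(y) \%*\% diag(p) \%*\% t(Psi)}; finally each balance is
#' multiplied by its branch-length factor. Balance \code{ni} equals the
#' scaled log-ratio of the weighted geometric mean abundance of the two
#' clades below internal node \code{i} (positive when the numerator clade,
#' the one carrying the +1 signs, is relatively more abundant).
#'
#' @param counts \code{N x D} matrix of non-negative counts (or relative
#'   abundances), taxa as named columns. Column set must match the tree's
#'   tips exactly.
#' @param tree rooted \code{phylo} (ignored when \code{basis} is given).
#' @param basis optional prebuilt \linkS4class{PhyloILRBasis}.
#' @param pseudocount added to every entry before closure (default 1);
#'   required positive when any count is zero.
#' @inheritParams buildBasis
#' @return a \linkS4class{PhyloBalances}.
#' @examples
#' fx <- toy3()
#' pb <- philrTransform(fx$counts, fx$tree, taxonScheme = "uniform",
#'                      branchScheme = "none", pseudocount = 0)
#' balances(pb)  # (0.2830, 0.4901)
#' @export
philrTransform <- function(counts, tree = NULL, basis = NULL,
                           taxonScheme = c("gm_norm", "uniform", "user"),
                           branchScheme = c("sqrt_sum", "sum", "none"),
                           pseudocount = 1, weights = NULL, blEpsilon = 0,
                           ...) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts needs taxon column names")
  if (is.null(basis)) {
    if (is.null(tree)) stop("supply either a tree or a prebuilt basis")
    taxonScheme <- match.arg(taxonScheme)
    branchScheme <- match.arg(branchScheme)
    basis <- buildBasis(tree, counts = counts, taxonScheme = taxonScheme,
                        branchScheme = branchScheme, weights = weights,
                        blEpsilon = blEpsilon, ...)
  }
  taxa <- colnames(basis@theta)
  if (!setequal(colnames(counts), taxa)) {
    extraC <- setdiff(colnames(counts), taxa)
    extraT <- setdiff(taxa, colnames(counts))
    stop("taxa and tree tips do not match exactly.",
         if (length(extraC)) paste0(" Only in table: ",
           paste(utils::head(extraC, 10), collapse = ", "), ".") else "",
         if (length(extraT)) paste0(" Only in tree: ",
           paste(utils::head(extraT, 10), collapse = ", "), ".") else "",
         " Use matchTableTree() to reconcile them.")
  }
  cc <- counts[, taxa, drop = FALSE] + pseudocount
  if (any(cc <= 0))
    stop("zeros (or negative entries) remain after adding the pseudocount; ",
         "use pseudocount > 0 on tables containing zero counts")
  x <- closure(cc)
  p <- basis@weights
  y <- sweep(x, 2L, p, "/")
  ystar <- clrp(y, p) %*% (p * t(basis@psi))
  ystar <- sweep(ystar, 2L, basis@branchFactors[colnames(ystar)], "*")
  if (is.null(rownames(ystar)) && !is.null(rownames(counts)))
    rownames(ystar) <- rownames(counts)
  new("PhyloBalances", balances = ystar, basis = basis,
      pseudocount = pseudocount)
}

#' Invert the phylogenetic ILR transform
#'
#' Undoes the branch-length scaling, maps back through the contrast matrix
#' and unshifts by the taxon weights:
#' \code{x = C[exp(y*/f \%*\% Psi) * p]}. The round trip
#' \code{inversePhilr(philrTransform(c))} reproduces the closed
#' pseudocounted input exactly (to floating-point accuracy).
#'
#' @param balances a \linkS4class{PhyloBalances}, or a plain sample x
#'   balance matrix (then \code{basis} is required).
#' @param basis the \linkS4class{PhyloILRBasis} to invert through when
#'   \code{balances} is a bare matrix.
#' @return \code{N x D} matrix of relative abundances (rows sum to 1).
#' @examples
#' fx <- toy3()
#' pb <- philrTransform(fx$counts, fx$tree, taxonScheme = "uniform",
#'                      branchScheme = "none", pseudocount = 0)
#' inversePhilr(pb)  # (0.5, 0.25, 0.25)
#' @export
inversePhilr <- function(balances, basis = NULL) {
  if (is(balances, "PhyloBalances")) {
    basis <- balances@basis
    y <- balances@balances
  } else {
    if (is.null(basis))
      stop("a bare balance matrix needs an explicit basis")
    y <- as.matrix(balances)
  }
  if (ncol(y) != nrow(basis@psi))
    stop("balance table has ", ncol(y), " columns but the basis defines ",
         nrow(basis@psi), " balances")
  bf <- basis@branchFactors
  if (!is.null(colnames(y))) {
    if (!all(colnames(y) %in% names(bf)))
      stop("balance names do not match the basis (provenance mismatch)")
    bf <- bf[colnames(y)]
  }
  y0 <- sweep(y, 2L, bf, "/")
  x <- exp(y0 %*% basis@psi)
  x <- sweep(x, 2L, basis@weights, "*")
  closure(x)
}
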