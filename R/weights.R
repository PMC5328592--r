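#' @describeIn taxonWeights compute soft-thresholding weights from a raw
#'   count matrix (samples as rows). Under \code{scheme = "gm_norm"} the
#'   weight of taxon \eqn{j} is the geometric mean of its pseudocounted
#'   counts across samples times the norm of its relative-abundance vector,
#'   \deqn{p_j = \left[\prod_s (c_{js} + 1)\right]^{1/N} \, \lVert x_j \rVert,}
#'   which down-weights taxa dominated by zero and near-zero counts.
#'   Relative abundances are computed by per-sample closure of the raw
#'   counts (set \code{normOnPseudocounted = TRUE} to close the
#'   pseudocounted counts instead). \code{norm = "euclidean"} is the
#'   default; \code{norm = "aitchison"} uses the Aitchison norm of the
#'   taxon's abundance profile and requires that profile to be strictly
#'   positive.
#'
#' @param scheme \code{"gm_norm"} (default) or \code{"uniform"}.
#' @param norm \code{"euclidean"} or \code{"aitchison"}.
#' @param normOnPseudocounted close counts + 1 instead of raw counts for
#'   the norm term.
#' @export
setMethod("taxonWeights", "matrix", function(x, scheme = c("gm_norm", "uniform"),
                                             norm = c("euclidean", "aitchison"),
                                             normOnPseudocounted = FALSE, ...) {
  scheme <- match.arg(scheme)
  norm <- match.arg(norm)
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative and complete")
  if (is.null(colnames(x)))
    stop("count matrix needs taxon ids as column names")
  if (scheme == "uniform") {
    p <- rep(1, ncol(x))
    names(p) <- colnames(x)
    attr(p, "scheme") <- "uniform"
    return(p)
  }
  gm <- exp(colMeans(log(x + 1)))
  xrel <- closure(if (normOnPseudocounted) x + 1 else x)
  nrm <- if (norm == "euclidean") {
    sqrt(colSums(xrel^2))
  } else {
    if (any(xrel == 0))
      stop("Aitchison norm needs strictly positive relative abundances; ",
           "filter zero counts or use norm = 'euclidean'")
    lx <- log(xrel)
    sqrt(colSums((t(lx) - colMeans(lx))^2))
  }
  p <- gm * nrm
  if (any(p == 0)) {
    bad <- colnames(x)[p == 0]
    stop("taxa with zero counts in every sample get weight 0, which is not ",
         "a valid positive weight; filter them first (see filterTaxa): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  names(p) <- colnames(x)
  attr(p, "scheme") <- paste0("gm_norm/", norm)
  p
})

#' @describeIn taxonWeights weights stored in a basis.
#' @export
setMethod("taxonWeights", "PhyloILRBasis", function(x, ...) x@weights)

#' @describeIn taxonWeights weights of the basis behind a balance table.
#' @export
setMethod("taxonWeights", "PhyloBalances", function(x, ...) x@basis@weights)

#' Branch-length scaling factor for a balance
#'
#' Maps the branch lengths of an internal node's two direct children to the
#' scalar multiplying that node's balance. Schemes: \code{"none"} gives 1,
#' \code{"sum"} gives \eqn{d_+ + d_-}, \code{"sqrt_sum"} gives
#' \eqn{\sqrt{d_+ + d_-}} (the default used for weighted analyses).
#'
#' A factor of zero (both child branches of length 0, as can arise from
#' resolved multichotomies) silently annihilates a balance, so it is an
#' error by default; supply \code{epsilon > 0} to add a small length to
#' both children instead.
#'
#' @param dPlus,dMinus non-negative child branch lengths (vectorized).
#' @param scheme \code{"none"}, \code{"sum"} or \code{"sqrt_sum"}.
#' @param epsilon optional length added to both children under
#'   \code{"sum"}/\code{"sqrt_sum"}.
#' @return positive numeric vector of factors.
#' @examples
#' branchFactor(0.3, 0.1, "sqrt_sum")  # sqrt(0.4)
#' @export
branchFactor <- function(dPlus, dMinus, scheme = c("sqrt_sum", "sum", "none"),
                         epsilon = 0) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(rep(1, length(dPlus)))
  if (anyNA(dPlus) || anyNA(dMinus))
    stop("branch lengths are absent; branch weighting needs a tree with ",
         "complete branch lengths")
  if (any(dPlus < 0) || any(dMinus < 0)) stop("branch lengths must be >= 0")
  s <- (dPlus + epsilon) + (dMinus + epsilon)
  f <- if (scheme == "sum") s else sqrt(s)
  if (any(f == 0)) {
    if (epsilon > 0) stop("branch factor still zero after epsilon floor")
    warning("zero branch factor (both child branches have length 0); ",
            "the corresponding balance is annihilated -- consider epsilon > 0")
  }
  f
}

#' Write taxon weights as a two-column TSV
#'
#' @param weights named numeric vector (as from \code{taxonWeights}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTaxonWeights <- function(weights, path) {
  utils::write.table(
    data.frame(taxon_id = names(weights), weight = unname(weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read taxon weights from a two-column TSV
#'
#' @param path path written by \code{\link{writeTaxonWeights}}.
#' @return named numeric vector.
#' @export
readTaxonWeights <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  p <- d[[2]]
  names(p) <- d[[1]]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("weights must be finite and strictly positive")
  p
}
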