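#' @include AllClasses.R
NULL

#' Extract the balance coordinate matrix
#'
#' Returns the sample x balance matrix of ILR coordinates (samples as rows,
#' one column per internal node of the phylogeny, named \code{n1..n(D-1)}).
#'
#' @param x a \linkS4class{PhyloBalances} object.
#' @return numeric matrix with \code{N} rows and \code{D - 1} columns.
#' @export
setGeneric("balances", function(x) standardGeneric("balances"))

#' Extract the ILR basis of a balance table
#'
#' @param x a \linkS4class{PhyloBalances} object.
#' @return the \linkS4class{PhyloILRBasis} used to compute the balances.
#' @export
setGeneric("ilrBasis", function(x) standardGeneric("ilrBasis"))

#' Extract the sign matrix encoding the sequential binary partition
#'
#' @param x a \linkS4class{PhyloILRBasis} or \linkS4class{PhyloBalances}.
#' @return \code{(D-1) x D} matrix over \{-1, 0, +1\}; rows are internal
#'   nodes in preorder, columns are taxa in canonical order.
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' Extract the contrast matrix of the weighted ILR basis
#'
#' @param x a \linkS4class{PhyloILRBasis} or \linkS4class{PhyloBalances}.
#' @return \code{(D-1) x D} real matrix \eqn{\Psi} whose rows are the
#'   orthonormal basis elements (with respect to the weighted inner product).
#' @export
setGeneric("contrastMatrix", function(x) standardGeneric("contrastMatrix"))

#' Per-taxon weights
#'
#' For a count matrix, computes soft-thresholding taxon weights (see
#' the \code{matrix} method); for a basis or balance table, extracts the
#' weights that were used to build it.
#'
#' @param x count matrix (samples x taxa), \linkS4class{PhyloILRBasis} or
#'   \linkS4class{PhyloBalances}.
#' @param ... passed to methods.
#' @return strictly positive numeric vector aligned to the taxa.
#' @export
setGeneric("taxonWeights", function(x, ...) standardGeneric("taxonWeights"))

#' Per-node geometry of a phylogeny
#'
#' For each internal node: the branch lengths of its two direct children
#' (\code{dPlus} for the numerator-side child, \code{dMinus} for the
#' denominator side) and the mean phylogenetic distance from the node to
#' its descendant tips (\code{meanTipDepth}).
#'
#' @param x a rooted binary \code{phylo}, a \linkS4class{PhyloILRBasis} or a
#'   \linkS4class{PhyloBalances}.
#' @param ... passed to methods.
#' @return data.frame with one row per internal node (\code{n1..n(D-1)}).
#' @export
setGeneric("nodeGeometry", function(x, ...) standardGeneric("nodeGeometry"))

#' Branch-length scaling factors applied to each balance
#'
#' @param x a \linkS4class{PhyloILRBasis} or \linkS4class{PhyloBalances}.
#' @return named numeric vector, one factor per balance (all 1 when the
#'   branch scheme is \code{"none"}).
#' @export
setGeneric("branchFactors", function(x) standardGeneric("branchFactors"))
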