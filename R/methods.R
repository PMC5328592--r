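## Accessors and show methods for the S4 containers.

#' @describeIn PhyloBalances the sample x balance coordinate matrix.
#' @param x a \linkS4class{PhyloBalances} object.
#' @export
setMethod("balances", "PhyloBalances", function(x) x@balances)

#' @describeIn PhyloBalances the basis used for the transform.
#' @export
setMethod("ilrBasis", "PhyloBalances", function(x) x@basis)

#' @describeIn PhyloILRBasis the sign matrix.
#' @param x a \linkS4class{PhyloILRBasis} object.
#' @export
setMethod("signMatrix", "PhyloILRBasis", function(x) x@theta)

#' @export
#' @describeIn PhyloBalances the sign matrix of the underlying basis.
setMethod("signMatrix", "PhyloBalances", function(x) x@basis@theta)

#' @describeIn PhyloILRBasis the contrast matrix.
#' @export
setMethod("contrastMatrix", "PhyloILRBasis", function(x) x@psi)

#' @describeIn PhyloBalances the contrast matrix of the underlying basis.
#' @export
setMethod("contrastMatrix", "PhyloBalances", function(x) x@basis@psi)

#' @describeIn PhyloILRBasis per-node geometry of the stored tree.
#' @export
setMethod("nodeGeometry", "PhyloILRBasis", function(x, ...) x@geometry)

#' @describeIn PhyloBalances per-node geometry of the basis tree.
#' @export
setMethod("nodeGeometry", "PhyloBalances", function(x, ...) x@basis@geometry)

#' @describeIn PhyloILRBasis branch-length factors per balance.
#' @export
setMethod("branchFactors", "PhyloILRBasis", function(x) x@branchFactors)

#' @describeIn PhyloBalances branch-length factors per balance.
#' @export
setMethod("branchFactors", "PhyloBalances", function(x) x@basis@branchFactors)

#' Tree stored in a basis
#'
#' @param x a \linkS4class{PhyloILRBasis} or \linkS4class{PhyloBalances}.
#' @return the canonical rooted binary \code{phylo}.
#' @export
basisTree <- function(x) {
  if (is(x, "PhyloBalances")) x@basis@tree else x@tree
}

setMethod("show", "PhyloILRBasis", function(object) {
  D <- ncol(object@theta)
  cat("PhyloILRBasis:", D, "taxa,", nrow(object@theta), "balances\n")
  cat("  taxon weights:", object@taxonScheme,
      "| branch weighting:", object@branchScheme, "\n")
  cat("  tree:", if (.hasBranchLengths(object@tree))
    "branch lengths present" else "no branch lengths", "\n")
})

setMethod("show", "PhyloBalances", function(object) {
  cat("PhyloBalances:", nrow(object@balances), "samples x",
      ncol(object@balances), "balances\n")
  cat("  pseudocount:", object@pseudocount,
      "| taxon weights:", object@basis@taxonScheme,
      "| branch weighting:", object@basis@branchScheme, "\n")
})
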