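setOldClass("phylo")

#' PhyloILRBasis: a weighted ILR basis built from a phylogeny
#'
#' Container for the sequential-binary-partition representation of a rooted
#' binary phylogeny together with the taxon weights and branch-length scheme
#' that define a (generalized) isometric log-ratio basis. Rows of the sign
#' matrix \eqn{\Theta} and of the contrast matrix \eqn{\Psi} index internal
#' nodes in a fixed preorder (named \code{n1..n(D-1)}); columns index taxa
#' in the canonical order of the stored tree.
#'
#' @slot tree rooted, strictly binary \code{phylo} in canonical child order.
#' @slot theta \code{(D-1) x D} sign matrix over \{-1, 0, +1\}.
#' @slot psi \code{(D-1) x D} contrast matrix; \code{Psi diag(p) Psi^T = I}.
#' @slot weights strictly positive per-taxon weights \code{p}.
#' @slot geometry data.frame of per-node child branch lengths and mean tip
#'   depth (zero rows when the tree carries no branch lengths).
#' @slot taxonScheme one of \code{"uniform"}, \code{"gm_norm"}, \code{"user"}.
#' @slot branchScheme one of \code{"none"}, \code{"sum"}, \code{"sqrt_sum"}.
#' @slot branchFactors per-balance scaling factor \code{f(d+, d-)}.
#'
#' @seealso \code{\link{buildBasis}}, \code{\link{philrTransform}}
#' @export
setClass("PhyloILRBasis",
  representation(
    tree = "ANY",
    theta = "matrix",
    psi = "matrix",
    weights = "numeric",
    geometry = "data.frame",
    taxonScheme = "character",
    branchScheme = "character",
    branchFactors = "numeric"
  )
)

setValidity("PhyloILRBasis", function(object) {
  msg <- character()
  th <- object@theta
  D <- ncol(th)
  if (!inherits(object@tree, "phylo"))
    msg <- c(msg, "'tree' must be a phylo object")
  if (nrow(th) != D - 1L)
    msg <- c(msg, "sign matrix must have D-1 rows for D taxa")
  if (!all(th %in% c(-1, 0, 1)))
    msg <- c(msg, "sign matrix entries must be in {-1, 0, +1}")
  if (any(rowSums(th == 1) < 1L) || any(rowSums(th == -1) < 1L))
    msg <- c(msg, "every sign-matrix row needs at least one +1 and one -1")
  if (!identical(dim(object@psi), dim(th)))
    msg <- c(msg, "contrast matrix dimensions must match the sign matrix")
  if (!identical(sign(object@psi), th))
    msg <- c(msg, "sign pattern of the contrast matrix must equal the sign matrix")
  if (length(object@weights) != D || any(!is.finite(object@weights)) ||
      any(object@weights <= 0))
    msg <- c(msg, "taxon weights must be length D, finite and strictly positive")
  if (length(object@branchFactors) != nrow(th) ||
      any(!is.finite(object@branchFactors)))
    msg <- c(msg, "branch factors must be one finite value per balance")
  if (length(msg)) msg else TRUE
})

#' PhyloBalances: samples in balance coordinates
#'
#' The result of the phylogenetic ILR transform: an \code{N x (D-1)} matrix
#' of balance coordinates (samples as rows) together with the
#' \linkS4class{PhyloILRBasis} and the pseudocount that produced it, which
#' is sufficient metadata to invert the transform exactly.
#'
#' @slot balances numeric matrix, samples x balances.
#' @slot basis the \linkS4class{PhyloILRBasis} used.
#' @slot pseudocount pseudocount added to the counts before closure.
#'
#' @seealso \code{\link{philrTransform}}, \code{\link{inversePhilr}}
#' @export
setClass("PhyloBalances",
  representation(
    balances = "matrix",
    basis = "PhyloILRBasis",
    pseudocount = "numeric"
  )
)

setValidity("PhyloBalances", function(object) {
  msg <- character()
  b <- object@balances
  if (ncol(b) != nrow(object@basis@theta))
    msg <- c(msg, "balance table must have one column per internal node")
  if (any(!is.finite(b)))
    msg <- c(msg, "balance values must be finite")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a single non-negative number")
  if (length(msg)) msg else TRUE
})
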