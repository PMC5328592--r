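#' @importFrom ape read.tree write.tree is.rooted is.binary multi2di root
#'   keep.tip node.depth.edgelength reorder.phylo
NULL

## Internal helpers ---------------------------------------------------------

.nTips <- function(tree) length(tree$tip.label)

#' @noRd
.checkTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a 'phylo' tree object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  invisible(tree)
}

## TRUE when the tree carries a complete set of branch lengths
#' @noRd
.hasBranchLengths <- function(tree) {
  !is.null(tree$edge.length) && !anyNA(tree$edge.length)
}

## children of each node, in edge (= Newick) order
#' @noRd
.childList <- function(tree) {
  nn <- .nTips(tree) + tree$Nnode
  kids <- vector("list", nn)
  e <- tree$edge
  for (k in seq_len(nrow(e))) kids[[e[k, 1L]]] <- c(kids[[e[k, 1L]]], e[k, 2L])
  kids
}

## lexicographically smallest descendant tip label per node (radix order,
## locale-independent)
#' @noRd
.minTipLabel <- function(tree) {
  ntip <- .nTips(tree)
  po <- reorder.phylo(tree, "postorder")$edge
  minlab <- rep(NA_character_, ntip + tree$Nnode)
  minlab[seq_len(ntip)] <- tree$tip.label
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]; ch <- po[k, 2L]
    if (is.na(minlab[p])) minlab[p] <- minlab[ch]
    else minlab[p] <- sort(c(minlab[p], minlab[ch]), method = "radix")[1L]
  }
  minlab
}

## descendant tip indices per node (tips map to themselves)
#' @noRd
.descTips <- function(tree) {
  ntip <- .nTips(tree)
  po <- reorder.phylo(tree, "postorder")$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (k in seq_len(nrow(po)))
    desc[[po[k, 1L]]] <- c(desc[[po[k, 1L]]], desc[[po[k, 2L]]])
  desc
}

## strictly binary in the rooted sense: every internal node has exactly two
## children (ape::is.binary calls a 3-tip star "binary" in the unrooted
## sense, which is not what the sign matrix needs)
#' @noRd
.isStrictlyBinary <- function(tree) {
  ntip <- .nTips(tree)
  deg <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)
  all(deg[(ntip + 1L):(ntip + tree$Nnode)] == 2L)
}

## internal nodes in preorder (root first, depth-first in child order)
#' @noRd
.preorderInternal <- function(tree) {
  e <- reorder.phylo(tree, "cladewise")$edge
  unique(e[, 1L])
}

## Exported operations ------------------------------------------------------

#' Read a phylogeny from Newick text
#'
#' Thin validated wrapper around \code{ape::read.tree}. Branch lengths are
#' preserved; absent lengths stay absent (they are never silently set to 0)
#' and operations that need lengths will refuse the tree. Unrooted trees are
#' rejected unless an outgroup is supplied.
#'
#' @param text Newick string.
#' @param outgroup optional tip label used to root an unrooted input via
#'   \code{\link{rootByOutgroup}}.
#' @return a \code{phylo} object.
#' @examples
#' tr <- readTreeText("((t1:0.5,t2:0.5):0.5,t3:0.5);")
#' @export
readTreeText <- function(text, outgroup = NULL) {
  ## ape signals some malformed inputs as warning + NULL; both become errors
  tree <- tryCatch(suppressWarnings(read.tree(text = text)),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: no tree found in input")
  .checkTree(tree)
  if (!is.rooted(tree)) {
    if (is.null(outgroup))
      stop("tree is unrooted; supply an outgroup or use rootByOutgroup()")
    tree <- rootByOutgroup(tree, outgroup)
  }
  tree
}

#' Read a phylogeny from a Newick file
#'
#' @param path path to a Newick file.
#' @inheritParams readTreeText
#' @return a \code{phylo} object.
#' @export
readTreeFile <- function(path, outgroup = NULL) {
  readTreeText(paste(readLines(path, warn = FALSE), collapse = ""), outgroup)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a \code{phylo} object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTreeFile <- function(tree, path) {
  write.tree(tree, file = path)
  invisible(path)
}

#' Put a rooted tree into canonical child order
#'
#' Reorders the children of every node so that the child containing the
#' lexicographically smallest descendant tip label comes first. This makes
#' every downstream object (sign matrix, contrast matrix, balance naming)
#' byte-reproducible regardless of the rotation in which the Newick input
#' was written. Topology, branch lengths and tip-to-tip path lengths are
#' unchanged.
#'
#' @param tree rooted \code{phylo}.
#' @return a \code{phylo} with identical topology in canonical order.
#' @export
canonicalizeTree <- function(tree) {
  .checkTree(tree)
  ntip <- .nTips(tree)
  kids <- .childList(tree)
  minlab <- .minTipLabel(tree)
  elen <- tree$edge.length
  edgeOf <- integer(ntip + tree$Nnode)
  edgeOf[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  build <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      ch <- kids[[node]]
      ch <- ch[order(minlab[ch], method = "radix")]
      lab <- paste0("(", paste(vapply(ch, build, character(1)),
                               collapse = ","), ")")
    }
    if (node != root && !is.null(elen) && !is.na(elen[edgeOf[node]]))
      lab <- paste0(lab, ":", sprintf("%.17g", elen[edgeOf[node]]))
    lab
  }
  read.tree(text = paste0(build(root), ";"))
}

#' Resolve multichotomies into a strictly binary tree
#'
#' Replaces every multichotomy by a series of dichotomies whose inserted
#' branches have length exactly zero (via \code{ape::multi2di}). Children
#' are first put in canonical order (see \code{\link{canonicalizeTree}})
#' so the resolution is deterministic for identical input, independent of
#' the child order in the source Newick.
#'
#' @param tree rooted \code{phylo}.
#' @return a strictly binary \code{phylo} with the same tip set, in
#'   canonical order.
#' @examples
#' tr <- resolveMultichotomies(ape::read.tree(text = "(t1:1,t2:1,t3:1);"))
#' @export
resolveMultichotomies <- function(tree) {
  tree <- canonicalizeTree(tree)
  if (!.isStrictlyBinary(tree)) tree <- canonicalizeTree(multi2di(tree, random = FALSE))
  tree
}

#' Root a tree by declaring an outgroup tip
#'
#' @param tree a \code{phylo} (rooted or unrooted).
#' @param outgroup tip label to place on one side of the root.
#' @return rooted \code{phylo}; pairwise tip-to-tip path lengths are
#'   preserved.
#' @export
rootByOutgroup <- function(tree, outgroup) {
  .checkTree(tree)
  if (!outgroup %in% tree$tip.label)
    stop("unknown outgroup tip: ", outgroup)
  root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Build the sign matrix of the sequential binary partition
#'
#' Encodes a rooted binary phylogeny as a \code{(D-1) x D} matrix over
#' \{-1, 0, +1\}. Row \code{i} corresponds to internal node \code{ni}
#' (preorder from the root); its +1 entries are the descendant tips of the
#' node's first child in canonical order and its -1 entries those of the
#' second child, so the +1 clade is always the one containing the
#' lexicographically smallest tip label. Columns follow the canonical tip
#' order of the tree.
#'
#' @param tree rooted, strictly binary \code{phylo}.
#' @return sign matrix with rownames \code{n1..n(D-1)} and colnames the tip
#'   labels.
#' @examples
#' buildSignMatrix(readTreeText("((t1:0.5,t2:0.5):0.5,t3:0.5);"))
#' @export
buildSignMatrix <- function(tree) {
  tree <- canonicalizeTree(tree)
  if (!.isStrictlyBinary(tree))
    stop("tree is not strictly binary; call resolveMultichotomies() first")
  ntip <- .nTips(tree)
  kids <- .childList(tree)
  desc <- .descTips(tree)
  preo <- .preorderInternal(tree)
  theta <- matrix(0, nrow = tree$Nnode, ncol = ntip,
                  dimnames = list(paste0("n", seq_len(tree$Nnode)),
                                  tree$tip.label))
  for (i in seq_along(preo)) {
    ch <- kids[[preo[i]]]
    theta[i, desc[[ch[1L]]]] <- 1
    theta[i, desc[[ch[2L]]]] <- -1
  }
  theta
}

#' @describeIn nodeGeometry compute geometry from a rooted binary tree with
#'   branch lengths.
#' @export
setMethod("nodeGeometry", "phylo", function(x, ...) {
  tree <- canonicalizeTree(x)
  if (!.isStrictlyBinary(tree))
    stop("tree is not strictly binary; call resolveMultichotomies() first")
  if (!.hasBranchLengths(tree))
    stop("tree has absent branch lengths; geometry (and any length-",
         "dependent feature) needs a fully specified tree")
  ntip <- .nTips(tree)
  kids <- .childList(tree)
  desc <- .descTips(tree)
  preo <- .preorderInternal(tree)
  edgeOf <- integer(ntip + tree$Nnode)
  edgeOf[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  ndep <- node.depth.edgelength(tree)
  out <- data.frame(
    balance = paste0("n", seq_along(preo)),
    node = preo,
    dPlus = NA_real_, dMinus = NA_real_, meanTipDepth = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(preo)) {
    nd <- preo[i]
    ch <- kids[[nd]]
    out$dPlus[i] <- tree$edge.length[edgeOf[ch[1L]]]
    out$dMinus[i] <- tree$edge.length[edgeOf[ch[2L]]]
    tips <- desc[[nd]]
    out$meanTipDepth[i] <- mean(ndep[tips]) - ndep[nd]
  }
  rownames(out) <- out$balance
  out
})
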