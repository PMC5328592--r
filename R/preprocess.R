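## Preprocessing: zero replacement, taxon and sample filtering, table-tree
## reconciliation. None of these mutate their input; every drop is reported
## via message() so a pipeline log captures each decision.

#' Add a pseudocount to every entry
#'
#' Zero counts are treated as rounded zeros (values below the detection
#' limit), replaced by adding a small constant prior to the log-ratio
#' transform. The conventional choice is 1; results are typically robust
#' to moderate alternatives (2, 3, 10).
#'
#' @param counts sample x taxon matrix of non-negative values.
#' @param pseudocount value added to every entry; must be > 0 when the
#'   table contains zeros.
#' @return matrix of the same shape.
#' @export
replaceZeros <- function(counts, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts == 0))
    stop("table contains zeros; pseudocount must be > 0")
  counts + pseudocount
}

#' Filter rare taxa by count and prevalence
#'
#' Keeps taxon \code{j} iff it is seen with more than \code{minCount}
#' counts in at least a fraction \code{minPrevalence} of samples
#' (inequalities are strict on the count, non-strict on the prevalence).
#' Defaults correspond to the common rule of dropping taxa not seen with
#' more than 3 counts in at least 1\% of samples.
#'
#' @param counts raw sample x taxon count matrix.
#' @param minCount count that must be exceeded (default 3).
#' @param minPrevalence required fraction of qualifying samples in [0, 1]
#'   (default 0.01).
#' @return the filtered matrix; dropped taxon ids are reported.
#' @export
filterTaxa <- function(counts, minCount = 3, minPrevalence = 0.01) {
  if (minCount < 0 || minPrevalence < 0 || minPrevalence > 1)
    stop("minCount must be >= 0 and minPrevalence in [0, 1]")
  qualifying <- colSums(counts > minCount)
  keep <- qualifying >= minPrevalence * nrow(counts)
  if (!any(keep))
    stop("all ", ncol(counts), " taxa dropped (minCount = ", minCount,
         ", minPrevalence = ", minPrevalence, "); relax the thresholds")
  if (any(!keep))
    message("filterTaxa: dropped ", sum(!keep), " of ", ncol(counts),
            " taxa: ", paste(utils::head(colnames(counts)[!keep], 20),
                             collapse = ", "),
            if (sum(!keep) > 20) ", ..." else "")
  counts[, keep, drop = FALSE]
}

#' Filter shallow samples by total count
#'
#' Drops samples whose total count is strictly fewer than
#' \code{minSampleDepth}.
#'
#' @param counts raw sample x taxon count matrix.
#' @param minSampleDepth minimum acceptable sequencing depth.
#' @return the filtered matrix; dropped sample ids are reported.
#' @export
filterSamples <- function(counts, minSampleDepth = 1000) {
  keep <- rowSums(counts) >= minSampleDepth
  if (!any(keep))
    stop("all ", nrow(counts), " samples have depth < ", minSampleDepth)
  if (any(!keep))
    message("filterSamples: dropped ", sum(!keep), " of ", nrow(counts),
            " samples: ", paste(utils::head(rownames(counts)[!keep], 20),
                                collapse = ", "),
            if (sum(!keep) > 20) ", ..." else "")
  counts[keep, , drop = FALSE]
}

#' Reconcile a count table with a phylogeny
#'
#' Restricts both objects to their common taxon set: the tree is pruned to
#' the taxa present in the table and the table's columns are reordered to
#' the canonical tip order of the pruned tree. Asymmetric differences are
#' reported.
#'
#' @param counts sample x taxon matrix with taxon column names.
#' @param tree rooted \code{phylo}.
#' @return list with elements \code{counts} and \code{tree}.
#' @export
matchTableTree <- function(counts, tree) {
  .checkTree(tree)
  taxa <- colnames(counts)
  common <- intersect(taxa, tree$tip.label)
  if (length(common) < 2L)
    stop("fewer than two taxa shared between table and tree")
  onlyTable <- setdiff(taxa, common)
  onlyTree <- setdiff(tree$tip.label, common)
  if (length(onlyTable))
    message("matchTableTree: ", length(onlyTable),
            " taxa only in table (dropped): ",
            paste(utils::head(onlyTable, 20), collapse = ", "))
  if (length(onlyTree))
    message("matchTableTree: ", length(onlyTree),
            " tips only in tree (pruned): ",
            paste(utils::head(onlyTree, 20), collapse = ", "))
  tree2 <- if (length(onlyTree)) ape::keep.tip(tree, common) else tree
  tree2 <- canonicalizeTree(tree2)
  list(counts = counts[, tree2$tip.label, drop = FALSE], tree = tree2)
}
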