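## Consensus taxonomy naming of balances: each clade below an internal node
## is labeled by the finest taxonomic rank at which a single identifier
## covers at least 95% of the clade's tips, and a balance is named
## "numerator/denominator" from its +1 and -1 clades.

.RANKS <- c("k", "p", "c", "o", "f", "g", "s")

#' Parse semicolon-delimited rank-prefixed lineages
#'
#' Accepts lineage strings of the usual greengenes-style form
#' \code{"k__Bacteria; p__Firmicutes; ...; s__"}. Empty tokens (a bare
#' prefix) and absent ranks become \code{NA}.
#'
#' @param lineages character vector of lineage strings, named by taxon id.
#' @return character matrix, taxa x ranks (\code{k,p,c,o,f,g,s}), holding
#'   the full prefixed identifier (e.g. \code{"g__Bacteroides"}) or NA.
#' @export
parseLineages <- function(lineages) {
  if (is.null(names(lineages))) stop("lineages must be named by taxon id")
  out <- matrix(NA_character_, nrow = length(lineages), ncol = length(.RANKS),
                dimnames = list(names(lineages), .RANKS))
  for (i in seq_along(lineages)) {
    toks <- trimws(strsplit(lineages[[i]], ";", fixed = TRUE)[[1]])
    for (tok in toks) {
      if (!grepl("^[kpcofgs]__", tok)) next
      r <- substr(tok, 1L, 1L)
      if (nchar(tok) > 3L) out[i, r] <- tok
    }
  }
  out
}

#' Read a taxonomy table
#'
#' Two-column TSV: taxon id, then a semicolon-delimited rank-prefixed
#' lineage.
#'
#' @param path path to the TSV (a header row is allowed and detected).
#' @return parsed taxa x ranks matrix (see \code{\link{parseLineages}}).
#' @export
readTaxonomy <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) && !grepl("__", d[1, 2], fixed = TRUE)) d <- d[-1, , drop = FALSE]
  parseLineages(stats::setNames(as.character(d[[2]]), as.character(d[[1]])))
}

#' Consensus taxonomic label for a set of tips
#'
#' Walks the taxonomy from the finest rank (species) to the coarsest
#' (kingdom) and returns the first identifier that represents at least
#' \code{threshold} of the tips at that rank (missing entries count
#' against the consensus); returns \code{"Unclassified"} when no rank
#' reaches consensus.
#'
#' @param tips character vector of taxon ids (rows of \code{taxonomy}).
#' @param taxonomy taxa x ranks matrix from \code{\link{parseLineages}}.
#' @param threshold consensus fraction (default 0.95).
#' @return a single prefixed label or \code{"Unclassified"}.
#' @export
consensusTaxonomy <- function(tips, taxonomy, threshold = 0.95) {
  if (length(tips) == 0L) stop("empty tip set")
  known <- intersect(tips, rownames(taxonomy))
  n <- length(tips)
  for (r in rev(.RANKS)) {
    vals <- taxonomy[known, r]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    tab <- sort(table(vals), decreasing = TRUE)
    if (tab[1L] >= threshold * n) return(names(tab)[1L])
  }
  "Unclassified"
}

#' Name one balance from its two clades
#'
#' Applies \code{\link{consensusTaxonomy}} separately to the +1 (numerator)
#' and -1 (denominator) clades of an internal node and combines the labels
#' as \code{"numerator/denominator"}.
#'
#' @param node balance id (\code{"n3"}) or row index into the sign matrix.
#' @param theta sign matrix, or a \linkS4class{PhyloILRBasis}.
#' @param taxonomy taxa x ranks matrix.
#' @param threshold consensus fraction (default 0.95).
#' @return named character vector with elements \code{numerator},
#'   \code{denominator} and \code{name}.
#' @export
nameBalance <- function(node, theta, taxonomy, threshold = 0.95) {
  if (is(theta, "PhyloILRBasis")) theta <- theta@theta
  row <- theta[node, ]
  num <- consensusTaxonomy(names(row)[row == 1], taxonomy, threshold)
  den <- consensusTaxonomy(names(row)[row == -1], taxonomy, threshold)
  c(numerator = num, denominator = den, name = paste0(num, "/", den))
}

#' Name every balance of a basis
#'
#' @param basis a \linkS4class{PhyloILRBasis} (or sign matrix).
#' @inheritParams nameBalance
#' @return data.frame with columns \code{balance}, \code{numerator},
#'   \code{denominator}, \code{name}.
#' @export
nameBalances <- function(basis, taxonomy, threshold = 0.95) {
  theta <- if (is(basis, "PhyloILRBasis")) basis@theta else basis
  nm <- t(vapply(rownames(theta), nameBalance, character(3),
                 theta = theta, taxonomy = taxonomy, threshold = threshold))
  data.frame(balance = rownames(theta), nm, row.names = rownames(theta),
             stringsAsFactors = FALSE)
}

#' Median phylogenetic depth per taxonomic rank
#'
#' Labels every internal node by the consensus taxonomy of all its
#' descendant tips, then, for each rank, takes the median of the mean
#' tip depths of the nodes labeled at that rank. This estimates, e.g., the
#' depth beyond which balances no longer involve leaves sharing the same
#' species assignment. Ranks with no labeled node are absent from the
#' result (never reported as 0).
#'
#' @param basis a \linkS4class{PhyloILRBasis} built from a tree with
#'   branch lengths.
#' @param taxonomy taxa x ranks matrix.
#' @param threshold consensus fraction (default 0.95).
#' @return named numeric vector, names among \code{k,p,c,o,f,g,s}.
#' @export
rankDepthMedians <- function(basis, taxonomy, threshold = 0.95) {
  geom <- nodeGeometry(basis)
  if (nrow(geom) == 0L)
    stop("depth analysis needs a tree with branch lengths")
  theta <- basis@theta
  labs <- vapply(rownames(theta), function(b) {
    consensusTaxonomy(names(which(theta[b, ] != 0)), taxonomy, threshold)
  }, character(1))
  rk <- ifelse(labs == "Unclassified", NA_character_, substr(labs, 1L, 1L))
  out <- vapply(.RANKS, function(r) {
    d <- geom$meanTipDepth[!is.na(rk) & rk == r]
    if (length(d)) stats::median(d) else NA_real_
  }, numeric(1))
  out[!is.na(out)]
}
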