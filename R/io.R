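## Delimited-text IO: count tables and balance tables as TSV (samples as
## rows), with a sidecar metadata TSV describing each balance.

#' Read a sample x taxon count table from TSV
#'
#' First column = sample ids, header row = taxon ids.
#'
#' @param path path to the TSV.
#' @return numeric matrix, samples as rows.
#' @export
readCountTable <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("count table must be numeric")
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative and complete")
  m
}

#' Read a sample x balance table from TSV
#'
#' Like \code{\link{readCountTable}} but without the non-negativity
#' constraint (balances are signed).
#'
#' @param path path to a TSV written by \code{\link{writeBalances}}.
#' @return numeric matrix, samples as rows.
#' @export
readBalanceTable <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (!is.numeric(m) || anyNA(m)) stop("balance table must be numeric and complete")
  m
}

#' Write a sample x taxon table as TSV
#'
#' @param counts matrix with sample rownames and taxon colnames.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCountTable <- function(counts, path) {
  utils::write.table(data.frame(sample_id = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a balance table and its metadata sidecar
#'
#' The balance TSV has samples as rows and balances \code{n1..n(D-1)} as
#' columns. The sidecar records, per balance: descendant tip counts of the
#' two clades, child branch lengths, the applied branch factor and
#' (optionally) the consensus taxonomy name.
#'
#' @param pb a \linkS4class{PhyloBalances}.
#' @param balancesPath path for the balance TSV.
#' @param metadataPath path for the sidecar TSV (default: balancesPath with
#'   a \code{_metadata.tsv} suffix).
#' @param names optional data.frame from \code{\link{nameBalances}}.
#' @return invisibly, the two paths.
#' @export
writeBalances <- function(pb, balancesPath,
                          metadataPath = sub("\\.tsv$", "_metadata.tsv",
                                             balancesPath),
                          names = NULL) {
  b <- balances(pb)
  utils::write.table(data.frame(sample_id = rownames(b), b,
                                check.names = FALSE),
                     balancesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  basis <- ilrBasis(pb)
  theta <- signMatrix(basis)
  geom <- nodeGeometry(basis)
  md <- data.frame(balance = rownames(theta),
                   n_tips_plus = rowSums(theta == 1),
                   n_tips_minus = rowSums(theta == -1),
                   d_plus = if (nrow(geom)) geom[rownames(theta), "dPlus"]
                            else NA_real_,
                   d_minus = if (nrow(geom)) geom[rownames(theta), "dMinus"]
                             else NA_real_,
                   branch_factor = branchFactors(basis)[rownames(theta)],
                   stringsAsFactors = FALSE)
  if (!is.null(names)) md$name <- names[rownames(theta), "name"]
  utils::write.table(md, metadataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(balancesPath, metadataPath))
}
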