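## Deterministic toy objects and a logistic-normal multinomial simulator
## with tunable phylogenetic covariance. The generative family is chosen
## because the transform's geometry is exactly Gaussian in balance space
## under it, which makes closed-form checks possible; it is a modeling
## convenience, not a claim about real microbiome data.

#' Three-taxon toy fixture
#'
#' The smallest non-degenerate worked example: the tree
#' \code{((t1:0.5,t2:0.5):0.5,t3:0.5);} and a one-sample table holding the
#' composition (0.5, 0.25, 0.25). Its unweighted balances are
#' (0.2830, 0.4901).
#'
#' @return list with elements \code{tree} (phylo) and \code{counts}
#'   (1 x 3 matrix).
#' @export
toy3 <- function() {
  tree <- readTreeText("((t1:0.5,t2:0.5):0.5,t3:0.5);")
  counts <- matrix(c(0.5, 0.25, 0.25), nrow = 1,
                   dimnames = list("s1", c("t1", "t2", "t3")))
  list(tree = tree, counts = counts)
}

#' Random rooted binary tree
#'
#' Random topology with exponentially distributed branch lengths,
#' deterministic for a given seed. Tips are labeled \code{t1..tD}.
#'
#' @param D number of tips (>= 2).
#' @param seed integer seed.
#' @param meanBranchLength mean of the exponential branch lengths
#'   (default 0.1, a typical per-branch divergence on 16S trees).
#' @return rooted binary \code{phylo}.
#' @export
randomBinaryTree <- function(D, seed = 1, meanBranchLength = 0.1) {
  if (D < 2) stop("need at least 2 tips")
  withr::with_seed(seed, {
    tree <- ape::rtree(D, rooted = TRUE,
                       br = function(n) stats::rexp(n, 1 / meanBranchLength))
    tree$tip.label <- paste0("t", seq_len(D))
    tree
  })
}

#' Simulate phylogenetically correlated count tables
#'
#' Logistic-normal multinomial generator: per sample, draw log-abundances
#' \code{z ~ MVN(0, Sigma)} with \code{Sigma_jk = sigma2 *
#' exp(-decayLambda * d_phylo(j, k))} (the stationary covariance of an
#' Ornstein-Uhlenbeck process on the tree), close \code{exp(z)} to a
#' composition, and draw counts from a multinomial whose size is Poisson
#' with mean \code{depth}. \code{decayLambda = 0} is treated as the
#' no-phylogenetic-signal case, i.e. independent (tip-exchangeable)
#' log-abundances \code{Sigma = sigma2 * I}, so that the marginal
#' log-abundance variance stays \code{sigma2} for every \code{decayLambda}.
#'
#' @param tree rooted \code{phylo} with branch lengths (taxa = tips).
#' @param nSamples number of samples (default 100).
#' @param depth mean total counts per sample (default 5000).
#' @param sigma2 log-scale variance per taxon (default 1).
#' @param decayLambda rate at which tip-tip log-abundance covariance
#'   decays with phylogenetic distance; 0 = exchangeable (default 0).
#' @param seed integer seed; the output is fully reproducible from it.
#' @return sample x taxon integer count matrix.
#' @export
simulateCounts <- function(tree, nSamples = 100, depth = 5000, sigma2 = 1,
                           decayLambda = 0, seed = 1) {
  if (sigma2 < 0 || decayLambda < 0)
    stop("sigma2 and decayLambda must be >= 0")
  tips <- tree$tip.label
  D <- length(tips)
  Sigma <- if (decayLambda == 0) {
    diag(sigma2, D)
  } else {
    dmat <- stats::cophenetic(tree)[tips, tips]
    sigma2 * exp(-decayLambda * dmat)
  }
  withr::with_seed(seed, {
    z <- if (sigma2 == 0) matrix(0, nSamples, D) else {
      ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < 1e-10) {
        message("simulateCounts: covariance regularized with jitter ",
                "(smallest eigenvalue ", signif(ev, 3), ")")
        Sigma <- Sigma + diag(1e-8 - min(ev, 0), D)
      }
      MASS::mvrnorm(nSamples, mu = rep(0, D), Sigma = Sigma)
    }
    comp <- closure(exp(z))
    sizes <- stats::rpois(nSamples, depth)
    counts <- t(vapply(seq_len(nSamples), function(i) {
      stats::rmultinom(1, sizes[i], comp[i, ])[, 1]
    }, integer(D)))
  })
  dimnames(counts) <- list(paste0("s", seq_len(nSamples)), tips)
  counts
}
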