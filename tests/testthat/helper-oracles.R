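## Independent oracles: every function here is written from the definitions
## and shares no code with the package's computation paths.

## plain clr of a positive composition (unweighted)
oracle_clr <- function(x) log(x) - mean(log(x))

## Aitchison distance = Euclidean distance between clr vectors
oracle_aitchison <- function(x1, x2) sqrt(sum((oracle_clr(x1) - oracle_clr(x2))^2))

## descendant tip labels per node, by independent recursive traversal of the
## ape edge matrix
oracle_desc_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  recurse <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], recurse))
  }
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  stats::setNames(lapply(nodes, recurse), nodes)
}

## direct per-node evaluation of the balance at each sign-matrix row:
## scale * log(gp(y+) / gp(y-)) on the shifted composition y = x / p
oracle_balances <- function(x, theta, p) {
  vapply(seq_len(nrow(theta)), function(i) {
    y <- x / p
    ip <- theta[i, ] == 1
    im <- theta[i, ] == -1
    np <- sum(p[ip]); nm <- sum(p[im])
    gp <- exp(sum(p[ip] * log(y[ip])) / np)
    gm <- exp(sum(p[im] * log(y[im])) / nm)
    sqrt(np * nm / (np + nm)) * log(gp / gm)
  }, numeric(1))
}

## random strictly positive composition
random_composition <- function(D) {
  v <- stats::rexp(D) + 1e-3
  v / sum(v)
}

## small random count table guaranteed free of all-zero taxa
random_count_table <- function(N, D, lambda = 20) {
  m <- matrix(stats::rpois(N * D, lambda), N, D,
              dimnames = list(paste0("s", seq_len(N)), paste0("t", seq_len(D))))
  m[1, ] <- m[1, ] + 1L
  m
}
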