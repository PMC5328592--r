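test_that("closure normalizes and is idempotent", {
  expect_equal(closure(c(4, 2, 2)), c(0.5, 0.25, 0.25))
  expect_equal(closure(c(1, 1, 1)), rep(1 / 3, 3))
  v <- c(3, 0.5, 9)
  expect_equal(closure(closure(v)), closure(v))
  expect_error(closure(c(0, 0)), "positive sum")
  m <- matrix(c(4, 2, 2, 1, 1, 2), 2, byrow = TRUE)
  expect_equal(rowSums(closure(m)), c(1, 1))
})

test_that("weighted geometric mean matches its definition", {
  y <- c(t1 = 0.5, t2 = 0.25, t3 = 0.25)
  expect_equal(weightedGMean(y, c("t1", "t2")), sqrt(0.5 * 0.25))
  expect_equal(weightedGMean(y, "t2", p = c(5, 5, 5)), 0.25)
  expect_equal(weightedGMean(rep(0.2, 3), 1:3, p = c(1, 1, 2)), 0.2)
  expect_error(weightedGMean(y, character(0)), "empty")
  expect_error(weightedGMean(c(1, -1), 1:2), "nonpositive")
})

test_that("weighted clr centers in the weighted geometry", {
  y <- c(0.5, 0.25, 0.25)
  expect_equal(clrp(y), log(y) - mean(log(y)), tolerance = 1e-12)
  expect_equal(clrp(y)[1], 0.4620981, tolerance = 1e-6)
  set.seed(3)
  for (r in 1:10) {
    D <- sample(3:20, 1)
    y <- random_composition(D)
    p <- rexp(D) + 0.1
    expect_equal(sum(p * clrp(y, p)), 0, tolerance = 1e-10)
  }
  expect_equal(clrp(rep(0.25, 4)), rep(0, 4))
})

test_that("contrast matrix rows are the unit-norm basis elements", {
  theta <- buildSignMatrix(toy3()$tree)
  psi <- buildContrastMatrix(theta)
  expect_equal(unname(psi["n1", ]), c(sqrt(1 / 6), sqrt(1 / 6), -sqrt(2 / 3)),
               tolerance = 1e-12)
  expect_equal(unname(psi["n2", ]), c(sqrt(1 / 2), -sqrt(1 / 2), 0),
               tolerance = 1e-12)

  pair <- buildContrastMatrix(matrix(c(1, -1), 1))
  expect_equal(unname(pair), matrix(c(1, -1) / sqrt(2), 1), tolerance = 1e-12)

  ## orthonormality in the weighted inner product, random (tree, p)
  set.seed(5)
  for (r in 1:10) {
    D <- sample(3:30, 1)
    th <- buildSignMatrix(randomBinaryTree(D, seed = r))
    p <- rexp(D) + 0.1
    ps <- buildContrastMatrix(th, p)
    expect_lt(max(abs(ps %*% (p * t(ps)) - diag(D - 1))), 1e-10)
    expect_lt(max(abs(ps %*% p)), 1e-10)
  }
})

test_that("the worked three-taxon example transforms and inverts exactly", {
  fx <- toy3()
  pb <- philrTransform(fx$counts, fx$tree, taxonScheme = "uniform",
                       branchScheme = "none", pseudocount = 0)
  expect_equal(unname(balances(pb)[1, ]), c(0.2829762, 0.4901291),
               tolerance = 1e-6)
  expect_equal(inversePhilr(pb)[1, ], fx$counts[1, ], tolerance = 1e-12)
})

test_that("degenerate compositions give zero balances", {
  fx <- toy3()
  unif <- matrix(1 / 3, 1, 3, dimnames = list("s1", c("t1", "t2", "t3")))
  pb <- philrTransform(unif, fx$tree, taxonScheme = "uniform",
                       branchScheme = "none", pseudocount = 0)
  expect_equal(unname(balances(pb)[1, ]), c(0, 0), tolerance = 1e-12)

  ## shifted composition constant under p = (1, 1, 2): balance n1 vanishes
  x <- matrix(c(0.25, 0.25, 0.5), 1, dimnames = list("s1", c("t1", "t2", "t3")))
  pbw <- philrTransform(x, fx$tree, taxonScheme = "user",
                        weights = c(t1 = 1, t2 = 1, t3 = 2),
                        branchScheme = "none", pseudocount = 0)
  expect_equal(unname(balances(pbw)[1, ]), c(0, 0), tolerance = 1e-12)

  ## zero balance vector inverts to the closure of the weights
  z <- matrix(0, 1, 2, dimnames = list("s1", c("n1", "n2")))
  expect_equal(unname(inversePhilr(z, ilrBasis(pbw))[1, ]),
               c(0.25, 0.25, 0.5), tolerance = 1e-12)
})

test_that("matrix form equals direct per-node evaluation, including non-uniform weights", {
  set.seed(9)
  for (r in 1:10) {
    D <- sample(3:50, 1)
    tr <- randomBinaryTree(D, seed = 100 + r)
    theta <- buildSignMatrix(tr)
    p <- stats::setNames(rexp(D) + 0.1, colnames(theta))
    x <- matrix(random_composition(D), 1, dimnames = list("s1", colnames(theta)))
    pb <- philrTransform(x, tr, taxonScheme = "user", weights = p,
                         branchScheme = "none", pseudocount = 0)
    expect_lt(max(abs(balances(pb)[1, ] -
                      oracle_balances(x[1, ], theta, p[colnames(theta)]))),
              1e-10)
  }
})

test_that("the transform is scale invariant on positive tables", {
  set.seed(15)
  tr <- randomBinaryTree(8, seed = 2)
  cn <- random_count_table(5, 8) + 1
  colnames(cn) <- tr$tip.label
  b1 <- balances(philrTransform(cn, tr, taxonScheme = "uniform",
                                branchScheme = "none", pseudocount = 0))
  b2 <- balances(philrTransform(cn * 37.5, tr, taxonScheme = "uniform",
                                branchScheme = "none", pseudocount = 0))
  expect_identical(b1, b2)
})

test_that("round trips recover the closed pseudocounted input for every weighting combination", {
  set.seed(21)
  for (r in 1:4) {
    D <- sample(4:30, 1)
    tr <- randomBinaryTree(D, seed = 200 + r)
    cn <- random_count_table(25, D)
    colnames(cn) <- tr$tip.label
    target <- closure(cn + 1)
    for (ts in c("uniform", "gm_norm")) for (bs in c("none", "sum", "sqrt_sum")) {
      pb <- philrTransform(cn, tr, taxonScheme = ts, branchScheme = bs,
                           pseudocount = 1)
      expect_lt(max(abs(inversePhilr(pb)[, colnames(target)] - target)),
                1e-10)
    }
  }
})

test_that("with unit weights the map is an isometry onto Aitchison geometry", {
  set.seed(27)
  tr <- randomBinaryTree(20, seed = 4)
  x <- t(replicate(12, random_composition(20)))
  colnames(x) <- tr$tip.label
  pb <- philrTransform(x, tr, taxonScheme = "uniform", branchScheme = "none",
                       pseudocount = 0)
  b <- balances(pb)
  for (i in 1:6) {
    jk <- sample(nrow(x), 2)
    expect_equal(sqrt(sum((b[jk[1], ] - b[jk[2], ])^2)),
                 oracle_aitchison(x[jk[1], ], x[jk[2], ]), tolerance = 1e-8)
  }
})

test_that("branch weighting scales balances by the recorded factors and stays invertible", {
  tr <- randomBinaryTree(10, seed = 6)
  cn <- random_count_table(8, 10)
  colnames(cn) <- tr$tip.label
  plain <- philrTransform(cn, tr, taxonScheme = "uniform",
                          branchScheme = "none")
  blw <- philrTransform(cn, tr, taxonScheme = "uniform",
                        branchScheme = "sqrt_sum")
  f <- branchFactors(blw)[colnames(balances(blw))]
  expect_equal(balances(blw), sweep(balances(plain), 2, f, "*"),
               tolerance = 1e-12)
  expect_lt(max(abs(inversePhilr(blw) - inversePhilr(plain))), 1e-12)

  ## branchFactor none leaves the transform bitwise identical
  none2 <- philrTransform(cn, tr, taxonScheme = "uniform",
                          branchScheme = "none")
  expect_identical(balances(plain), balances(none2))
})

test_that("taxon/tip mismatches are reported with the offending names", {
  fx <- toy3()
  bad <- fx$counts
  colnames(bad) <- c("t1", "t2", "tX")
  expect_error(philrTransform(bad, fx$tree, taxonScheme = "uniform"),
               "tX")
  expect_error(philrTransform(fx$counts * 0, fx$tree,
                              taxonScheme = "uniform", pseudocount = 0),
               "pseudocount")
})
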