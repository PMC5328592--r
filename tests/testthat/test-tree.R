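test_that("Newick reading validates input and preserves what it sees", {
  tr <- readTreeText("((t1:0.5,t2:0.5):0.5,t3:0.5);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_equal(sort(tr$edge.length), c(0.5, 0.5, 0.5, 0.5))

  ## absent branch lengths stay absent and block length-dependent features
  nolen <- readTreeText("((t1,t2),t3);")
  expect_null(nolen$edge.length)
  expect_error(nodeGeometry(nolen), "absent branch lengths")

  expect_error(readTreeText("((t1:0.1,t1:0.2):0.3,t3:0.4);"), "duplicate")
  expect_error(readTreeText("(t1:1,t2:1,t3:1,t4:1);"), "rootByOutgroup")
  expect_error(readTreeText("not a newick"), "parse")
})

test_that("multichotomies resolve deterministically into zero-length dichotomies", {
  tri <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  bin <- resolveMultichotomies(tri)
  expect_true(ape::is.binary(bin))
  expect_equal(bin$Nnode, 2L)
  expect_equal(sort(bin$tip.label), sort(tri$tip.label))
  expect_equal(sum(bin$edge.length == 0), 1L)

  ## binary input passes through unchanged (canonical toy tree)
  toy <- toy3()$tree
  expect_equal(ape::write.tree(resolveMultichotomies(toy)),
               ape::write.tree(toy))

  ## 4-way polytomy: 3 internal nodes, 2 inserted zero branches, stable
  poly <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  b1 <- resolveMultichotomies(poly)
  expect_equal(b1$Nnode, 3L)
  expect_equal(sum(b1$edge.length == 0), 2L)
  expect_equal(ape::write.tree(resolveMultichotomies(poly)),
               ape::write.tree(b1))
})

test_that("outgroup rooting places the outgroup at the root and preserves path lengths", {
  tr <- ape::unroot(ape::read.tree(text = "((t1:0.3,t2:0.2):0.1,(t3:0.4,t4:0.5):0.2);"))
  rt <- rootByOutgroup(tr, "t3")
  root <- length(rt$tip.label) + 1L
  rootKids <- rt$edge[rt$edge[, 1] == root, 2]
  expect_true(which(rt$tip.label == "t3") %in% rootKids)

  d0 <- stats::cophenetic(tr)
  d1 <- stats::cophenetic(rt)
  expect_equal(d1[rownames(d0), colnames(d0)], d0, tolerance = 1e-12)

  ## rerooting at the current outgroup keeps the topology
  toy <- toy3()$tree
  again <- rootByOutgroup(toy, "t3")
  expect_equal(ape::write.tree(canonicalizeTree(again)),
               ape::write.tree(canonicalizeTree(toy)))

  expect_error(rootByOutgroup(toy, "nope"), "unknown outgroup")
})

test_that("sign matrix encodes the sequential binary partition with the declared sign policy", {
  theta <- buildSignMatrix(toy3()$tree)
  expect_equal(theta["n1", c("t1", "t2", "t3")], c(t1 = 1, t2 = 1, t3 = -1))
  expect_equal(theta["n2", c("t1", "t2", "t3")], c(t1 = 1, t2 = -1, t3 = 0))

  pair <- buildSignMatrix(readTreeText("(t1:1,t2:1);"))
  expect_equal(unname(pair), matrix(c(1, -1), 1))

  expect_error(buildSignMatrix(ape::read.tree(text = "(t1:1,t2:1,t3:1);")),
               "not strictly binary")
})

test_that("sign-matrix rows match brute-force descendant enumeration on random trees", {
  set.seed(42)
  for (D in c(3, 5, 8, 10)) {
    tr <- randomBinaryTree(D, seed = D)
    theta <- buildSignMatrix(tr)
    desc <- oracle_desc_tips(canonicalizeTree(tr))
    for (i in seq_len(nrow(theta))) {
      nz <- colnames(theta)[theta[i, ] != 0]
      plus <- colnames(theta)[theta[i, ] == 1]
      minus <- colnames(theta)[theta[i, ] == -1]
      ## the nonzero set of some oracle node equals this row's support,
      ## and the +/- sets partition it disjointly
      hit <- Filter(function(s) setequal(s, nz), desc)
      expect_length(hit, 1L)
      expect_length(intersect(plus, minus), 0L)
      expect_setequal(c(plus, minus), nz)
      ## declared policy: +1 clade carries the smallest tip label
      expect_identical(sort(plus, method = "radix")[1],
                       sort(nz, method = "radix")[1])
    }
  }
})

test_that("the sign matrix is invariant to Newick child-order rotation", {
  a <- buildSignMatrix(readTreeText("((t1:0.5,t2:0.5):0.5,t3:0.5);"))
  b <- buildSignMatrix(readTreeText("(t3:0.5,(t2:0.5,t1:0.5):0.5);"))
  expect_identical(a, b)
})

test_that("node geometry reports child branch lengths and mean tip depth", {
  g <- nodeGeometry(readTreeText("((t1:0.1,t2:0.3):0.2,t3:0.6);"))
  expect_equal(g["n2", "dPlus"], 0.1)
  expect_equal(g["n2", "dMinus"], 0.3)
  expect_equal(g["n2", "meanTipDepth"], 0.2)

  gt <- nodeGeometry(toy3()$tree)
  expect_equal(gt["n1", "meanTipDepth"], (1 + 1 + 0.5) / 3)

  ## zero-length inserted branch recorded as 0, not dropped
  bin <- resolveMultichotomies(ape::read.tree(text = "(t1:1,t2:1,t3:1);"))
  gb <- nodeGeometry(bin)
  expect_true(any(c(gb$dPlus, gb$dMinus) == 0))
})
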