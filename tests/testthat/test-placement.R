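test_that("edge fit recovers a query attached mid-edge with a pendant", {
  tree <- backboneTree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  ph <- treePhylo(tree)
  ## attach at the midpoint of the first internal (non-pendant) edge with
  ## pendant 0.5, and construct delta by summing true path lengths
  internal <- which(ph$edge[, 2] > length(ph$tip.label))[1]
  edgeNum <- internal - 1L
  u <- ph$edge[internal, 1]; v <- ph$edge[internal, 2]
  len <- ph$edge.length[internal]
  D <- ape::dist.nodes(ph)
  leaves <- seq_along(ph$tip.label)
  onDistal <- D[v, leaves] < D[u, leaves]
  x <- len / 2; p <- 0.5
  delta <- ifelse(onDistal, p + (len - x) + D[v, leaves],
                  p + x + D[u, leaves])
  names(delta) <- ph$tip.label
  fit <- edgeFit(edgeNum, delta, tree)
  expect_equal(fit$distal, x, tolerance = 1e-9)
  expect_equal(fit$pendant, p, tolerance = 1e-9)
  expect_equal(fit$lse, 0, tolerance = 1e-12)
  ## and the fit agrees with the brute-force grid optimizer
  w <- pmax(delta, 1e-6)^-2
  g <- gridEdgeFit(tree, edgeNum, delta, w)
  expect_equal(fit$lse, unname(g["obj"]), tolerance = 1e-6)
})

test_that("boundary solution x = 0, p = 1 is found when the query sits at a node", {
  tree <- simulateTree(8, scale = 0.2, seed = 21)
  ph <- treePhylo(tree)
  internal <- which(ph$edge[, 2] > length(ph$tip.label))[1]
  u <- ph$edge[internal, 1]
  D <- ape::dist.nodes(ph)
  ## query exactly at endpoint u with pendant 1: delta = dist(u, leaf) + 1
  delta <- D[u, seq_along(ph$tip.label)] + 1
  names(delta) <- ph$tip.label
  fit <- edgeFit(internal - 1L, delta, tree)
  expect_equal(fit$distal, 0, tolerance = 1e-9)
  expect_equal(fit$pendant, 1, tolerance = 1e-9)
  expect_equal(fit$lse, 0, tolerance = 1e-10)
})

test_that("two-leaf degenerate backbone is fitted exactly", {
  tree <- backboneTree(ape::read.tree(text = "(A:1,B:2);"))
  ph <- treePhylo(tree)
  ## point on the edge to A at x = 0.4 from the junction, pendant 0.1
  edgeA <- which(ph$edge[, 2] == match("A", ph$tip.label)) - 1L
  delta <- c(A = 0.1 + (1 - 0.4), B = 0.1 + 0.4 + 2)
  fit <- edgeFit(edgeA, delta, tree)
  expect_equal(fit$lse, 0, tolerance = 1e-12)
  expect_equal(fit$distal, 0.4, tolerance = 1e-9)
  expect_equal(fit$pendant, 0.1, tolerance = 1e-9)
})

test_that("additive distances give exact recovery of the pruning edge", {
  nTrees <- 12
  for (i in seq_len(nTrees)) {
    nl <- sample(c(8, 16, 32), 1)
    full <- simulateTree(nl, scale = 0.15, seed = 100 + i)
    q <- leafNames(full)[1]
    parts <- makeQueries(full, q)
    delta <- additiveDistances(full, q, leafNames(parts$backboneTree))
    pl <- placeQuery(delta, parts$backboneTree, queryId = q)
    expect_equal(pl@edgeNum, parts$truth$edge_num[1])
    expect_lt(pl@lse, 1e-10)
  }
})

test_that("per-edge fits agree with the brute-force grid optimizer", {
  set.seed(77)
  for (i in 1:5) {
    tree <- simulateTree(8, scale = 0.2, seed = 200 + i)
    n <- length(leafNames(tree))
    delta <- setNames(runif(n, 0.05, 1.2), leafNames(tree))
    w <- pmax(delta, 1e-6)^-2
    geom <- edgeGeometry(tree)
    for (e in seq_len(nEdges(tree)) - 1L) {
      fit <- edgeFit(e, delta, tree)
      g <- gridEdgeFit(tree, e, delta, w)
      expect_lt(abs(fit$lse - g["obj"]), 1e-6)
    }
  }
})

test_that("the returned placement minimizes the objective over all edges", {
  tree <- simulateTree(16, scale = 0.15, seed = 31)
  delta <- setNames(runif(16, 0.05, 1), leafNames(tree))
  pl <- placeQuery(delta, tree)
  for (e in seq_len(nEdges(tree)) - 1L)
    expect_lte(pl@lse, edgeFit(e, delta, tree)$lse + 1e-12)
})

test_that("ties are broken by the smallest edge number", {
  tree <- backboneTree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  delta <- c(A = 2, B = 2, C = 2, D = 2)   # fully symmetric query
  pl <- placeQuery(delta, tree)
  lses <- vapply(seq_len(nEdges(tree)) - 1L,
                 function(e) edgeFit(e, delta, tree)$lse, numeric(1))
  expect_equal(pl@edgeNum, as.integer(min(which(lses <= min(lses) + 1e-12)) - 1))
})

test_that("OLS weighting (exponent 0) matches the linear-model closed form", {
  tree <- simulateTree(8, scale = 0.2, seed = 41)
  geom <- edgeGeometry(tree)
  delta <- setNames(runif(8, 0.3, 1.5), geom$leafNames)
  param0 <- placementParam(weightExponent = 0)
  for (e in c(1L, 5L, 9L)) {
    r <- delta - geom$K[e + 1L, ]
    s <- geom$S[e + 1L, ]
    cf <- coef(lm(r ~ s))                  # intercept = pendant, slope = distal
    if (cf[1] >= 0 && cf[2] >= 0 && cf[2] <= geom$len[e + 1L]) {
      fit <- edgeFit(e, delta, tree, param = param0)
      expect_equal(unname(fit$pendant), unname(cf[1]), tolerance = 1e-8)
      expect_equal(unname(fit$distal), unname(cf[2]), tolerance = 1e-8)
    }
  }
})

test_that("queries with fewer than two usable distances are rejected", {
  tree <- simulateTree(6, scale = 0.1, seed = 51)
  delta <- setNames(rep(NA_real_, 6), leafNames(tree))
  delta[1] <- 0.2
  expect_error(placeQuery(delta, tree), "valid distances")
})

test_that("branch-length refit recovers simulated lengths on a fixed topology", {
  tree <- simulateTree(16, scale = 0.08, seed = 2)
  aln <- evolveJC69(tree, 5000, seed = 9)
  refit <- refitBranchLengths(tree, aln)
  expect_identical(treePhylo(refit)$edge, treePhylo(tree)$edge)
  idx <- edgeLengths(tree) >= 0.05
  relErr <- abs(edgeLengths(refit)[idx] - edgeLengths(tree)[idx]) /
    edgeLengths(tree)[idx]
  expect_lt(max(relErr), 0.15)
  ## deterministic: same input, same output
  refit2 <- refitBranchLengths(tree, aln)
  expect_identical(edgeLengths(refit), edgeLengths(refit2))
})

test_that("refit excludes gap-only pairs but still fits the rest", {
  tree <- simulateTree(6, scale = 0.1, seed = 61)
  aln <- evolveJC69(tree, 400, seed = 62)
  m <- as.matrix(aln)
  ## make one pair share no ungapped site
  m[1, 1:200] <- "-"
  m[2, 201:400] <- "-"
  aln2 <- seqAlignment(m, "DNA")
  refit <- refitBranchLengths(tree, aln2)
  expect_true(all(is.finite(edgeLengths(refit))))
  expect_true(all(edgeLengths(refit) >= 0))
})
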