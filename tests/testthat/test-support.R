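test_that("bootstrap weight matrices have multinomial structure", {
  w <- makeBootstrapWeights(50, 20, seed = 1)
  expect_true(all(w@weights[1, ] == 1))               # row 0 = original
  expect_true(all(rowSums(w@weights[-1, ]) == 50))    # each row resamples L
  expect_true(all(w@weights >= 0))
  w2 <- makeBootstrapWeights(50, 20, seed = 1)
  expect_identical(w@weights, w2@weights)             # deterministic
  w3 <- makeBootstrapWeights(50, 20, seed = 2)
  expect_false(identical(w@weights, w3@weights))
  expect_error(makeBootstrapWeights(0, 5, 1), "L")
  expect_error(makeBootstrapWeights(10, 0, 1), "B")
})

test_that("bootstrap sampling counts have the multinomial mean", {
  w <- makeBootstrapWeights(100, 10000, seed = 7)
  means <- colMeans(w@weights[-1, ])
  se <- sqrt(1 * (1 - 1 / 100) / 10000)   # per-site count variance ~ 1
  expect_lt(max(abs(means - 1)), 4 * se)
  expect_lt(abs(mean(means) - 1), 1e-12)  # rows sum to L exactly
})

test_that("subsample weight matrices select b distinct sites per replicate", {
  w <- makeSubsampleWeights(1000, 5, seed = 3)
  expect_equal(w@b, 501L)                 # default b = round(1000^0.9)
  expect_true(all(w@weights %in% 0:1))
  expect_true(all(rowSums(w@weights[-1, ]) == 501))
  wFull <- makeSubsampleWeights(40, 5, seed = 3, b = 40)
  expect_true(all(wFull@weights == 1))    # exhaustive subsample
  expect_error(makeSubsampleWeights(40, 5, seed = 3, b = 41), "b must")
})

test_that("matrix-formulation bootstrap equals the naive string oracle", {
  for (i in 1:6) {
    n <- sample(4:8, 1)
    L <- sample(20:60, 1)
    aln <- randomAlignment(n, L, seed = 300 + i, gapFrac = 0.15)
    q <- as.matrix(randomAlignment(1, L, seed = 400 + i, gapFrac = 0.15))[1, ]
    prof <- buildProfile(q, aln)
    w <- makeBootstrapWeights(L, 12, seed = 500 + i)
    P <- w@weights %*% prof@V
    Lp <- w@weights %*% prof@G
    for (r in seq_len(nrow(w@weights))) {
      o <- naiveBootstrapOracle(aln, q, w@weights[r, ])
      expect_identical(unname(P[r, ]), unname(as.numeric(o$mismatches)))
      expect_identical(unname(Lp[r, ]), unname(as.numeric(o$validSites)))
    }
    ## and the derived Hamming/JC distances match the direct computation
    d <- fastBootstrapDistances(w, prof)
    o0 <- naiveBootstrapOracle(aln, q, rep(1L, L))
    h0 <- ifelse(o0$validSites > 0, o0$mismatches / o0$validSites, NA)
    expect_identical(unname(d@hamming[1, ]), unname(h0))
  }
})

test_that("an identity weight row reproduces direct pairwise distances", {
  aln <- randomAlignment(5, 30, seed = 9, gapFrac = 0.1)
  q <- as.matrix(randomAlignment(1, 30, seed = 10, gapFrac = 0.1))[1, ]
  prof <- buildProfile(q, aln)
  w <- makeBootstrapWeights(30, 1, seed = 1)
  d <- fastBootstrapDistances(w, prof)
  for (j in seq_len(5)) {
    o <- directCounts(q, as.matrix(aln)[j, ])
    if (o["valid"] > 0)
      expect_equal(unname(d@hamming[1, j]), unname(o["mism"] / o["valid"]))
  }
})

test_that("replicates sampling only gapped overlap are flagged invalid", {
  ## r1 overlaps the query only in the first half, r2 everywhere; a
  ## replicate drawing only second-half sites leaves r1 with L' = 0
  aln <- seqAlignment(c(r1 = "AAAA----", r2 = "AAAAAAAA"), "DNA")
  q <- "AAAACAAA"
  prof <- buildProfile(q, aln)
  W <- new("ReplicateWeights", kind = "bootstrap",
           weights = rbind(rep(1L, 8), c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L)),
           B = 1L, b = NA_integer_, seed = 1L)
  d <- fastBootstrapDistances(W, prof)
  expect_false(d@valid[2, 1])   # L' = 0 for r1 in the replicate
  expect_true(d@valid[2, 2])
  expect_true(all(d@valid[1, ]))
})

test_that("full-size subsampling reproduces the original distances exactly", {
  aln <- randomAlignment(5, 40, seed = 12, gapFrac = 0.1)
  q <- as.matrix(randomAlignment(1, 40, seed = 13, gapFrac = 0.1))[1, ]
  prof <- buildProfile(q, aln)
  w <- makeSubsampleWeights(40, 8, seed = 2, b = 40)
  d <- subsampleDistances(w, prof)
  for (r in 2:9)
    expect_equal(unname(d@hamming[r, ]), unname(d@hamming[1, ]))
})

test_that("subsample correction leaves h_n fixed when h_b equals h_n", {
  ## identical query and reference: every subsample gives h_b = h_n = 0,
  ## so the corrected value is h_n regardless of b
  aln <- seqAlignment(c(r1 = paste(rep("A", 50), collapse = "")), "DNA")
  qSame <- paste(rep("A", 50), collapse = "")
  prof <- buildProfile(qSame, aln)
  w <- makeSubsampleWeights(50, 5, seed = 4, b = 20)
  d <- subsampleDistances(w, prof)
  expect_true(all(d@hamming == 0))
  expect_true(all(d@corrected == 0))
})

test_that("corrected subsample variance matches its sampling-theory value", {
  ## matched Monte-Carlo design: one JC pair at t = 0.2, L = 2000.
  ## The sqrt(b/n) correction rescales the subsample estimator's spread by
  ## b/n; drawing b of n sites without replacement has the finite-population
  ## variance (sigma^2 / b) (n - b)/(n - 1), so the corrected replicate
  ## variance is the bootstrap variance times (n - b)/(n - 1).
  tr <- backboneTree(ape::read.tree(text = "(A:0.1,B:0.1);"))
  aln <- evolveJC69(tr, 2000, seed = 5)
  backbone <- aln["A"]
  q <- as.matrix(aln)["B", ]
  prof <- buildProfile(q, backbone)
  B <- 2000
  wb <- makeBootstrapWeights(2000, B, seed = 6)
  ws <- makeSubsampleWeights(2000, B, seed = 6)   # b = round(2000^0.9)
  db <- fastBootstrapDistances(wb, prof)
  ds <- subsampleDistances(ws, prof)
  vBoot <- var(db@hamming[-1, 1])
  vSub <- var(ds@hamming[-1, 1])
  expected <- (2000 - ws@b) / (2000 - 1)
  expect_lt(abs(vSub / vBoot - expected) / expected, 0.15)
})

test_that("parametric draws have the stated moments", {
  B <- 5000
  hHat <- c(a = 0.25); l <- c(a = 400)
  db <- parametricDistances(hHat, l, B, mode = "binomial", seed = 8)
  xs <- db@hamming[-1, 1]
  se <- sqrt(0.25 * 0.75 / 400) / sqrt(B)
  expect_lt(abs(mean(xs) - 0.25), 3 * se)
  dp <- parametricDistances(hHat, l, B, mode = "poisson", seed = 8)
  xsP <- dp@hamming[-1, 1] * 400
  seP <- sqrt(0.25 * 400) / sqrt(B)
  expect_lt(abs(mean(xsP) - 100), 3 * seP)
  ## degenerate case: h = 0 gives all-zero draws and t = 0
  d0 <- parametricDistances(c(a = 0), c(a = 100), 50, "binomial", seed = 9)
  expect_true(all(d0@hamming == 0))
  expect_true(all(d0@corrected == 0))
  expect_error(parametricDistances(c(a = 0.8), c(a = 100), 10, "binomial",
                                   seed = 1), "saturated")
})

test_that("support aggregation is the definitional replicate fraction", {
  agg <- lspplace:::aggregateSupport
  edges <- c(rep(5L, 75), rep(2L, 25))
  s <- agg(edges)
  expect_equal(unname(s), c(0.75, 0.25))
  expect_equal(names(s), c("5", "2"))
  expect_equal(sum(s), 1)
  ## invalid replicates drop out of the denominator
  s2 <- agg(c(rep(5L, 3), NA, NA))
  expect_equal(unname(s2), 1)
  expect_error(agg(c(NA_integer_, NA_integer_)), "all replicates invalid")
})

test_that("support fractions sum to one and B = 1 gives unit support", {
  sc <- tinyScenario()
  q <- seqIds(sc$queryAlignment)[1]
  qrow <- as.matrix(sc$queryAlignment)[q, ]
  for (m in c("fast_bs", "subsample", "binomial", "poisson")) {
    sp <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                         method = m, B = 20, seed = 5, queryId = q)
    expect_equal(sum(supportValues(sp)), 1, tolerance = 1e-9,
                 label = paste("support sum,", m))
  }
  sp1 <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                        method = "fast_bs", B = 1, seed = 5, queryId = q)
  expect_equal(unname(supportValues(sp1)), 1)
})

test_that("computeSupport is deterministic under a fixed seed", {
  sc <- tinyScenario()
  q <- seqIds(sc$queryAlignment)[2]
  qrow <- as.matrix(sc$queryAlignment)[q, ]
  for (m in c("fast_bs", "subsample", "binomial")) {
    a <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                        method = m, B = 15, seed = 42, queryId = q)
    b <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                        method = m, B = 15, seed = 42, queryId = q)
    expect_identical(supportValues(a), supportValues(b))
  }
})

test_that("slow bootstrap without refit reproduces the fast pipeline", {
  sc <- tinyScenario()
  q <- seqIds(sc$queryAlignment)[1]
  qrow <- as.matrix(sc$queryAlignment)[q, ]
  w <- makeBootstrapWeights(nSites(sc$backboneAlignment), 15, seed = 7)
  fast <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                         method = "fast_bs", B = 15, seed = 7, weights = w,
                         queryId = q)
  slow <- slowBootstrap(qrow, sc$backboneAlignment, sc$backboneTree,
                        B = 15, seed = 7, refit = FALSE, weights = w,
                        queryId = q)
  expect_identical(supportValues(fast), supportValues(slow))
  expect_equal(bestPlacement(fast)@edgeNum, bestPlacement(slow)@edgeNum)
})

test_that("slow bootstrap with refit runs and is deterministic", {
  sc <- simulateScenario(nLeaves = 10, L = 200, nQueries = 1, scale = 0.08,
                         seed = 13)
  q <- seqIds(sc$queryAlignment)[1]
  qrow <- as.matrix(sc$queryAlignment)[q, ]
  a <- slowBootstrap(qrow, sc$backboneAlignment, sc$backboneTree,
                     B = 5, seed = 3, refit = TRUE, queryId = q)
  b <- slowBootstrap(qrow, sc$backboneAlignment, sc$backboneTree,
                     B = 5, seed = 3, refit = TRUE, queryId = q)
  expect_identical(supportValues(a), supportValues(b))
  expect_equal(sum(supportValues(a)), 1, tolerance = 1e-9)
  b1 <- slowBootstrap(qrow, sc$backboneAlignment, sc$backboneTree,
                      B = 1, seed = 3, refit = TRUE, queryId = q)
  expect_equal(unname(supportValues(b1)), 1)
})

test_that("a signal-free query spreads support over several edges", {
  sc <- simulateScenario(nLeaves = 12, L = 400, nQueries = 2, scale = 0.08,
                         seed = 17)
  set.seed(99)
  noise <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  sp <- computeSupport(noise, sc$backboneAlignment, sc$backboneTree,
                       method = "fast_bs", B = 100, seed = 23,
                       queryId = "noise")
  expect_gt(length(supportValues(sp)), 1)
  expect_lt(max(supportValues(sp)), 1)
})

test_that("parametric and bootstrap support rank edges concordantly", {
  sc <- tinyScenario(seed = 19)
  q <- seqIds(sc$queryAlignment)[1]
  qrow <- as.matrix(sc$queryAlignment)[q, ]
  bs <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                       "fast_bs", B = 100, seed = 29, queryId = q)
  pm <- computeSupport(qrow, sc$backboneAlignment, sc$backboneTree,
                       "binomial", B = 100, seed = 29, queryId = q)
  ## same top edge, and positive rank agreement over the union of edges
  expect_equal(names(supportValues(bs))[1], names(supportValues(pm))[1])
  edges <- union(names(supportValues(bs)), names(supportValues(pm)))
  a <- supportValues(bs)[edges]; a[is.na(a)] <- 0
  b <- supportValues(pm)[edges]; b[is.na(b)] <- 0
  if (length(edges) > 2)
    expect_gt(cor(a, b, method = "spearman"), 0)
})

test_that("amino-acid support goes through the Scoredist slow path", {
  base <- strsplit("ACDEFGHIKLMNPQRSTVWYACDEFGHIKL", "")[[1]]
  mut <- function(s, at, to) { s[at] <- to; s }
  seqs <- rbind(A = base,
                B = mut(base, c(2, 11), c("S", "T")),
                C = mut(base, c(5, 17, 23), c("A", "G", "V")),
                D = mut(base, c(5, 17, 29), c("A", "G", "K")))
  backbone <- seqAlignment(seqs, "AA")
  tree <- backboneTree(ape::read.tree(
    text = "((A:0.05,B:0.05):0.04,(C:0.05,D:0.05):0.04);"))
  q <- mut(base, c(5, 17), c("A", "G"))   # near the C/D cherry
  sp <- slowBootstrap(q, backbone, tree, B = 20, seed = 3, refit = FALSE,
                      queryId = "q")
  expect_s4_class(sp, "SupportedPlacement")
  expect_equal(sum(supportValues(sp)), 1, tolerance = 1e-9)
  sp2 <- slowBootstrap(q, backbone, tree, B = 20, seed = 3, refit = FALSE,
                       queryId = "q")
  expect_identical(supportValues(sp), supportValues(sp2))
  ## the placement should land on the C/D side of the tree
  ph <- treePhylo(tree)
  cd <- ape::getMRCA(ph, c("C", "D"))
  cdEdges <- which(ph$edge[, 1] == cd | ph$edge[, 2] == cd) - 1L
  expect_true(bestPlacement(sp)@edgeNum %in% cdEdges)
  ## refit is JC69-based and refuses AA input
  expect_error(slowBootstrap(q, backbone, tree, B = 5, seed = 3,
                             refit = TRUE, queryId = "q"),
               "amino-acid")
  ## fast and parametric methods are DNA-only
  expect_error(computeSupport(q, backbone, tree, "fast_bs", B = 5, seed = 1,
                              queryId = "q"), "DNA-only")
})
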