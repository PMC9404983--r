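## Shared fixtures and independent oracles for the test suite.

## random gapped alignment fixture (character-level, built in code)
randomAlignment <- function(n, L, seed, gapFrac = 0.1, alphabet = "DNA") {
  set.seed(seed)
  core <- if (alphabet == "DNA") c("A", "C", "G", "T") else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(sample(core, n * L, replace = TRUE), n, L)
  if (gapFrac > 0)
    m[matrix(runif(n * L) < gapFrac, n, L)] <- "-"
  rownames(m) <- paste0("s", seq_len(n))
  seqAlignment(m, alphabet)
}

## independent per-site mismatch/valid counting by direct character
## comparison (no matrix algebra) — the string-level oracle
directCounts <- function(query, refRow) {
  obs <- function(ch) ch %in% c("A", "C", "G", "T")
  both <- obs(query) & obs(refRow)
  c(mism = sum(both & query != refRow), valid = sum(both))
}

## Independent objective evaluation for a candidate placement (edge, x, p):
## path distances are recomputed from ape::dist.nodes, with the side of each
## leaf determined by comparing its distance to the two edge endpoints.
placementObjective <- function(tree, edgeNum, x, p, delta, w) {
  ph <- treePhylo(tree)
  ntip <- length(ph$tip.label)
  D <- ape::dist.nodes(ph)
  u <- ph$edge[edgeNum + 1L, 1L]
  v <- ph$edge[edgeNum + 1L, 2L]
  len <- ph$edge.length[edgeNum + 1L]
  leaves <- seq_len(ntip)
  distalSide <- D[v, leaves] < D[u, leaves]
  d <- ifelse(distalSide, p + (len - x) + D[v, leaves],
              p + x + D[u, leaves])
  delta <- delta[ph$tip.label]
  sum(w * (delta - d)^2, na.rm = TRUE)
}

## Brute-force constrained optimizer for one edge: coarse grid then local
## polish with L-BFGS-B on the directly-evaluated objective.
gridEdgeFit <- function(tree, edgeNum, delta, w, gridN = 41) {
  ph <- treePhylo(tree)
  len <- ph$edge.length[edgeNum + 1L]
  pmaxv <- max(delta, na.rm = TRUE) + 0.5
  xs <- seq(0, len, length.out = gridN)
  ps <- seq(0, pmaxv, length.out = gridN)
  best <- c(obj = Inf, x = 0, p = 0)
  for (x in xs) for (p in ps) {
    o <- placementObjective(tree, edgeNum, x, p, delta, w)
    if (o < best["obj"]) best <- c(obj = o, x = x, p = p)
  }
  if (len > 0 || pmaxv > 0) {
    fn <- function(par) placementObjective(tree, edgeNum, par[1], par[2],
                                           delta, w)
    op <- optim(c(best["x"], best["p"]), fn, method = "L-BFGS-B",
                lower = c(0, 0), upper = c(max(len, 1e-12), pmaxv + 1))
    if (op$value < best["obj"])
      best <- c(obj = op$value, x = op$par[1], p = op$par[2])
  }
  best
}

## additive (true path) distances from a leaf of the full tree to the
## remaining leaves, used for exact-recovery tests
additiveDistances <- function(fullTree, queryLeaf, backboneLeaves) {
  ph <- treePhylo(fullTree)
  D <- ape::dist.nodes(ph)
  qi <- match(queryLeaf, ph$tip.label)
  d <- D[qi, match(backboneLeaves, ph$tip.label)]
  names(d) <- backboneLeaves
  d
}

## tiny deterministic backbone + query used across IO/support tests
tinyScenario <- function(seed = 3) {
  sc <- simulateScenario(nLeaves = 12, L = 60, nQueries = 2, scale = 0.08,
                         seed = seed)
  sc
}

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
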