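#' @include AllClasses.R
NULL

#' Simulate a random backbone tree
#'
#' Generates a random unrooted binary topology with independent
#' exponentially distributed branch lengths. This is the tree model behind
#' all synthetic placement scenarios: a desk-scale stand-in with known true
#' branch lengths in substitutions/site.
#'
#' @param nLeaves number of leaves (>= 4).
#' @param scale mean branch length in substitutions/site (default 0.05, a
#'   moderately diverged single-gene backbone).
#' @param seed RNG seed.
#' @return a \code{BackboneTree}
#' @export
simulateTree <- function(nLeaves, scale = 0.05, seed) {
  if (nLeaves < 4L) stop("nLeaves must be >= 4")
  ph <- withSeed(seed, {
    t0 <- ape::unroot(ape::rtree(nLeaves, br = NULL))
    t0$edge.length <- stats::rexp(nrow(t0$edge), rate = 1 / scale)
    t0
  })
  backboneTree(ph)
}

#' Evolve sequences down a tree under JC69
#'
#' The root sequence is uniform over \{A, C, G, T\}; along each branch of
#' length t every site independently changes with probability
#' \code{h = 3/4 (1 - exp(-4t/3))}, and a changing site picks one of the
#' three alternative bases uniformly. No indels are simulated: fragmentary
#' data are produced by masking (\code{\link{fragmentQuery}}), matching the
#' model the placement method itself assumes.
#'
#' @param tree a \code{BackboneTree}.
#' @param L number of sites.
#' @param seed RNG seed.
#' @return a \code{SeqAlignment} of the leaf sequences.
#' @export
evolveJC69 <- function(tree, L, seed) {
  ph <- ape::reorder.phylo(treePhylo(tree), "cladewise")  # parents first
  ntip <- length(ph$tip.label)
  nnode <- ntip + ph$Nnode
  root <- setdiff(ph$edge[, 1L], ph$edge[, 2L])[1L]
  states <- matrix(NA_integer_, nnode, L)
  withSeed(seed, {
    states[root, ] <- sample.int(4L, L, replace = TRUE)
    for (r in seq_len(nrow(ph$edge))) {
      par <- ph$edge[r, 1L]; child <- ph$edge[r, 2L]
      h <- jc69ExpectedH(ph$edge.length[r])
      s <- states[par, ]
      mut <- runif(L) < h
      if (any(mut))
        s[mut] <- 1L + (s[mut] - 1L + sample.int(3L, sum(mut),
                                                 replace = TRUE)) %% 4L
      states[child, ] <- s
    }
  })
  m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), ]], nrow = ntip,
              dimnames = list(ph$tip.label, NULL))
  seqAlignment(m, "DNA")
}

#' Prune query leaves and record their true attachment edges
#'
#' Removes the selected leaves from the tree (suppressing the resulting
#' degree-2 nodes and summing the merged branch lengths) and records, for
#' each removed leaf, the edge of the pruned tree onto which it attaches.
#' The attachment edge is resolved combinatorially: with all other queries
#' removed, the query's attachment node splits the remaining leaves in two;
#' the pruned-tree edge carrying exactly that bipartition is the truth.
#'
#' @param tree original \code{BackboneTree}.
#' @param queryIds leaf labels to prune (must leave >= 4 leaves, i.e.
#'   \code{length(queryIds) < nLeaves - 3}).
#' @param alignment optional \code{SeqAlignment} on the full leaf set; when
#'   given, it is split into backbone and query alignments.
#' @return list: \code{backboneTree} (pruned), \code{truth}
#'   (data.frame query_id, edge_num), and when \code{alignment} is supplied,
#'   \code{backboneAlignment} and \code{queryAlignment}.
#' @export
makeQueries <- function(tree, queryIds, alignment = NULL) {
  ph <- treePhylo(tree)
  labs <- ph$tip.label
  if (!all(queryIds %in% labs)) stop("unknown query leaves")
  if (length(queryIds) >= length(labs) - 3L)
    stop("too many queries: need length(queryIds) < nLeaves - 3")
  ph2 <- ape::drop.tip(ph, queryIds)
  ## drop.tip suppresses internal degree-2 nodes but keeps a degree-2 root;
  ## merge its two basal edges too, per the pruning contract (every degree-2
  ## node is suppressed and the merged branch lengths are summed)
  nt2 <- length(ph2$tip.label)
  root2 <- setdiff(ph2$edge[, 1L], ph2$edge[, 2L])[1L]
  if (sum(ph2$edge[, 1L] == root2) == 2L && nt2 > 2L)
    ph2 <- ape::unroot(ph2)
  pruned <- backboneTree(ph2)
  keys <- edgeBipartitionKeys(pruned)
  anchor <- min(leafNames(pruned))
  ## min edge_num per key: when a degree-2 root duplicates a bipartition the
  ## placement tie rule picks the smaller edge number, so the truth must too
  keyMap <- tapply(seq_along(keys) - 1L, keys, min)
  truth <- data.frame(query_id = queryIds,
                      edge_num = NA_integer_, stringsAsFactors = FALSE)
  for (qi in seq_along(queryIds)) {
    q <- queryIds[qi]
    others <- setdiff(queryIds, q)
    phq <- if (length(others)) ape::drop.tip(ph, others) else ph
    tipIdx <- match(q, phq$tip.label)
    parent <- phq$edge[phq$edge[, 2L] == tipIdx, 1L]
    ## leaves on the far side of the attachment node, seen from q:
    ## one of the bipartition sides of the merged edge is the clade of the
    ## attachment node's other child(ren) once q's pendant edge is cut.
    sets <- cladeTips(ape::reorder.phylo(phq, "postorder"))
    kids <- phq$edge[phq$edge[, 1L] == parent, 2L]
    kids <- setdiff(kids, tipIdx)
    rootNode <- setdiff(phq$edge[, 1L], phq$edge[, 2L])[1L]
    if (parent == rootNode) {
      ## the attachment node is the root: removing q leaves a degree-2 root
      ## whose two incident edges merge; the merged edge separates the two
      ## remaining child clades, so either clade is a bipartition side
      if (length(kids) != 2L)
        stop("attachment node of '", q, "' keeps degree >= 3 after pruning; ",
             "truth edge is ambiguous on non-binary trees")
      sideTips <- phq$tip.label[sets[[kids[1L]]]]
    } else {
      if (length(kids) != 1L)
        stop("attachment node of '", q, "' keeps degree >= 3 after pruning; ",
             "truth edge is ambiguous on non-binary trees")
      sideTips <- phq$tip.label[sets[[kids]]]
    }
    sideTips <- setdiff(sideTips, q)
    allTips <- setdiff(phq$tip.label, q)
    if (anchor %in% sideTips) sideTips <- setdiff(allTips, sideTips)
    key <- paste(sort(sideTips), collapse = "\r")
    hit <- keyMap[key]
    if (is.na(hit))
      stop("could not resolve attachment edge for '", q, "'")
    truth$edge_num[qi] <- as.integer(hit)
  }
  out <- list(backboneTree = pruned, truth = truth)
  if (!is.null(alignment)) {
    out$backboneAlignment <- alignment[setdiff(seqIds(alignment), queryIds)]
    out$queryAlignment <- alignment[queryIds]
  }
  out
}

#' Fragment an aligned query sequence
#'
#' Emulates fragmentary (read-like) queries: keeps a contiguous window of
#' \code{fragmentLength} non-gap characters starting at a uniformly chosen
#' admissible position, and replaces every other non-gap character with a
#' gap. Alignment coordinates are preserved.
#'
#' @param query aligned sequence (single string or character vector).
#' @param fragmentLength number of non-gap characters to keep.
#' @param seed RNG seed (fixes the window position).
#' @return character vector of the same length as the input.
#' @export
fragmentQuery <- function(query, fragmentLength, seed) {
  chars <- if (length(query) == 1L) strsplit(query, "")[[1L]] else query
  nonGap <- which(chars != "-" & chars != ".")
  if (fragmentLength > length(nonGap))
    stop("fragment longer than the sequence (", length(nonGap),
         " non-gap characters)")
  start <- withSeed(seed,
                    sample.int(length(nonGap) - fragmentLength + 1L, 1L))
  keep <- nonGap[start:(start + fragmentLength - 1L)]
  out <- rep("-", length(chars))
  out[keep] <- chars[keep]
  out
}

#' Naive bootstrap counting oracle
#'
#' The reference computation that the linear-algebraic bootstrap must match
#' bit-exactly: materialize one resampled alignment by repeating each column
#' according to a weight row, then count mismatches and mutually observed
#' sites by direct string comparison against every reference.
#'
#' @param alignment backbone \code{SeqAlignment}.
#' @param query aligned query (string or character vector).
#' @param hRow integer vector of length L: per-site sampling counts.
#' @return list with \code{mismatches} and \code{validSites}, named per
#'   reference.
#' @export
naiveBootstrapOracle <- function(alignment, query, hRow) {
  if (length(query) == 1L) query <- strsplit(toupper(query), "")[[1L]]
  L <- nSites(alignment)
  if (length(hRow) != L) stop("hRow length must equal L")
  cols <- rep(seq_len(L), hRow)
  M <- as.matrix(alignment)[, cols, drop = FALSE]
  q <- query[cols]
  qObs <- isObserved(q, alignment@alphabet)
  mism <- integer(nrow(M)); valid <- integer(nrow(M))
  for (i in seq_len(nrow(M))) {
    both <- qObs & isObserved(M[i, ], alignment@alphabet)
    valid[i] <- sum(both)
    mism[i] <- sum(both & M[i, ] != q)
  }
  list(mismatches = setNames(mism, seqIds(alignment)),
       validSites = setNames(valid, seqIds(alignment)))
}

#' Simulate a complete placement scenario
#'
#' Ties the generator together: a random tree on \code{nLeaves} leaves,
#' JC69-evolved sequences, \code{nQueries} leaves pruned out as queries with
#' their true attachment edges recorded, and (optionally) fragmentary query
#' versions produced by windowed masking. All stages derive their randomness
#' from \code{seed}.
#'
#' @param nLeaves total number of simulated leaves (backbone keeps
#'   \code{nLeaves - nQueries}).
#' @param L alignment length.
#' @param nQueries number of leaves pruned as queries.
#' @param scale mean branch length (substitutions/site).
#' @param fragmentLength optional non-gap length for fragmentary queries.
#' @param seed RNG seed.
#' @return list: backboneTree, backboneAlignment, queryAlignment, truth,
#'   fullTree, fullAlignment, and fragmentedQueries when requested.
#' @export
simulateScenario <- function(nLeaves, L, nQueries, scale = 0.05,
                             fragmentLength = NULL, seed) {
  if (nQueries >= nLeaves - 3L) stop("nQueries must be < nLeaves - 3")
  if (!is.null(fragmentLength) && fragmentLength > L)
    stop("fragmentLength must be <= L")
  tree <- simulateTree(nLeaves, scale = scale, seed = seed)
  aln <- evolveJC69(tree, L, seed = seed + 1L)
  qIds <- withSeed(seed + 2L,
                   sample(leafNames(tree), nQueries))
  parts <- makeQueries(tree, qIds, alignment = aln)
  out <- list(backboneTree = parts$backboneTree,
              backboneAlignment = parts$backboneAlignment,
              queryAlignment = parts$queryAlignment,
              truth = parts$truth, fullTree = tree, fullAlignment = aln)
  if (!is.null(fragmentLength)) {
    qm <- as.matrix(parts$queryAlignment)
    fm <- qm
    for (i in seq_len(nrow(qm)))
      fm[i, ] <- fragmentQuery(qm[i, ], fragmentLength,
                               seed = querySeed(seed + 3L, rownames(qm)[i]))
    out$fragmentedQueries <- seqAlignment(fm, seqAlphabet(parts$queryAlignment))
  }
  out
}
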