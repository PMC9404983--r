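#' @include AllClasses.R
NULL

#' Bootstrap site-resampling weights
#'
#' Generates the (B+1) x L matrix H of the linear-algebraic bootstrap: row 0
#' is all ones (the original alignment) and each of the B following rows
#' counts how many times each site was drawn when sampling L sites with
#' replacement. H is computed once per run and shared by all queries, so
#' every query sees the same replicate alignments.
#'
#' @param L alignment length (>= 1).
#' @param B number of replicates (>= 1).
#' @param seed RNG seed (required; the matrix is deterministic given it).
#' @return a \code{ReplicateWeights} of kind "bootstrap"
#' @export
makeBootstrapWeights <- function(L, B, seed) {
  if (L < 1L) stop("L must be >= 1")
  if (B < 1L) stop("B must be >= 1")
  H <- withSeed(seed, {
    t(vapply(seq_len(B),
             function(i) tabulate(sample.int(L, L, replace = TRUE), L),
             integer(L)))
  })
  W <- rbind(rep(1L, L), H)
  new("ReplicateWeights", kind = "bootstrap", weights = W, B = as.integer(B),
      b = NA_integer_, seed = as.integer(seed))
}

#' Subsampling (m-out-of-n) site-selection weights
#'
#' Each replicate row selects b distinct sites uniformly without replacement
#' (binary indicators); row 0 is all ones. The default subsample size is
#' \code{b = round(L^0.9)} (round-half-even), small enough that replicates
#' differ but large enough for the sqrt(b/n) variance correction to apply.
#'
#' @param L alignment length.
#' @param B number of replicates.
#' @param b subsample size, \code{1 <= b <= L}; default \code{round(L^0.9)}.
#' @param seed RNG seed.
#' @return a \code{ReplicateWeights} of kind "subsample"
#' @export
makeSubsampleWeights <- function(L, B, seed, b = NULL) {
  if (L < 1L) stop("L must be >= 1")
  if (B < 1L) stop("B must be >= 1")
  if (is.null(b)) b <- round(L ^ 0.9)
  b <- as.integer(b)
  if (b < 1L || b > L) stop("b must satisfy 1 <= b <= L")
  S <- withSeed(seed, {
    t(vapply(seq_len(B), function(i) {
      row <- integer(L)
      row[sample.int(L, b)] <- 1L
      row
    }, integer(L)))
  })
  W <- rbind(rep(1L, L), S)
  new("ReplicateWeights", kind = "subsample", weights = W, B = as.integer(B),
      b = b, seed = as.integer(seed))
}

#' Fast (linear-algebraic) bootstrap distances
#'
#' The core of fast bootstrapping: replicate mismatch counts are the single
#' matrix product \code{P = H V} and replicate valid-site counts are
#' \code{L' = H G}, where V/G are the query's mismatch profile. The result is
#' bit-exact equal to materializing each resampled alignment and re-counting
#' mismatches by string comparison, but performs the string work only once.
#'
#' @param weights a \code{ReplicateWeights} (bootstrap kind).
#' @param profile a \code{MismatchProfile} with L rows matching the weights.
#' @return a \code{DistanceReplicates}
#' @export
fastBootstrapDistances <- function(weights, profile) {
  stopifnot(is(weights, "ReplicateWeights"), is(profile, "MismatchProfile"))
  H <- weights@weights
  if (ncol(H) != nrow(profile@V))
    stop("weight columns (", ncol(H), ") do not match profile sites (",
         nrow(profile@V), ")")
  P <- H %*% profile@V
  Lp <- H %*% profile@G
  distancesFromCounts(P, Lp, queryId = profile@queryId)
}

#' Subsample distances with m-out-of-n variance correction
#'
#' Computes replicate Hamming distances from b-site subsamples
#' (\code{P' = S V}, normalized by the subsampled valid-site counts), then
#' restores the variance of the full-data estimator with the correction
#' \code{h_corrected = sqrt(b/n) (h_b - h_n) + h_n}, where h_n is the
#' original-alignment Hamming distance and n the total number of sites. The
#' JC69 correction is applied last. Corrected values below 0 are clamped to
#' 0; values at or above 3/4 are flagged invalid (JC69 domain).
#'
#' @param weights a \code{ReplicateWeights} of kind "subsample".
#' @param profile a \code{MismatchProfile}.
#' @return a \code{DistanceReplicates} (row 0 = uncorrected original)
#' @export
subsampleDistances <- function(weights, profile) {
  stopifnot(is(weights, "ReplicateWeights"), is(profile, "MismatchProfile"))
  if (weights@kind != "subsample") stop("weights must be of kind 'subsample'")
  S <- weights@weights
  L <- nrow(profile@V)
  if (ncol(S) != L) stop("weight columns do not match profile sites")
  P <- S %*% profile@V
  Lp <- S %*% profile@G
  h <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  pos <- Lp > 0
  h[pos] <- P[pos] / Lp[pos]
  hn <- h[1L, ]                       # full-alignment Hamming per reference
  fac <- sqrt(weights@b / L)
  hc <- h
  for (i in seq_len(nrow(h))[-1L])
    hc[i, ] <- pmax(fac * (h[i, ] - hn) + hn, 0)
  valid <- pos & !is.na(hc) & hc < 0.75
  corrected <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  corrected[valid] <- jc69Correct(hc[valid])
  new("DistanceReplicates", queryId = profile@queryId, hamming = hc,
      corrected = corrected, validSites = Lp, valid = valid,
      B = nrow(P) - 1L)
}

#' Parametric (binomial/Poisson) replicate distances
#'
#' Models each query-reference distance independently: with l mutually
#' observed sites and observed Hamming fraction h-hat, replicate mismatch
#' counts are drawn as \code{x ~ Binomial(l, h-hat)} (or
#' \code{Poisson(h-hat l)}), then transformed back through the JC69
#' correction \code{t = -3/4 log(1 - 4x/(3l))}. Draws are independent across
#' references, ignoring the covariance induced by shared tree paths — the
#' known simplification of this scheme. Draws with \code{x/l >= 3/4} are
#' flagged invalid.
#'
#' @param hHat observed normalized Hamming distance per reference
#'   (all < 3/4; saturated references must be removed by the caller).
#' @param l mutually observed site count per reference (>= 1).
#' @param B number of replicates.
#' @param mode "binomial" or "poisson".
#' @param seed RNG seed.
#' @param queryId identifier carried through.
#' @return a \code{DistanceReplicates} (row 0 = observed h-hat)
#' @export
parametricDistances <- function(hHat, l, B, mode = c("binomial", "poisson"),
                                seed, queryId = "query") {
  mode <- match.arg(mode)
  if (any(hHat < 0, na.rm = TRUE)) stop("negative Hamming distance")
  if (any(hHat >= 0.75, na.rm = TRUE))
    stop("saturated h-hat (>= 3/4) on input")
  if (any(l < 1, na.rm = TRUE)) stop("l must be >= 1")
  n <- length(hHat)
  x <- withSeed(seed, {
    if (mode == "binomial")
      matrix(rbinom(B * n, size = rep(l, each = B),
                    prob = rep(hHat, each = B)), nrow = B)
    else
      matrix(rpois(B * n, lambda = rep(hHat * l, each = B)), nrow = B)
  })
  h <- rbind(hHat, sweep(x, 2L, l, "/"))
  Lp <- matrix(rep(l, each = B + 1L), nrow = B + 1L)
  dimnames(h) <- list(NULL, names(hHat))
  valid <- !is.na(h) & h < 0.75
  corrected <- matrix(NA_real_, nrow(h), ncol(h), dimnames = dimnames(h))
  corrected[valid] <- jc69Correct(h[valid])
  new("DistanceReplicates", queryId = queryId, hamming = h,
      corrected = corrected, validSites = Lp, valid = valid,
      B = as.integer(B))
}

## Aggregate per-replicate edge choices (NA = invalid replicate) into
## support fractions, sorted by decreasing support with ties broken by
## smaller edge number.
aggregateSupport <- function(edges) {
  ok <- !is.na(edges)
  if (!any(ok)) stop("all replicates invalid")
  tab <- table(edges[ok])
  sup <- as.numeric(tab) / sum(ok)
  names(sup) <- names(tab)
  ord <- order(-sup, as.integer(names(sup)))
  sup[ord]
}

#' Slow bootstrap: materialized replicates with branch-length re-estimation
#'
#' The reference implementation of bootstrapping: each replicate alignment is
#' materialized by repeating sites according to a bootstrap weight row, the
#' backbone branch lengths are optionally re-estimated on the fixed topology
#' from the resampled backbone sequences, the query distances are recomputed
#' on the resampled columns, and the query is placed. With \code{refit =
#' FALSE} the per-replicate edge choices are identical to the fast
#' linear-algebraic pipeline given the same weight matrix.
#'
#' @param query aligned query sequence (named string or character vector).
#' @param backbone backbone \code{SeqAlignment}.
#' @param tree backbone \code{BackboneTree}.
#' @param B number of replicates.
#' @param seed RNG seed (generates the shared weight matrix).
#' @param refit re-estimate branch lengths per replicate (default TRUE;
#'   DNA only, since the refit fits JC69 distances — pass FALSE for
#'   amino-acid alignments, whose replicate distances use Scoredist).
#' @param param a \code{PlacementParam}.
#' @param weights optional precomputed bootstrap \code{ReplicateWeights}.
#' @param queryId identifier.
#' @return a \code{SupportedPlacement} with method tag "slow_bs"
#' @export
slowBootstrap <- function(query, backbone, tree, B = 100, seed,
                          refit = TRUE, param = placementParam(),
                          weights = NULL, queryId = NULL) {
  if (is.null(queryId))
    queryId <- if (!is.null(names(query)) && length(query) == 1L)
      names(query) else "query"
  if (length(query) == 1L) query <- strsplit(toupper(query), "")[[1L]]
  L <- nSites(backbone)
  if (length(query) != L) stop("query length does not match alignment")
  if (is.null(weights)) weights <- makeBootstrapWeights(L, B, seed)
  aa <- backbone@alphabet == "AA"
  if (aa && refit)
    stop("branch-length re-estimation uses JC69 (DNA) distances; ",
         "call with refit = FALSE for amino-acid alignments")
  W <- weights@weights
  labs <- leafNames(tree)
  geom0 <- edgeGeometry(tree)
  edges <- rep(NA_integer_, nrow(W))
  row0Fit <- NULL
  sat <- 0L
  for (i in seq_len(nrow(W))) {
    cols <- rep(seq_len(L), W[i, ])
    repAln <- seqAlignment(as.matrix(backbone)[, cols, drop = FALSE],
                           backbone@alphabet)
    repQuery <- query[cols]
    treeI <- tree
    geomI <- geom0
    if (refit && i > 1L) {
      treeI <- refitBranchLengths(tree, repAln, param@weightExponent)
      geomI <- edgeGeometry(treeI)
    }
    if (aa) {
      ## amino acids: Scoredist per reference on the materialized replicate
      refs <- as.matrix(repAln)
      delta <- vapply(geomI$leafNames, function(r)
        tryCatch(scoredist(repQuery, refs[r, ]),
                 error = function(e) NA_real_), numeric(1))
      vmask <- !is.na(delta)
      sat <- sat + sum(!vmask)
      if (sum(vmask) < 2L) next
      w <- placementWeights(delta, vmask, param)
      fit <- fitAllEdges(geomI, ifelse(vmask, delta, NA_real_), w,
                         param@nonnegConstraints)
      edges[i] <- which.min(fit$lse) - 1L
      if (i == 1L)
        row0Fit <- data.frame(edgeNum = seq_along(fit$lse) - 1L,
                              distal = fit$distal, pendant = fit$pendant,
                              lse = fit$lse)
      next
    }
    prof <- buildProfile(repQuery, repAln[labs], queryId = queryId)
    P <- colSums(prof@V)
    Lp <- colSums(prof@G)
    dr <- distancesFromCounts(rbind(P), rbind(Lp), queryId = queryId)
    sat <- sat + sum(!dr@valid)
    delta <- dr@corrected[1L, geomI$leafNames]
    vmask <- dr@valid[1L, geomI$leafNames] & !is.na(delta)
    if (sum(vmask) < 2L) next
    w <- placementWeights(delta, vmask, param)
    fit <- fitAllEdges(geomI, ifelse(vmask, delta, NA_real_), w,
                       param@nonnegConstraints)
    edges[i] <- which.min(fit$lse) - 1L
    if (i == 1L)
      row0Fit <- data.frame(edgeNum = seq_along(fit$lse) - 1L,
                            distal = fit$distal, pendant = fit$pendant,
                            lse = fit$lse)
  }
  finalizeSupport(queryId, edges, row0Fit, weights@B, "slow_bs", sat)
}

## Shared assembly of a SupportedPlacement from replicate edge choices.
finalizeSupport <- function(queryId, edges, row0Fit, B, method, saturated) {
  if (is.na(edges[1L]))
    stop("original alignment yields no valid placement for '", queryId, "'")
  repEdges <- edges[-1L]
  support <- aggregateSupport(repEdges)
  orig <- row0Fit[row0Fit$edgeNum == edges[1L], ]
  placement <- new("Placement", queryId = queryId,
                   edgeNum = as.integer(edges[1L]),
                   distal = orig$distal, pendant = orig$pendant,
                   lse = orig$lse)
  fits <- row0Fit[row0Fit$edgeNum %in% as.integer(names(support)), ]
  new("SupportedPlacement", queryId = queryId, original = placement,
      support = support, edgeFits = fits, B = as.integer(B),
      method = method,
      diagnostics = list(droppedReplicates = sum(is.na(repEdges)),
                         saturatedEntries = as.integer(saturated)))
}

#' Compute placement support for one query
#'
#' Places the query on the original alignment (replicate row 0) and on each
#' of B replicate distance sets generated by the chosen method, then reports
#' the fraction of valid replicates choosing each edge as that edge's
#' support. Replicates with no valid placement are excluded from the
#' denominator and counted in the diagnostics.
#'
#' Methods: \code{fast_bs} (linear-algebraic bootstrap), \code{slow_bs}
#' (materialized bootstrap with branch-length re-estimation),
#' \code{subsample} (m-out-of-n with variance correction), \code{binomial} /
#' \code{poisson} (parametric per-distance sampling, seeded per query so
#' results are independent of query processing order).
#'
#' @param query aligned query sequence (named string or character vector).
#' @param backbone backbone \code{SeqAlignment}.
#' @param tree backbone \code{BackboneTree}.
#' @param method support method (see above).
#' @param B number of replicates (default 100).
#' @param seed run seed (mandatory).
#' @param b subsample size (subsample method; default \code{round(L^0.9)}).
#' @param param a \code{PlacementParam}.
#' @param weights optional shared \code{ReplicateWeights} (one matrix per
#'   run, reused across queries).
#' @param geom optional precomputed \code{edgeGeometry(tree)}.
#' @param refit for slow_bs: re-estimate branch lengths (default TRUE).
#' @param queryId identifier.
#' @return a \code{SupportedPlacement}
#' @export
computeSupport <- function(query, backbone, tree,
                           method = c("fast_bs", "slow_bs", "subsample",
                                      "binomial", "poisson"),
                           B = 100, seed, b = NULL,
                           param = placementParam(), weights = NULL,
                           geom = NULL, refit = TRUE, queryId = NULL) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required")
  if (is.null(queryId))
    queryId <- if (!is.null(names(query)) && length(query) == 1L)
      names(query) else "query"
  if (method == "slow_bs")
    return(slowBootstrap(query, backbone, tree, B = B, seed = seed,
                         refit = refit, param = param, weights = weights,
                         queryId = queryId))
  if (backbone@alphabet == "AA")
    stop("the fast and parametric methods use the JC69 correction and are ",
         "DNA-only; use method = 'slow_bs' (Scoredist) for amino acids")
  if (is.null(geom)) geom <- edgeGeometry(tree)
  backbone <- backbone[leafNames(tree)]
  prof <- buildProfile(query, backbone, queryId = queryId)
  L <- nSites(backbone)
  dreps <- switch(
    method,
    fast_bs = {
      if (is.null(weights)) weights <- makeBootstrapWeights(L, B, seed)
      fastBootstrapDistances(weights, prof)
    },
    subsample = {
      if (is.null(weights)) weights <- makeSubsampleWeights(L, B, seed, b = b)
      subsampleDistances(weights, prof)
    },
    {
      P0 <- colSums(prof@V); L0 <- colSums(prof@G)
      usable <- L0 > 0 & (P0 / pmax(L0, 1)) < 0.75
      if (sum(usable) < 2L)
        stop("fewer than 2 unsaturated references for '", queryId, "'")
      dr <- parametricDistances(
        hHat = (P0 / L0)[usable], l = L0[usable], B = B, mode = method,
        seed = querySeed(seed, queryId), queryId = queryId)
      ## re-inflate to full reference set with the unusable ones invalid
      expand <- function(m, fill = NA_real_) {
        out <- matrix(fill, nrow(m), length(P0),
                      dimnames = list(NULL, names(P0)))
        out[, usable] <- m
        out
      }
      validFull <- expand(dr@valid * 1, 0) == 1
      new("DistanceReplicates", queryId = queryId,
          hamming = expand(dr@hamming), corrected = expand(dr@corrected),
          validSites = expand(dr@validSites, 0), valid = validFull,
          B = as.integer(B))
    })
  res <- placeReplicates(dreps, tree, param, geom)
  finalizeSupport(queryId, res$edges, res$row0Fit, B, method,
                  saturated = sum(!dreps@valid))
}
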