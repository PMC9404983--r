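#' @include AllClasses.R
NULL

#' Placement solver parameters
#'
#' @param weightExponent least-squares weight exponent k in
#'   \code{w = delta^(-k)}; one of 0, 1, 2. The default 2 is the
#'   Fitch–Margoliash weighting, which down-weights long, high-variance
#'   distances.
#' @param nonnegConstraints constrain the pendant length to be >= 0 and the
#'   attachment point to lie on the edge (default TRUE).
#' @return a \code{PlacementParam}
#' @export
placementParam <- function(weightExponent = 2, nonnegConstraints = TRUE) {
  obj <- new("PlacementParam", weightExponent = weightExponent,
             nonnegConstraints = nonnegConstraints)
  validObject(obj)
  obj
}

## floor applied to distances before raising to a negative power, so that a
## zero observed distance (identical sequences) does not produce an infinite
## weight
.WEIGHT_DELTA_FLOOR <- 1e-6

placementWeights <- function(delta, valid, param) {
  w <- numeric(length(delta))
  if (param@weightExponent == 0) w[valid] <- 1
  else w[valid] <- pmax(delta[valid], .WEIGHT_DELTA_FLOOR) ^
      (-param@weightExponent)
  w
}

#' Precompute per-edge placement geometry
#'
#' For each edge e = (u, v) (u proximal/parent side, v distal/child side) and
#' each backbone leaf i, placing a query at distance x from u along e with
#' pendant length p gives a path distance \code{p + x + D(u, i)} when i is on
#' the proximal side and \code{p + (len_e - x) + D(v, i)} when i is on the
#' distal side. This function assembles the E x n matrices of constants and
#' side signs so that the per-edge weighted least-squares fit is a handful of
#' vectorized operations per replicate.
#'
#' @param tree a \code{BackboneTree}
#' @return list with \code{K} (E x n path-constant matrix), \code{S} (E x n
#'   side signs, +1 proximal / -1 distal), \code{len} (edge lengths),
#'   \code{leafNames} (column order).
#' @export
edgeGeometry <- function(tree) {
  ph <- treePhylo(tree)
  ntip <- length(ph$tip.label)
  D <- ape::dist.nodes(ph)
  sets <- cladeTips(ph)
  E <- nrow(ph$edge)
  K <- matrix(0, E, ntip)
  S <- matrix(1, E, ntip)
  len <- ph$edge.length
  for (r in seq_len(E)) {
    u <- ph$edge[r, 1L]; v <- ph$edge[r, 2L]
    distal <- sets[[v]]
    S[r, distal] <- -1
    K[r, ] <- D[u, seq_len(ntip)]
    K[r, distal] <- len[r] + D[v, distal]
  }
  colnames(K) <- colnames(S) <- ph$tip.label
  list(K = K, S = S, len = len, leafNames = ph$tip.label)
}

## Vectorized constrained WLS fit of (pendant p, distal x) for ALL edges at
## once. delta and w are length-n vectors in geometry column order (w = 0
## marks unusable references). Returns list of vectors distal, pendant, lse
## (length E). The 2x2 normal equations are solved in closed form; the
## solution is then projected onto {p >= 0, 0 <= x <= len} by clamping each
## active constraint and re-minimizing the free coordinate, keeping the
## feasible candidate with the smallest objective.
fitAllEdges <- function(geom, delta, w, nonneg = TRUE) {
  use <- w > 0 & is.finite(delta)
  if (sum(use) < 2L) stop("fewer than 2 usable distances")
  wu <- ifelse(use, w, 0)
  d0 <- ifelse(use, delta, 0)
  a <- sum(wu)                             # sum w  (same for p and x terms)
  R <- -sweep(geom$K, 2L, d0, "-")         # delta_i - k_i, edges x n
  R[, !use] <- 0
  b1 <- as.vector(R %*% wu)                # sum w r
  b2 <- as.vector((geom$S * R) %*% wu)     # sum w s r
  bS <- as.vector(geom$S %*% wu)           # sum w s
  rss0 <- as.vector((R * R) %*% wu)        # sum w r^2
  len <- geom$len
  obj <- function(p, x) rss0 - 2 * p * b1 - 2 * x * b2 +
    a * p^2 + a * x^2 + 2 * bS * p * x
  det <- a * a - bS * bS
  safeDet <- ifelse(abs(det) > 1e-12 * a * a, det, NA_real_)
  pU <- (a * b1 - bS * b2) / safeDet
  xU <- (a * b2 - bS * b1) / safeDet
  if (!nonneg) {
    ## only the on-edge constraint for x is kept; pendant may go negative
    x1 <- pmin(pmax(ifelse(is.na(xU), 0, xU), 0), len)
    p1 <- (b1 - bS * x1) / a
    return(list(distal = x1, pendant = p1, lse = pmax(obj(p1, x1), 0)))
  }
  ## candidate 1: interior solution (when feasible)
  feas <- !is.na(pU) & pU >= 0 & xU >= 0 & xU <= len
  o1 <- ifelse(feas, obj(ifelse(feas, pU, 0), ifelse(feas, xU, 0)), Inf)
  ## candidate 2: p = 0, x free then clamped
  x2 <- pmin(pmax(b2 / a, 0), len)
  o2 <- obj(0, x2)
  ## candidate 3: x = 0, p free then clamped
  p3 <- pmax(b1 / a, 0)
  o3 <- obj(p3, 0)
  ## candidate 4: x = len, p free then clamped
  p4 <- pmax((b1 - bS * len) / a, 0)
  o4 <- obj(p4, len)
  objs <- cbind(o1, o2, o3, o4)
  pick <- max.col(-objs, ties.method = "first")
  distal <- cbind(ifelse(feas, xU, 0), x2, 0, len)[cbind(seq_along(pick), pick)]
  pendant <- cbind(ifelse(feas, pU, 0), 0, p3, p4)[cbind(seq_along(pick), pick)]
  lse <- pmax(objs[cbind(seq_along(pick), pick)], 0)
  list(distal = distal, pendant = pendant, lse = lse)
}

#' Constrained least-squares fit of a query onto one edge
#'
#' Solves the 2-variable weighted least-squares problem for the attachment
#' point (distal position x along the edge) and pendant length p on a single
#' edge, by the closed-form normal equations followed by projection onto the
#' constraints \code{p >= 0, 0 <= x <= len}.
#'
#' @param edgeNum edge number (0-based).
#' @param delta named numeric vector of corrected distances to backbone
#'   leaves (NA = unusable).
#' @param tree a \code{BackboneTree}.
#' @param param a \code{PlacementParam}.
#' @param weights optional explicit weights (overrides param-derived ones).
#' @return list(distal, pendant, lse)
#' @export
edgeFit <- function(edgeNum, delta, tree, param = placementParam(),
                    weights = NULL) {
  geom <- edgeGeometry(tree)
  delta <- delta[geom$leafNames]
  valid <- !is.na(delta)
  w <- if (is.null(weights)) placementWeights(delta, valid, param)
  else ifelse(valid, weights[geom$leafNames], 0)
  fit <- fitAllEdges(geom, delta, w, param@nonnegConstraints)
  i <- edgeNum + 1L
  if (i < 1L || i > length(fit$lse)) stop("edge ", edgeNum, " not in tree")
  list(distal = fit$distal[i], pendant = fit$pendant[i], lse = fit$lse[i])
}

#' Place a query by exhaustive least-squares fitting over all edges
#'
#' Finds the edge, attachment point, and pendant length minimizing the
#' weighted least-squares error between the observed corrected distances and
#' the resulting tree path distances. Every edge is fitted (O(n) each); ties
#' in the objective are broken deterministically by the smallest edge number.
#' References with invalid (saturated or missing) distances receive weight 0;
#' the query is rejected only when fewer than two usable distances remain.
#'
#' @param delta named numeric vector of corrected distances (names = leaf
#'   labels; NA = unusable).
#' @param tree a \code{BackboneTree}.
#' @param param a \code{PlacementParam}.
#' @param queryId identifier recorded in the result.
#' @param geom optional precomputed \code{edgeGeometry(tree)}.
#' @return a \code{Placement}
#' @export
placeQuery <- function(delta, tree, param = placementParam(),
                       queryId = "query", geom = NULL) {
  if (is.null(geom)) geom <- edgeGeometry(tree)
  delta <- delta[geom$leafNames]
  valid <- !is.na(delta) & is.finite(delta)
  if (sum(valid) < 2L) stop("no valid distances for query '", queryId, "'")
  w <- placementWeights(delta, valid, param)
  fit <- fitAllEdges(geom, ifelse(valid, delta, NA_real_), w,
                     param@nonnegConstraints)
  best <- which.min(fit$lse)   # first minimum = smallest edge_num
  new("Placement", queryId = queryId, edgeNum = as.integer(best - 1L),
      distal = fit$distal[best], pendant = fit$pendant[best],
      lse = fit$lse[best])
}

## Place every row of a DistanceReplicates object. Returns list(edges:
## integer vector length B+1 (NA = replicate unusable), row0Fit: full
## per-edge fit of the original distances).
placeReplicates <- function(dreps, tree, param = placementParam(),
                            geom = NULL) {
  if (is.null(geom)) geom <- edgeGeometry(tree)
  n <- ncol(dreps@corrected)
  cols <- match(geom$leafNames, colnames(dreps@corrected))
  if (anyNA(cols)) stop("distance columns do not cover the backbone leaves")
  edges <- rep(NA_integer_, nrow(dreps@corrected))
  row0Fit <- NULL
  for (i in seq_len(nrow(dreps@corrected))) {
    delta <- dreps@corrected[i, cols]
    valid <- dreps@valid[i, cols] & !is.na(delta)
    if (sum(valid) < 2L) next
    w <- placementWeights(delta, valid, param)
    fit <- fitAllEdges(geom, ifelse(valid, delta, NA_real_), w,
                       param@nonnegConstraints)
    edges[i] <- which.min(fit$lse) - 1L
    if (i == 1L)
      row0Fit <- data.frame(edgeNum = seq_along(fit$lse) - 1L,
                            distal = fit$distal, pendant = fit$pendant,
                            lse = fit$lse)
  }
  list(edges = edges, row0Fit = row0Fit)
}

#' Re-estimate branch lengths on a fixed topology
#'
#' Fits all pairwise JC69 distances among the backbone sequences to the tree
#' path lengths by non-negative weighted least squares (weights
#' \code{delta^(-2)}), keeping the topology and edge numbering unchanged.
#' This is the branch-length re-estimation step of slow bootstrapping: each
#' resampled alignment implies slightly different distances, and refitting
#' lets the backbone adapt to the replicate. Saturated or gap-only pairs are
#' excluded from the fit; if their fraction exceeds \code{maxInvalidFrac} the
#' refit aborts.
#'
#' @param tree a \code{BackboneTree}.
#' @param alignment a \code{SeqAlignment} covering all backbone leaves
#'   (possibly column-resampled).
#' @param weightExponent weight exponent for the WLS fit (default 2).
#' @param maxInvalidFrac maximum tolerated fraction of unusable pairs.
#' @return a \code{BackboneTree} with updated branch lengths.
#' @export
refitBranchLengths <- function(tree, alignment, weightExponent = 2,
                               maxInvalidFrac = 0.5) {
  stopifnot(is(tree, "BackboneTree"), is(alignment, "SeqAlignment"))
  ph <- treePhylo(tree)
  labs <- ph$tip.label
  if (!all(labs %in% seqIds(alignment)))
    stop("alignment does not cover all backbone leaves")
  pw <- pairwiseJC(alignment[labs])
  n <- length(labs)
  pairs <- which(upper.tri(pw$corrected), arr.ind = TRUE)
  ok <- pw$valid[pairs]
  if (mean(!ok) > maxInvalidFrac)
    stop("fraction of saturated/empty pairs (", fmtNum(mean(!ok)),
         ") exceeds maxInvalidFrac")
  pairs <- pairs[ok, , drop = FALSE]
  delta <- pw$corrected[pairs]
  ## leaf x edge incidence: edge j is on the root path of every tip in its
  ## child clade; a pair's path indicator is the XOR of the two root paths
  sets <- cladeTips(ph)
  E <- nrow(ph$edge)
  Z <- matrix(0, n, E)
  for (r in seq_len(E)) Z[sets[[ph$edge[r, 2L]]], r] <- 1
  A <- abs(Z[pairs[, 1L], , drop = FALSE] - Z[pairs[, 2L], , drop = FALSE])
  w <- if (weightExponent == 0) rep(1, length(delta))
  else pmax(delta, .WEIGHT_DELTA_FLOOR) ^ (-weightExponent)
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(A * sw, delta * sw)
  ph$edge.length <- as.numeric(fit$x)
  backboneTree(ph)
}
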