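#' @include AllClasses.R
NULL

## Sites count as observed only when the character is in the core alphabet
## (A/C/G/T for DNA, the 20 standard residues for AA). Gaps and ambiguity
## codes are both treated as missing: distances are Hamming fractions over
## mutually observed sites, with gaps ignored.
isObserved <- function(chars, alphabet) chars %in% coreAlphabet(alphabet)

#' Build the per-query mismatch profile
#'
#' Performs the string comparison between a query and every backbone sequence
#' exactly once per site, recording the results in two L x n binary matrices:
#' \code{V[i, j] = 1} when site i is observed in both query and reference j
#' and the characters differ; \code{G[i, j] = 1} when site i is observed in
#' both. Every bootstrap/subsample replicate distance is subsequently a
#' weighted column sum of V and G — no further string operations are needed.
#'
#' @param query aligned query sequence: a single string or character vector
#'   of length \code{nSites(backbone)}; may be named (the name becomes the
#'   query id).
#' @param backbone a \code{SeqAlignment} of the backbone sequences.
#' @param queryId identifier used when \code{query} is unnamed.
#' @return a \code{MismatchProfile}
#' @export
buildProfile <- function(query, backbone, queryId = NULL) {
  stopifnot(is(backbone, "SeqAlignment"))
  if (is.null(queryId))
    queryId <- if (!is.null(names(query)) && length(query) == 1L)
      names(query) else "query"
  if (length(query) == 1L) query <- strsplit(toupper(query), "")[[1L]]
  else query <- toupper(query)
  L <- nSites(backbone)
  if (length(query) != L)
    stop("query length ", length(query), " does not match alignment width ",
         L)
  M <- as.matrix(backbone)                      # n x L
  qObs <- isObserved(query, backbone@alphabet)  # length L
  refObs <- isObserved(M, backbone@alphabet)    # n x L logical (matrix)
  dim(refObs) <- dim(M)
  G <- t(refObs & rep(qObs, each = nrow(M)))    # L x n
  mism <- t(M != rep(query, each = nrow(M)))
  V <- (G & mism)
  storage.mode(G) <- "integer"
  storage.mode(V) <- "integer"
  colnames(V) <- colnames(G) <- seqIds(backbone)
  new("MismatchProfile", queryId = queryId, V = V, G = G)
}

#' JC69 distance correction
#'
#' Transforms a normalized Hamming distance h into an estimated number of
#' substitutions per site, \code{-3/4 * log(1 - 4h/3)}. The transform is only
#' defined for \code{h < 3/4}; saturated values (h >= 3/4) yield \code{NA},
#' the saturation sentinel, and are excluded from the placement objective by
#' callers rather than capped.
#'
#' @param h numeric vector of normalized Hamming distances, \code{h >= 0}.
#' @return corrected distances; \code{NA} where saturated.
#' @examples
#' jc69Correct(0.3)   # ~0.38312
#' @export
jc69Correct <- function(h) {
  if (any(h < 0, na.rm = TRUE)) stop("negative Hamming distance")
  out <- rep(NA_real_, length(h))
  ok <- !is.na(h) & h < 0.75
  out[ok] <- -0.75 * log1p(-4 * h[ok] / 3)
  out
}

#' Expected Hamming distance under JC69
#'
#' The exact inverse of \code{\link{jc69Correct}} on [0, 3/4): under JC69 the
#' per-site probability of an observed difference at evolutionary distance t
#' is \code{h = 3/4 * (1 - exp(-4t/3))}.
#'
#' @param t numeric vector of distances in substitutions/site, \code{t >= 0}.
#' @return expected normalized Hamming distances in [0, 3/4).
#' @export
jc69ExpectedH <- function(t) {
  if (any(t < 0, na.rm = TRUE)) stop("negative distance")
  0.75 * -expm1(-4 * t / 3)
}

## Robinson & Robinson (1991) amino-acid background frequencies, the
## composition used by the Scoredist reference for the expected random score.
.AA_FREQ <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364,
              C = 0.01925, Q = 0.04264, E = 0.06295, G = 0.07377,
              H = 0.02199, I = 0.05142, L = 0.09019, K = 0.05744,
              M = 0.02243, F = 0.03856, P = 0.05203, S = 0.07120,
              T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

blosum62Matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Scoredist amino-acid distance
#'
#' Computes the evolutionary distance between two aligned amino-acid
#' sequences by the Scoredist procedure: the BLOSUM62 similarity score over
#' mutually observed sites is normalized between the expected score of two
#' random sequences (Robinson–Robinson composition) and the upper-limit score
#' (mean of the two self-scores), then log-corrected and scaled,
#' \code{d = -ln(sigma_n / sigma_un) * 100 * coef}. The default empirical
#' calibration coefficient is 1.3 (the FastTree-2 convention, which keeps the
#' distances on the same scale as FastTree-2 backbone branch lengths); the
#' original publication's 1.13 is selectable.
#'
#' @param a,b aligned AA sequences (single strings or character vectors of
#'   equal length).
#' @param coef empirical scaling coefficient: 1.3 (default) or 1.13.
#' @param maxDistance distance reported when the normalized score is <= 0
#'   (log-domain boundary); also the cap on the reported distance.
#' @return a single non-negative distance (percentage-scaled substitutions).
#' @export
scoredist <- function(a, b, coef = 1.3, maxDistance = 1000) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a %in% .AA_CORE & b %in% .AA_CORE
  l <- sum(keep)
  if (l == 0L) stop("no overlapping ungapped sites")
  S <- blosum62Matrix()
  a <- a[keep]; b <- b[keep]
  sigma <- sum(S[cbind(a, b)])
  expPerSite <- as.numeric(.AA_FREQ %*% S[names(.AA_FREQ), names(.AA_FREQ)] %*%
                             .AA_FREQ)
  sigmaR <- l * expPerSite
  upper <- (sum(S[cbind(a, a)]) + sum(S[cbind(b, b)])) / 2
  sigmaN <- sigma - sigmaR
  sigmaUN <- upper - sigmaR
  if (sigmaN <= 0) return(maxDistance)
  d <- -log(sigmaN / sigmaUN) * 100 * coef
  min(max(d, 0), maxDistance)
}

#' Replicate distances from mismatch and valid-site counts
#'
#' Converts replicate-weighted mismatch counts P and valid-site counts L'
#' into normalized Hamming distances \code{h = P / L'} and JC69-corrected
#' distances. Entries with \code{L' = 0} (no mutually observed site sampled)
#' or \code{h >= 3/4} (saturation) are flagged invalid; they are excluded
#' from the placement objective rather than capped.
#'
#' @param P (B+1) x n matrix of mismatch counts; row 1 is the original
#'   alignment.
#' @param Lprime (B+1) x n matrix of mutually observed site counts.
#' @param queryId query identifier carried through.
#' @return a \code{DistanceReplicates}
#' @export
distancesFromCounts <- function(P, Lprime, queryId = "query") {
  P <- as.matrix(P); Lprime <- as.matrix(Lprime)
  if (!identical(dim(P), dim(Lprime)))
    stop("P and L' dimensions differ")
  if (any(P < 0)) stop("negative mismatch counts")
  if (any(P > Lprime)) stop("mismatch counts exceed valid-site counts")
  h <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  pos <- Lprime > 0
  h[pos] <- P[pos] / Lprime[pos]
  valid <- pos & !is.na(h) & h < 0.75
  corrected <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  corrected[valid] <- jc69Correct(h[valid])
  new("DistanceReplicates", queryId = queryId, hamming = h,
      corrected = corrected, validSites = Lprime, valid = valid,
      B = nrow(P) - 1L)
}

## All pairwise JC69 distances among the rows of an alignment, by one-hot
## matrix products: O(n^2 L) in a handful of dense multiplications.
## Returns list(hamming, corrected, validSites, valid) of n x n matrices.
pairwiseJC <- function(alignment) {
  M <- as.matrix(alignment)
  core <- coreAlphabet(alignment@alphabet)
  n <- nrow(M)
  obs <- matrix(0, n, ncol(M))
  match <- matrix(0, n, n)
  for (ch in core) {
    X <- (M == ch) * 1
    obs <- obs + X
    match <- match + tcrossprod(X)
  }
  validSites <- tcrossprod(obs)        # both-observed site counts
  mism <- validSites - match
  h <- matrix(NA_real_, n, n, dimnames = list(rownames(M), rownames(M)))
  pos <- validSites > 0
  h[pos] <- mism[pos] / validSites[pos]
  valid <- pos & !is.na(h) & h < 0.75
  corrected <- matrix(NA_real_, n, n, dimnames = dimnames(h))
  corrected[valid] <- jc69Correct(h[valid])
  diag(valid) <- FALSE
  list(hamming = h, corrected = corrected, validSites = validSites,
       valid = valid)
}
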