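## S4 classes for the placement pipeline. Validity methods enforce the
## structural invariants that downstream numerics rely on.

.DNA_CORE <- c("A", "C", "G", "T")
.AA_CORE <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.DNA_EXTRA <- c("-", ".", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H",
                "V", "U", "?")
.AA_EXTRA <- c("-", ".", "X", "B", "Z", "J", "U", "O", "*", "?")

coreAlphabet <- function(alphabet) {
  switch(alphabet, DNA = .DNA_CORE, AA = .AA_CORE,
         stop("alphabet must be 'DNA' or 'AA'"))
}

allowedCharacters <- function(alphabet) {
  switch(alphabet,
         DNA = c(.DNA_CORE, .DNA_EXTRA),
         AA = c(.AA_CORE, .AA_EXTRA),
         stop("alphabet must be 'DNA' or 'AA'"))
}

#' Aligned sequence set
#'
#' Fixed-width character matrix over a declared alphabet (DNA or amino acid),
#' with unique row identifiers. This is the substrate for all site resampling:
#' bootstrap and subsample replicates are defined as reweightings of its
#' columns. Ambiguity codes are retained on input but are treated as gaps by
#' all distance computations (only the core alphabet counts as an observed
#' character).
#'
#' @slot seqs character matrix, one row per sequence (rownames are the
#'   sequence identifiers), one column per alignment site; uppercase.
#' @slot alphabet either \code{"DNA"} or \code{"AA"}.
#' @export
setClass("SeqAlignment",
         representation(seqs = "matrix", alphabet = "character"))

setValidity("SeqAlignment", function(object) {
  msg <- character()
  if (!is.character(object@seqs)) msg <- c(msg, "seqs must be character")
  ids <- rownames(object@seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "sequence ids must be unique, non-empty rownames")
  if (!object@alphabet %in% c("DNA", "AA"))
    msg <- c(msg, "alphabet must be 'DNA' or 'AA'")
  else {
    bad <- setdiff(unique(as.vector(object@seqs)),
                   allowedCharacters(object@alphabet))
    if (length(bad))
      msg <- c(msg, paste0("illegal characters for ", object@alphabet,
                           " alphabet: ", paste(bad, collapse = " ")))
  }
  if (length(msg)) msg else TRUE
})

#' Backbone tree with stable edge numbering
#'
#' An unrooted leaf-labeled tree with non-negative branch lengths in
#' substitutions per site. Edges carry a stable integer numbering
#' \code{0..(E-1)} assigned by a depth-first post-order traversal of the tree
#' as read; the numbering is recomputed identically when the same Newick
#' string is re-read, which is what jplace consumers require.
#'
#' @slot phylo an \code{ape::phylo} object stored in post-order edge order;
#'   edge \code{i} of the matrix has \code{edge_num = i - 1}.
#' @export
setClass("BackboneTree", representation(phylo = "ANY"))

setValidity("BackboneTree", function(object) {
  ph <- object@phylo
  msg <- character()
  if (!inherits(ph, "phylo")) return("phylo slot must be an ape 'phylo'")
  if (is.null(ph$edge.length) || length(ph$edge.length) != nrow(ph$edge))
    msg <- c(msg, "every edge must have a branch length")
  else {
    if (any(!is.finite(ph$edge.length)))
      msg <- c(msg, "branch lengths must be finite")
    if (any(ph$edge.length < 0, na.rm = TRUE))
      msg <- c(msg, "negative branch length")
  }
  if (is.null(ph$tip.label) || any(!nzchar(ph$tip.label)))
    msg <- c(msg, "unlabeled leaf")
  if (anyDuplicated(ph$tip.label)) msg <- c(msg, "duplicate leaf labels")
  if (length(msg)) msg else TRUE
})

#' Per-query mismatch profile
#'
#' The reusable core of the linear-algebraic replicate formulation. For a
#' query \code{q} against an \code{n}-sequence backbone of length \code{L},
#' \code{V} is the L x n binary matrix with \code{V[i, j] = 1} when site
#' \code{i} is ungapped in both \code{q} and reference \code{j} and the two
#' characters differ; \code{G[i, j] = 1} when site \code{i} is ungapped in
#' both. String comparison is performed exactly once per (site, reference);
#' every replicate distance is then a weighted column sum of these matrices.
#'
#' @slot queryId single query identifier.
#' @slot V integer L x n mismatch indicator matrix.
#' @slot G integer L x n both-ungapped indicator matrix.
#' @export
setClass("MismatchProfile",
         representation(queryId = "character", V = "matrix", G = "matrix"))

setValidity("MismatchProfile", function(object) {
  if (!identical(dim(object@V), dim(object@G)))
    return("V and G must have identical dimensions")
  if (any(object@V > object@G)) return("V must be <= G elementwise")
  if (any(object@V < 0) || any(object@G < 0) || any(object@G > 1))
    return("V and G must be binary")
  TRUE
})

#' Replicate site weights
#'
#' The (B+1) x L integer matrix driving site resampling. Row 1 (replicate 0)
#' is all ones and represents the original alignment; rows 2..(B+1) are either
#' multinomial bootstrap counts (each row sums to L) or binary subsample
#' indicators (each row sums to b). One weight matrix is computed per run and
#' shared by all queries.
#'
#' @slot kind \code{"bootstrap"} or \code{"subsample"}.
#' @slot weights integer (B+1) x L matrix.
#' @slot B number of replicates.
#' @slot b subsample size (\code{NA} for bootstrap).
#' @slot seed RNG seed used to generate the matrix.
#' @export
setClass("ReplicateWeights",
         representation(kind = "character", weights = "matrix",
                        B = "integer", b = "integer", seed = "integer"))

setValidity("ReplicateWeights", function(object) {
  W <- object@weights
  msg <- character()
  if (!object@kind %in% c("bootstrap", "subsample"))
    msg <- c(msg, "kind must be 'bootstrap' or 'subsample'")
  if (nrow(W) != object@B + 1L) msg <- c(msg, "weights must have B+1 rows")
  if (any(W < 0)) msg <- c(msg, "weights must be non-negative")
  if (!all(W[1L, ] == 1L)) msg <- c(msg, "row 0 must be all ones")
  L <- ncol(W)
  if (object@kind == "bootstrap" && object@B >= 1L &&
      !all(rowSums(W[-1L, , drop = FALSE]) == L))
    msg <- c(msg, "bootstrap rows must each sum to L")
  if (object@kind == "subsample") {
    if (!all(W %in% c(0L, 1L))) msg <- c(msg, "subsample entries must be 0/1")
    if (object@B >= 1L && !all(rowSums(W[-1L, , drop = FALSE]) == object@b))
      msg <- c(msg, "subsample rows must each sum to b")
  }
  if (length(msg)) msg else TRUE
})

#' Replicate distances for one query
#'
#' Normalized Hamming and phylogenetically corrected distances from one query
#' to each backbone reference, for the original alignment (row 1) and B
#' replicate alignments (rows 2..(B+1)). Entries where no mutually ungapped
#' site survives resampling, or where the Hamming distance reaches the JC69
#' saturation point 3/4, are flagged invalid and excluded from placement.
#'
#' @slot queryId query identifier.
#' @slot hamming (B+1) x n normalized Hamming distances.
#' @slot corrected (B+1) x n corrected distances (substitutions/site).
#' @slot validSites (B+1) x n counts of mutually ungapped sites.
#' @slot valid logical (B+1) x n; FALSE marks saturated/empty entries.
#' @slot B replicate count.
#' @export
setClass("DistanceReplicates",
         representation(queryId = "character", hamming = "matrix",
                        corrected = "matrix", validSites = "matrix",
                        valid = "matrix", B = "integer"))

setValidity("DistanceReplicates", function(object) {
  msg <- character()
  if (nrow(object@hamming) != object@B + 1L)
    msg <- c(msg, "hamming must have B+1 rows")
  for (s in c("corrected", "validSites", "valid"))
    if (!identical(dim(slot(object, s)), dim(object@hamming)))
      msg <- c(msg, paste0(s, " must match hamming dimensions"))
  ok <- object@valid
  if (any(object@corrected[ok] < 0, na.rm = TRUE))
    msg <- c(msg, "corrected distances must be >= 0 where valid")
  if (any(object@hamming[ok] >= 0.75, na.rm = TRUE))
    msg <- c(msg, "valid Hamming distances must be < 3/4")
  if (length(msg)) msg else TRUE
})

#' Placement solver parameters
#'
#' @slot weightExponent exponent k of the least-squares weights
#'   \code{w = delta^(-k)}; 2 (Fitch–Margoliash, the default), 1 (Beyer), or
#'   0 (ordinary least squares).
#' @slot nonnegConstraints when TRUE (default) the pendant length is
#'   constrained to be non-negative and the attachment point is constrained to
#'   lie on the edge.
#' @export
setClass("PlacementParam",
         representation(weightExponent = "numeric",
                        nonnegConstraints = "logical"))

setValidity("PlacementParam", function(object) {
  if (!object@weightExponent %in% c(0, 1, 2))
    return("weightExponent must be 0, 1, or 2")
  TRUE
})

#' A single least-squares placement
#'
#' The minimizer of the weighted least-squares placement objective
#' \code{sum_i w_i (delta_i - d_i)^2} over edges and attachment coordinates.
#'
#' @slot queryId query identifier.
#' @slot edgeNum edge number of the chosen edge.
#' @slot distal position of the attachment point along the edge, measured
#'   from the proximal (parent-side) endpoint, in [0, edge length].
#' @slot pendant length of the branch connecting the query to the attachment
#'   point (>= 0 under the default constraints).
#' @slot lse value of the weighted least-squares objective at the optimum.
#' @export
setClass("Placement",
         representation(queryId = "character", edgeNum = "integer",
                        distal = "numeric", pendant = "numeric",
                        lse = "numeric"))

#' Placement with replicate support
#'
#' The original-alignment placement together with per-edge support fractions:
#' the fraction of the B replicate placements that chose each edge. Fractions
#' are taken over replicates that produced a valid placement; replicates with
#' fewer than two usable distances are dropped from the denominator and
#' counted in \code{diagnostics$droppedReplicates}.
#'
#' @slot queryId query identifier.
#' @slot original the row-0 (original alignment) \code{Placement}.
#' @slot support named numeric vector, names are edge numbers, sorted by
#'   decreasing support; sums to 1 over valid replicates.
#' @slot edgeFits data.frame of the original-distance fit (edgeNum, distal,
#'   pendant, lse) for every supported edge.
#' @slot B number of replicates requested.
#' @slot method one of fast_bs, slow_bs, subsample, binomial, poisson.
#' @slot diagnostics list: droppedReplicates, saturatedEntries.
#' @export
setClass("SupportedPlacement",
         representation(queryId = "character", original = "Placement",
                        support = "numeric", edgeFits = "data.frame",
                        B = "integer", method = "character",
                        diagnostics = "list"))

setValidity("SupportedPlacement", function(object) {
  if (length(object@support) &&
      abs(sum(object@support) - 1) > 1e-9)
    return("support fractions must sum to 1")
  TRUE
})
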