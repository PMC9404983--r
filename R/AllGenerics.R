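#' @include AllClasses.R
NULL

#' Number of sequences in an alignment
#' @param x a \code{SeqAlignment}
#' @return integer
#' @export
setGeneric("nSeqs", function(x) standardGeneric("nSeqs"))

#' Number of alignment sites (columns)
#' @param x a \code{SeqAlignment}
#' @return integer
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Sequence identifiers
#' @param x a \code{SeqAlignment}
#' @return character vector
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Alphabet of an alignment
#' @param x a \code{SeqAlignment}
#' @return "DNA" or "AA"
#' @export
setGeneric("seqAlphabet", function(x) standardGeneric("seqAlphabet"))

#' Number of edges of a backbone tree
#' @param x a \code{BackboneTree}
#' @return integer
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Branch lengths by edge number
#' @param x a \code{BackboneTree}
#' @return numeric vector ordered by edge number 0..(E-1)
#' @export
setGeneric("edgeLengths", function(x) standardGeneric("edgeLengths"))

#' Leaf labels of a backbone tree
#' @param x a \code{BackboneTree}
#' @return character vector
#' @export
setGeneric("leafNames", function(x) standardGeneric("leafNames"))

#' Underlying ape phylo object
#' @param x a \code{BackboneTree}
#' @return an \code{ape::phylo}, edges in post-order (edge_num = row - 1)
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))

#' Support fractions of a supported placement
#' @param x a \code{SupportedPlacement}
#' @return named numeric vector (names are edge numbers), decreasing
#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))

#' Best (original-alignment) placement
#' @param x a \code{SupportedPlacement}
#' @return a \code{Placement}
#' @export
setGeneric("bestPlacement", function(x) standardGeneric("bestPlacement"))

setMethod("nSeqs", "SeqAlignment", function(x) nrow(x@seqs))
setMethod("nSites", "SeqAlignment", function(x) ncol(x@seqs))
setMethod("seqIds", "SeqAlignment", function(x) rownames(x@seqs))
setMethod("seqAlphabet", "SeqAlignment", function(x) x@alphabet)

#' @param x a SeqAlignment
#' @param ... unused
#' @describeIn SeqAlignment-class coerce to a character matrix
#' @export
setMethod("as.matrix", "SeqAlignment", function(x, ...) x@seqs)

setMethod("nEdges", "BackboneTree", function(x) nrow(x@phylo$edge))
setMethod("edgeLengths", "BackboneTree", function(x) x@phylo$edge.length)
setMethod("leafNames", "BackboneTree", function(x) x@phylo$tip.label)
setMethod("treePhylo", "BackboneTree", function(x) x@phylo)

setMethod("supportValues", "SupportedPlacement", function(x) x@support)
setMethod("bestPlacement", "SupportedPlacement", function(x) x@original)

setMethod("show", "SeqAlignment", function(object) {
  cat("SeqAlignment:", nSeqs(object), object@alphabet, "sequences x",
      nSites(object), "sites\n")
  ids <- head(seqIds(object), 3)
  cat("  ids:", paste(ids, collapse = ", "),
      if (nSeqs(object) > 3) "..." else "", "\n")
})

setMethod("show", "BackboneTree", function(object) {
  cat("BackboneTree:", length(leafNames(object)), "leaves,",
      nEdges(object), "edges (edge_num 0..", nEdges(object) - 1L, ")\n",
      sep = " ")
  cat("  total branch length:", fmtNum(sum(edgeLengths(object))), "\n")
})

setMethod("show", "MismatchProfile", function(object) {
  cat("MismatchProfile for query '", object@queryId, "': ",
      nrow(object@V), " sites x ", ncol(object@V), " references\n", sep = "")
})

setMethod("show", "ReplicateWeights", function(object) {
  cat("ReplicateWeights (", object@kind, "): B = ", object@B,
      ", L = ", ncol(object@weights), sep = "")
  if (object@kind == "subsample") cat(", b =", object@b)
  cat(", seed =", object@seed, "\n")
})

setMethod("show", "DistanceReplicates", function(object) {
  cat("DistanceReplicates for query '", object@queryId, "': B = ",
      object@B, ", ", ncol(object@hamming), " references, ",
      sum(!object@valid), " invalid entries\n", sep = "")
})

setMethod("show", "Placement", function(object) {
  cat("Placement of '", object@queryId, "' on edge ", object@edgeNum,
      ": distal = ", fmtNum(object@distal),
      ", pendant = ", fmtNum(object@pendant),
      ", LSE = ", fmtNum(object@lse), "\n", sep = "")
})

setMethod("show", "SupportedPlacement", function(object) {
  cat("SupportedPlacement ('", object@method, "', B = ", object@B,
      ") for query '", object@queryId, "'\n", sep = "")
  show(object@original)
  s <- head(object@support, 5)
  cat("  support:", paste(sprintf("e%s=%.3f", names(s), s), collapse = " "),
      if (length(object@support) > 5) "..." else "", "\n")
})
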