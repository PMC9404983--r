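#' @include AllClasses.R
NULL

#' Construct a SeqAlignment from a character matrix or vector of strings
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix (rows = sequences, rownames = ids).
#' @param alphabet "DNA" or "AA".
#' @return a \code{SeqAlignment}
#' @examples
#' aln <- seqAlignment(c(s1 = "ACGT", s2 = "ACGA"), "DNA")
#' nSites(aln)
#' @export
seqAlignment <- function(seqs, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named")
    widths <- nchar(seqs)
    if (length(seqs) == 0L) stop("no records")
    if (length(unique(widths)) != 1L)
      stop("ragged alignment: records have unequal lengths")
    m <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                byrow = TRUE, dimnames = list(names(seqs), NULL))
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate ids: ", paste(unique(rownames(m)[duplicated(rownames(m))]),
                                  collapse = ", "))
  obj <- new("SeqAlignment", seqs = m, alphabet = alphabet)
  validObject(obj)
  obj
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length (an aligned FASTA); ragged input is
#' an error, never silently padded. Sequences are uppercased on input. Parsing
#' is done by \code{Biostrings::readBStringSet}.
#'
#' @param path path to an aligned FASTA file.
#' @param alphabet "DNA" or "AA".
#' @return a \code{SeqAlignment}
#' @export
readAlignment <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in '", path, "'")
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L)
    stop("ragged alignment in '", path, "': record lengths ",
         paste(unique(w), collapse = ", "))
  ids <- sub("\\s.*$", "", names(set))   # FASTA id = first token of header
  seqs <- as.character(set)
  names(seqs) <- ids
  seqAlignment(seqs, alphabet)
}

#' Write a SeqAlignment to FASTA
#'
#' @param x a \code{SeqAlignment}
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
writeAlignment <- function(x, path) {
  stopifnot(is(x, "SeqAlignment"))
  strs <- apply(x@seqs, 1L, paste, collapse = "")
  out <- character(2L * length(strs))
  out[c(TRUE, FALSE)] <- paste0(">", names(strs))
  out[c(FALSE, TRUE)] <- strs
  writeLines(out, path)
  invisible(path)
}

#' Extract rows of an alignment
#'
#' @param x a SeqAlignment
#' @param i row ids or indices
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @return a \code{SeqAlignment} with the selected sequences
#' @export
setMethod("[", "SeqAlignment", function(x, i, j, ..., drop = FALSE) {
  new("SeqAlignment", seqs = x@seqs[i, , drop = FALSE],
      alphabet = x@alphabet)
})

## One row of an alignment as a bare character vector of length L.
alignmentRow <- function(x, id) {
  if (!id %in% rownames(x@seqs)) stop("unknown sequence id '", id, "'")
  x@seqs[id, ]
}
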