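#' @include AllClasses.R
NULL

#' Construct a BackboneTree from an ape phylo object
#'
#' The tree is validated (finite, non-negative branch lengths on every edge;
#' unique, non-empty leaf labels) and stored with its edges in depth-first
#' post-order. Edge numbers are the post-order row indices minus one, a
#' numbering that is recomputed identically when the tree is written to
#' Newick and re-read.
#'
#' @param phylo an \code{ape::phylo} with branch lengths.
#' @return a \code{BackboneTree}
#' @export
backboneTree <- function(phylo) {
  if (!inherits(phylo, "phylo")) stop("not a phylo object")
  if (is.null(phylo$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(phylo$edge.length) || any(!is.finite(phylo$edge.length)))
    stop("missing or non-finite branch length")
  if (any(phylo$edge.length < 0))
    stop("negative branch length")
  if (is.null(phylo$tip.label) || any(is.na(phylo$tip.label)) ||
      any(!nzchar(phylo$tip.label)))
    stop("unlabeled leaf")
  ph <- ape::reorder.phylo(phylo, "postorder")
  obj <- new("BackboneTree", phylo = ph)
  validObject(obj)
  obj
}

#' Read a Newick tree file
#'
#' @param path path to a Newick file (single tree).
#' @return a \code{BackboneTree} with stable post-order edge numbering.
#' @export
readTree <- function(path) {
  ph <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(ph)) stop("unparseable Newick in '", path, "'")
  if (inherits(ph, "multiPhylo")) ph <- ph[[1L]]
  backboneTree(ph)
}

#' Write a BackboneTree to Newick
#'
#' @param x a \code{BackboneTree}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeTree <- function(x, path) {
  stopifnot(is(x, "BackboneTree"))
  ape::write.tree(treePhylo(x), file = path)
  invisible(path)
}

## tip index sets for every node (tips and internal), by post-order sweep
cladeTips <- function(ph) {
  nt <- length(ph$tip.label)
  nn <- ph$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- i
  for (r in seq_len(nrow(ph$edge))) {      # post-order: children first
    p <- ph$edge[r, 1L]; v <- ph$edge[r, 2L]
    sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

## canonical bipartition key of each edge: the child-side leaf-name set,
## complemented if it contains the anchor (lexicographically smallest leaf),
## so the key is orientation-free and comparable across trees on the same
## leaf set minus/plus pruned taxa.
edgeBipartitionKeys <- function(x, anchor = NULL) {
  ph <- treePhylo(x)
  sets <- cladeTips(ph)
  labels <- ph$tip.label
  if (is.null(anchor)) anchor <- min(labels)
  vapply(seq_len(nrow(ph$edge)), function(r) {
    tips <- labels[sets[[ph$edge[r, 2L]]]]
    if (anchor %in% tips) tips <- setdiff(labels, tips)
    paste(sort(tips), collapse = "\r")
  }, character(1))
}

## edge_num (0-based) of the parent edge of each node; NA for the root
edgeNumOfNode <- function(ph) {
  nn <- length(ph$tip.label) + ph$Nnode
  en <- rep(NA_integer_, nn)
  en[ph$edge[, 2L]] <- seq_len(nrow(ph$edge)) - 1L
  en
}

## Newick string with jplace-style {edge_num} annotations
jplaceTreeString <- function(x) {
  ph <- treePhylo(x)
  ntip <- length(ph$tip.label)
  en <- edgeNumOfNode(ph)
  len <- numeric(ntip + ph$Nnode)
  len[ph$edge[, 2L]] <- ph$edge.length
  kids <- split(ph$edge[, 2L], ph$edge[, 1L])
  root <- setdiff(ph$edge[, 1L], ph$edge[, 2L])[1L]
  rec <- function(v) {
    lab <- if (v <= ntip) ph$tip.label[v] else ""
    core <- if (v > ntip)
      paste0("(", paste(vapply(kids[[as.character(v)]], rec, character(1)),
                        collapse = ","), ")", lab)
    else lab
    if (is.na(en[v])) core
    else paste0(core, ":", format(len[v], digits = 15), "{", en[v], "}")
  }
  paste0(rec(root), ";")
}

#' Write placements to a jplace v3 file
#'
#' Emits the standard placement interchange JSON: a \code{"tree"} string with
#' \code{{edge_num}} annotations, a \code{"fields"} vector
#' \code{["edge_num","support","least_squares_error","distal_length",
#' "pendant_length"]}, and one row per candidate edge per query, sorted by
#' decreasing support.
#'
#' @param tree a \code{BackboneTree}
#' @param placements list of \code{SupportedPlacement}
#' @param path output path
#' @param invocation free-text provenance string stored in the metadata block
#' @return invisibly, \code{path}
#' @export
writeJplace <- function(tree, placements, path,
                        invocation = "lspplace") {
  stopifnot(is(tree, "BackboneTree"))
  E <- nEdges(tree)
  pl <- lapply(unname(placements), function(sp) {
    stopifnot(is(sp, "SupportedPlacement"))
    edges <- as.integer(names(sp@support))
    if (any(edges < 0L | edges >= E))
      stop("unknown edge number ", paste(edges[edges < 0L | edges >= E],
                                         collapse = ", "),
           " for query '", sp@queryId, "'")
    fits <- sp@edgeFits
    rows <- lapply(seq_along(edges), function(k) {
      f <- fits[fits$edgeNum == edges[k], , drop = FALSE]
      if (nrow(f) == 0L) f <- data.frame(distal = 0, pendant = 0, lse = NA_real_)
      list(edges[k], unname(sp@support[k]), f$lse[1L], f$distal[1L],
           f$pendant[1L])
    })
    list(p = rows, n = list(sp@queryId))
  })
  doc <- list(
    version = 3L,
    tree = jplaceTreeString(tree),
    placements = pl,
    fields = list("edge_num", "support", "least_squares_error",
                  "distal_length", "pendant_length"),
    metadata = list(invocation = invocation)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a jplace file into a placement table
#'
#' Only the information needed for evaluation is extracted: the per-query
#' support rows. The reference tree string is returned verbatim (and with the
#' \code{{edge_num}} annotations stripped, parseable by \code{ape}).
#'
#' @param path path to a jplace JSON file
#' @return list with \code{tree} (annotated Newick string) and
#'   \code{placements}, a data.frame with columns query_id, edge_num, support
#'   and any further declared fields.
#' @export
readJplace <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fields <- unlist(doc$fields)
  required <- c("version", "tree", "placements", "fields")
  miss <- setdiff(required, names(doc))
  if (length(miss)) stop("jplace missing keys: ", paste(miss, collapse = ", "))
  ps <- doc$placements
  ## normalize to a list of list(p = <matrix>, n/nm = <ids>) entries,
  ## whatever shape jsonlite simplification produced
  entries <- if (is.data.frame(ps)) {
    lapply(seq_len(nrow(ps)), function(i)
      list(p = ps$p[[i]],
           n = if (!is.null(ps$n)) ps$n[[i]] else ps$nm[[i]]))
  } else as.list(ps)
  rows <- list()
  for (i in seq_along(entries)) {
    p <- entries[[i]]$p
    if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, p)
    p <- matrix(as.numeric(unlist(p)), ncol = length(fields))
    nm <- unlist(entries[[i]]$n %||% entries[[i]]$nm)[1L]
    df <- as.data.frame(p)
    names(df) <- fields
    df$query_id <- nm
    rows[[i]] <- df
  }
  placements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(edge_num = integer(), support = numeric(),
               query_id = character())
  names(placements)[names(placements) == "edge_num"] <- "edge_num"
  list(tree = doc$tree, placements = placements)
}
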