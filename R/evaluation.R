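#' @include AllClasses.R
NULL

#' Label placements against known truth
#'
#' Joins a placement table (one row per query per supported edge) with a
#' truth table mapping each query to the edge its leaf was pruned from, and
#' labels each query's top placement. "Correct" means the highest-support
#' edge equals the true edge exactly; ties in support are broken by the
#' smaller edge number, matching the placement tie rule.
#'
#' @param placements data.frame with columns \code{query_id},
#'   \code{edge_num}, \code{support} (fractions in [0,1]), or a list of
#'   \code{SupportedPlacement} objects.
#' @param truth data.frame with columns \code{query_id}, \code{edge_num}
#'   (the true edge).
#' @return data.frame, one row per query: query_id, top_edge, support
#'   (of the top edge), true_edge, correct.
#' @export
labelPlacements <- function(placements, truth) {
  placements <- placementTable(placements)
  if (nrow(placements) == 0L) stop("empty placement set")
  if (!all(c("query_id", "edge_num") %in% names(truth)))
    stop("truth table must have columns query_id, edge_num")
  miss <- setdiff(unique(placements$query_id), truth$query_id)
  if (length(miss))
    stop("queries missing from truth table: ", paste(miss, collapse = ", "))
  sp <- split(placements, placements$query_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(-d$support, d$edge_num), ]
    data.frame(query_id = d$query_id[1L], top_edge = d$edge_num[1L],
               support = d$support[1L], stringsAsFactors = FALSE)
  }))
  out$true_edge <- truth$edge_num[match(out$query_id, truth$query_id)]
  out$correct <- out$top_edge == out$true_edge
  rownames(out) <- NULL
  out
}

#' Coerce supported placements to a long table
#'
#' @param placements list of \code{SupportedPlacement} or an already-long
#'   data.frame.
#' @return data.frame with columns query_id, edge_num, support.
#' @export
placementTable <- function(placements) {
  if (is.data.frame(placements)) return(placements)
  do.call(rbind, lapply(placements, function(sp) {
    data.frame(query_id = sp@queryId,
               edge_num = as.integer(names(sp@support)),
               support = as.numeric(sp@support), stringsAsFactors = FALSE)
  }))
}

#' Support calibration: binned accuracy and MSE against the unity line
#'
#' Bins the top placements by their support percentage into left-inclusive
#' intervals (the last bin holds exactly 100%), computes the fraction of
#' correct placements per bin, and summarizes miscalibration as the mean
#' squared difference between observed accuracy and the bin midpoint (as a
#' fraction). A perfectly calibrated method has roughly 45% correct
#' placements in its 40–50% support bin, and so on. By default the MSE
#' weights bins by occupancy; empty bins are excluded.
#'
#' @param labeled output of \code{\link{labelPlacements}}.
#' @param breaks bin edges on the percent scale (default \code{seq(0, 100,
#'   10)}, giving bins [0,10), ..., [90,100), \{100\}).
#' @param weighted weight the MSE by bin occupancy (default TRUE).
#' @return list with \code{bins} (data.frame: lower, midpoint, n, accuracy)
#'   and \code{mse}.
#' @export
calibration <- function(labeled, breaks = seq(0, 100, 10), weighted = TRUE) {
  if (nrow(labeled) == 0L) stop("empty input")
  sp <- labeled$support * 100
  idx <- findInterval(sp, breaks)         # last break -> extra bin {100}
  nb <- length(breaks)
  mids <- c(breaks[-nb] + diff(breaks) / 2, breaks[nb])
  lowers <- c(breaks[-nb], breaks[nb])
  rows <- lapply(seq_len(nb), function(k) {
    inBin <- idx == k
    if (!any(inBin)) return(NULL)
    data.frame(lower = lowers[k], midpoint = mids[k], n = sum(inBin),
               accuracy = mean(labeled$correct[inBin]))
  })
  bins <- do.call(rbind, rows)
  w <- if (weighted) bins$n else rep(1, nrow(bins))
  mse <- sum(w * (bins$accuracy - bins$midpoint / 100) ^ 2) / sum(w)
  list(bins = bins, mse = mse)
}

#' ROC curve and AUROC of support as a correctness classifier
#'
#' For each integer threshold T in 0..100, a correct placement with support
#' s >= T is a true positive (else a false negative) and an incorrect
#' placement with s >= T is a false positive (else a true negative); the
#' curve plots recall = TP/(TP+FN) against FPR = FP/(FP+TN). The area under
#' the curve is computed by the trapezoid rule over the threshold sweep
#' (anchored at (0,0)).
#'
#' @param labeled output of \code{\link{labelPlacements}}.
#' @return list with \code{points} (data.frame: threshold, fpr, recall) and
#'   \code{auroc} (\code{NA} with a message when only one class is present).
#' @export
rocSupport <- function(labeled) {
  s <- labeled$support * 100
  correct <- labeled$correct
  nPos <- sum(correct); nNeg <- sum(!correct)
  thresholds <- 0:100
  recall <- vapply(thresholds, function(T) sum(correct & s >= T), 0)
  fpr <- vapply(thresholds, function(T) sum(!correct & s >= T), 0)
  pts <- data.frame(threshold = thresholds,
                    fpr = if (nNeg) fpr / nNeg else NA_real_,
                    recall = if (nPos) recall / nPos else NA_real_)
  if (nPos == 0L || nNeg == 0L)
    return(list(points = pts, auroc = NA_real_,
                message = "single-class input: AUROC undefined"))
  ## sweep is monotone: T decreasing => (fpr, recall) non-decreasing
  xs <- c(0, rev(pts$fpr))
  ys <- c(0, rev(pts$recall))
  auroc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  list(points = pts, auroc = auroc)
}

#' ECDFs of top-placement support, split by correctness
#'
#' A well-behaved support measure concentrates incorrect placements at low
#' support and correct placements at high support, so the correct-class ECDF
#' should lie below (to the right of) the incorrect-class ECDF.
#'
#' @param labeled output of \code{\link{labelPlacements}}.
#' @return list with \code{correct} and \code{incorrect}, each a
#'   right-continuous step function from \code{stats::ecdf} (or NULL when the
#'   class is empty).
#' @export
ecdfByClass <- function(labeled) {
  if (nrow(labeled) == 0L) stop("empty input")
  mk <- function(v) if (length(v)) ecdf(v) else NULL
  list(correct = mk(labeled$support[labeled$correct]),
       incorrect = mk(labeled$support[!labeled$correct]))
}

#' Top-k placement accuracy
#'
#' The fraction of queries whose true edge is among their k highest-support
#' edges, for k = 1..kmax (ties broken by smaller edge number). Non-
#' decreasing in k by construction; k = 1 is the plain placement accuracy.
#'
#' @param placements long placement table or list of
#'   \code{SupportedPlacement}.
#' @param truth truth table (query_id, edge_num).
#' @param kmax largest k (default 10).
#' @return numeric vector of length kmax, accuracy at each k.
#' @export
topkAccuracy <- function(placements, truth, kmax = 10) {
  placements <- placementTable(placements)
  sp <- split(placements, placements$query_id)
  hitRank <- vapply(sp, function(d) {
    d <- d[order(-d$support, d$edge_num), ]
    te <- truth$edge_num[match(d$query_id[1L], truth$query_id)]
    r <- which(d$edge_num == te)
    if (length(r)) r[1L] else Inf
  }, numeric(1))
  vapply(seq_len(kmax), function(k) mean(hitRank <= k), numeric(1))
}

#' Read a placement truth table
#'
#' @param path TSV file with header columns query_id and edge_num.
#' @return data.frame(query_id, edge_num)
#' @export
readTruth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty truth file '", path, "'")
  if (!all(c("query_id", "edge_num") %in% names(df)))
    stop("truth file must have columns query_id, edge_num")
  df
}

#' Write a placement truth table
#'
#' @param truth data.frame(query_id, edge_num)
#' @param path output TSV path
#' @return invisibly, \code{path}
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
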