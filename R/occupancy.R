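#' Occupancy of interaction presence bits
#'
#' Occupancy is the percentage of trajectory frames in which an interaction
#' satisfies its geometric criterion: 100 * frames-present / frames. An
#' optional fractional window restricts the computation to a sub-range of
#' frames (e.g. the converged region).
#'
#' @param presence logical vector (one interaction) or matrix (records x
#'   frames).
#' @param n_frames total frame count (defaults to the presence length/width).
#' @param window optional fractional window \code{c(lo, hi)} over the frame
#'   range.
#' @return numeric occupancy percent (vector for a matrix input).
#' @export
occupancy_pct <- function(presence, n_frames = NULL, window = NULL) {
  if (is.matrix(presence)) {
    nf <- if (is.null(n_frames)) ncol(presence) else n_frames
    if (nf < 1) stop("n_frames must be >= 1")
    cols <- seq_len(ncol(presence))
    if (!is.null(window)) {
      cols <- which(.window_mask(seq_len(ncol(presence)), window))
      nf <- length(cols)
    }
    return(100 * rowSums(presence[, cols, drop = FALSE]) / nf)
  }
  nf <- if (is.null(n_frames)) length(presence) else n_frames
  if (nf < 1) stop("n_frames must be >= 1")
  idx <- seq_along(presence)
  if (!is.null(window)) idx <- which(.window_mask(seq_along(presence), window))
  100 * sum(presence[idx]) / length(idx)
}

#' Lifetime bin of an occupancy value
#'
#' Occupancy classes: short-lived (0 < X <= 10 percent), substantially live
#' (10 < X <= 90) and long-lived (90 < X <= 100). Boundaries are
#' right-inclusive, so exactly 10 percent is short-lived.
#'
#' @param occ numeric occupancies in (0, 100].
#' @return character vector: "short", "substantial" or "long".
#' @export
lifetime_bin <- function(occ) {
  if (any(occ <= 0 | occ > 100)) stop("occupancies must lie in (0, 100]")
  ifelse(occ <= 10, "short", ifelse(occ <= 90, "substantial", "long"))
}

#' Histogram of occupancies over lifetime bins
#'
#' Returns both the three-class lifetime counts and a fine-grained histogram
#' over ten right-inclusive 10-percent-wide bins (0,10], (10,20], ...,
#' (90,100].
#'
#' @param occ numeric occupancies in (0, 100]; may be empty.
#' @return list with \code{bins} (data.frame label, count) and \code{fine}
#'   (data.frame bin_low, bin_high, count).
#' @export
lifetime_histogram <- function(occ) {
  if (length(occ) && any(occ <= 0 | occ > 100)) {
    stop("occupancies must lie in (0, 100]")
  }
  lab <- factor(lifetime_bin(occ[occ > 0]),
                levels = c("short", "substantial", "long"))
  lo <- seq(0, 90, by = 10)
  fine_idx <- pmin(pmax(ceiling(occ / 10), 1L), 10L)
  fine <- tabulate(fine_idx, nbins = 10L)
  list(
    bins = data.frame(label = levels(lab), count = as.integer(table(lab))),
    fine = data.frame(bin_low = lo, bin_high = lo + 10, count = fine)
  )
}

#' Filter records by occupancy
#'
#' Keeps records whose occupancy is strictly higher than the threshold
#' (default 50 percent), so a record at exactly the threshold is dropped.
#'
#' @param records data.frame with an \code{occupancy} column.
#' @param threshold percent in (0, 100), exclusive bound.
#' @return the filtered data.frame.
#' @export
filter_by_occupancy <- function(records, threshold = 50) {
  if (threshold <= 0 || threshold >= 100) stop("threshold must lie in (0, 100)")
  stopifnot(is.data.frame(records), "occupancy" %in% names(records))
  out <- records[records$occupancy > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential classification of interactions across conditions
#'
#' Interactions observed under several conditions (e.g. temperatures) are
#' matched by identity and classified against an ordered condition sequence:
#' \itemize{
#'   \item \code{comparable}: above the occupancy filter in every condition
#'     and max - min occupancy within \code{comparability_tol};
#'   \item \code{maintained}: present everywhere with minimum occupancy at
#'     least \code{maintained_floor};
#'   \item \code{weakened}: present everywhere, occupancy strictly decreasing
#'     along the condition order with total drop above the tolerance;
#'   \item \code{variable}: present everywhere but matching none of the
#'     above;
#'   \item \code{lost}: above the filter in the reference condition only;
#'   \item \code{gained}: above the filter in non-reference conditions only;
#'   \item \code{partial}: any other mixed presence pattern.
#' }
#' The first three checks apply in the order listed, so a tight spread wins
#' over a high floor (a record at 94/93/92 is comparable, not maintained).
#'
#' @param tables named list of data.frames, one per condition in comparison
#'   order (first = reference), each with columns \code{id} and
#'   \code{occupancy}.
#' @param occupancy_filter presence threshold, percent (strict, default 50).
#' @param comparability_tol max spread in percentage points still called
#'   comparable (default 10).
#' @param maintained_floor minimum occupancy for "maintained" (default 80).
#' @return data.frame of class \code{differential_calls}: \code{id}, one
#'   \code{occ_<condition>} column per condition, \code{call}; rows sorted by
#'   \code{id}.
#' @export
differential_classify <- function(tables, occupancy_filter = 50,
                                  comparability_tol = 10,
                                  maintained_floor = 80) {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (condition labels)")
  }
  for (tb in tables) {
    if (!all(c("id", "occupancy") %in% names(tb))) {
      stop("each condition table needs 'id' and 'occupancy' columns")
    }
    if (anyDuplicated(tb$id)) stop("duplicate interaction ids within a condition")
  }
  conds <- names(tables)
  ids <- sort(unique(unlist(lapply(tables, function(tb) tb$id))))
  occ <- sapply(tables, function(tb) tb$occupancy[match(ids, tb$id)])
  occ <- matrix(occ, nrow = length(ids),
                dimnames = list(NULL, conds))
  present <- !is.na(occ) & occ > occupancy_filter
  call <- character(length(ids))
  for (k in seq_along(ids)) {
    o <- occ[k, ]
    pk <- present[k, ]
    if (all(pk)) {
      spread <- max(o) - min(o)
      decreasing <- all(diff(o) < 0)
      call[k] <- if (spread <= comparability_tol) "comparable"
        else if (min(o) >= maintained_floor) "maintained"
        else if (decreasing && spread > comparability_tol) "weakened"
        else "variable"
    } else if (pk[1] && !any(pk[-1])) {
      call[k] <- "lost"
    } else if (!pk[1] && any(pk[-1])) {
      call[k] <- "gained"
    } else {
      call[k] <- "partial"
    }
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(conds)) out[[paste0("occ_", conds[j])]] <- occ[, j]
  out$call <- call
  class(out) <- c("differential_calls", "data.frame")
  out
}
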