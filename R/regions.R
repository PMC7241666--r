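#' Per-residue fluctuation difference between two conditions
#'
#' Element-wise difference of two RMSF profiles (test minus reference) over
#' an identical residue coverage. Negative values (residues calmer in the
#' test condition) are retained.
#'
#' @param test,reference \code{residue_profile} data.frames (resseq, resname,
#'   value) covering the same residues.
#' @return a \code{residue_profile} of differences (Angstrom).
#' @export
delta_rmsf <- function(test, reference) {
  stopifnot(is.data.frame(test), is.data.frame(reference))
  if (nrow(test) != nrow(reference) ||
      !all(test$resseq == reference$resseq)) {
    stop("profiles must cover identical residues in the same order")
  }
  out <- test
  out$value <- test$value - reference$value
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' Call thermal-sensitive regions from a fluctuation profile
#'
#' Residues whose (delta-)RMSF meets the lower threshold are segmented into
#' maximal runs; runs separated by at most \code{max_gap} sub-threshold
#' residues merge; merged runs shorter than \code{min_length} residues are
#' discarded. The first and last \code{exclude_termini} residues of the
#' profile are ignored, since free chain termini fluctuate strongly for
#' reasons unrelated to thermal sensitivity. Each region is flagged
#' \code{"moderate"} or \code{"high"} according to the highest threshold its
#' maximum value reaches (defaults 0.5 and 1.0 Angstrom).
#'
#' @param profile a \code{residue_profile} (typically a delta-RMSF).
#' @param thresholds ascending numeric thresholds, Angstrom; the first
#'   segments, later ones only upgrade the flag.
#' @param min_length minimum region length in residues (default 3).
#' @param max_gap largest sub-threshold gap bridged when merging (default 1).
#' @param exclude_termini residues ignored at each profile end (default 5).
#' @return data.frame of class \code{region_calls}: \code{start}, \code{end}
#'   (residue numbers), \code{mean_delta}, \code{max_delta},
#'   \code{flag_level}; non-overlapping, sorted by \code{start}.
#' @export
call_regions <- function(profile, thresholds = c(0.5, 1.0), min_length = 3,
                         max_gap = 1, exclude_termini = 5) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  n <- nrow(profile)
  usable <- rep(TRUE, n)
  if (exclude_termini > 0) {
    drop <- c(seq_len(min(exclude_termini, n)),
              seq.int(max(1L, n - exclude_termini + 1L), n))
    usable[unique(drop)] <- FALSE
  }
  hot <- usable & profile$value >= thresholds[1]
  if (!any(hot)) {
    return(.empty_region_calls())
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by <= max_gap sub-threshold residues
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap <= max_gap) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_length, , drop = FALSE]
  if (!nrow(merged)) {
    return(.empty_region_calls())
  }
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(k) {
    idx <- merged$start[k]:merged$end[k]
    mx <- max(profile$value[idx])
    lvl_i <- max(which(thresholds <= mx))
    data.frame(start = profile$resseq[merged$start[k]],
               end = profile$resseq[merged$end[k]],
               mean_delta = mean(profile$value[idx]),
               max_delta = mx,
               flag_level = if (length(thresholds) > 1 && lvl_i >= 2)
                 "high" else "moderate")
  }))
  class(out) <- c("region_calls", "data.frame")
  out
}

.empty_region_calls <- function() {
  out <- data.frame(start = integer(0), end = integer(0),
                    mean_delta = numeric(0), max_delta = numeric(0),
                    flag_level = character(0))
  class(out) <- c("region_calls", "data.frame")
  out
}

#' One-way analysis of variance between condition groups
#'
#' Classical fixed-effects one-way ANOVA of two or more groups of per-frame
#' observations (RMSD, Rg or SASA values), via the equal-variance F test.
#' Per-frame values from a trajectory are serially correlated, so the
#' p-value rests on a pseudo-replication assumption; it is reported in the
#' same spirit in which such comparisons are conventionally made, and the
#' caveat is documented rather than corrected.
#'
#' @param groups list (optionally named) of numeric vectors, each of length
#'   at least 2.
#' @param alpha significance level for the flag (default 0.05).
#' @return list of class \code{anova_result}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p_value}, \code{significant}.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  res <- list(F = unname(ft$statistic),
              df_between = unname(ft$parameter[1]),
              df_within = unname(ft$parameter[2]),
              p_value = unname(ft$p.value),
              significant = unname(ft$p.value) < alpha)
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$F, digits = 6), ", p = ", format(x$p_value, digits = 4),
      if (x$significant) " (significant)" else "", "\n", sep = "")
  invisible(x)
}
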