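#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two conformations of the same atoms, via singular
#' value decomposition of the weighted covariance matrix with the standard
#' reflection correction so the returned rotation has determinant +1.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix to superpose onto.
#' @param weights optional per-atom non-negative weights (default: uniform).
#' @return object of class \code{superposition}: list with \code{rotation}
#'   (3 x 3, det +1), \code{translation} (length-3), and \code{rmsd_after}
#'   (Angstrom). The fitted coordinates are
#'   \code{mobile \%*\% t(rotation) + translation} (rows).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n) {
    stop("superposition needs matched coordinate sets of at least 3 atoms")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("invalid superposition weights")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  R <- sweep(reference, 2, cr)
  if (qr(M)$rank < 2) stop("degenerate (collinear) configuration")
  H <- t(M * w) %*% R
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - R)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - rot %*% cm),
                 rmsd_after = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp a \code{superposition}.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

# Direct RMSD between matched coordinate sets (no fitting).
.raw_rmsd <- function(a, b, weights = NULL) {
  n <- nrow(a)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Backbone RMSD time series relative to a reference structure
#'
#' For every frame, the selected atoms are rigidly superposed onto the same
#' atoms of the reference (the initial structure by default) and the RMSD
#' over the selection is recorded. A converged-window mean and standard
#' deviation are returned alongside the series; the window defaults to the
#' final 75 percent of the run, the portion of a production trajectory
#' typically treated as equilibrated.
#'
#' @param traj a \code{trajectory}.
#' @param selection selection name or atom indices (default \code{"backbone"}).
#' @param reference n x 3 coordinate matrix of the reference structure for
#'   the full topology (default: the trajectory's first frame).
#' @param window numeric length-2 fractional time window used for the
#'   summary, e.g. \code{c(0.25, 1)}.
#' @return object of class \code{metric_series}: list with \code{series}
#'   (data.frame frame, time_ns, value), \code{window_mean}, \code{window_sd},
#'   \code{label}, \code{units}.
#' @export
rmsd_series <- function(traj, selection = "backbone", reference = NULL,
                        window = c(0.25, 1)) {
  sel <- resolve_selection(traj$topology, selection)
  if (!length(sel)) stop("empty selection")
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  ref <- as.matrix(reference)[sel, , drop = FALSE]
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    kabsch_superpose(traj$coords[sel, , f], ref)$rmsd_after
  }, numeric(1))
  .metric_series(traj, vals, window, label = "rmsd", units = "Angstrom")
}

.metric_series <- function(traj, vals, window, label, units) {
  nf <- length(vals)
  t_ns <- traj$times / 1000
  in_win <- .window_mask(traj$times, window)
  structure(list(
    series = data.frame(frame = seq_len(nf) - 1L, time_ns = t_ns, value = vals),
    window_mean = mean(vals[in_win]),
    window_sd = stats::sd(vals[in_win]),
    window = window, label = label, units = units,
    condition = traj$condition
  ), class = "metric_series")
}

.window_mask <- function(times, window) {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  t0 <- min(times); t1 <- max(times)
  lo <- t0 + window[1] * (t1 - t0)
  hi <- t0 + window[2] * (t1 - t0)
  times >= lo & times <= hi
}

#' @export
print.metric_series <- function(x, ...) {
  cat("<metric_series> ", x$label, " (", x$units, "), ", nrow(x$series),
      " frames; window [", x$window[1], ", ", x$window[2], "] mean ",
      format(x$window_mean, digits = 4), " +/- ",
      format(x$window_sd, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Per-residue root-mean-square fluctuation profile
#'
#' Every frame is superposed onto the initial structure using the alignment
#' selection; the fluctuation of each selected atom is then the RMS deviation
#' from its reference position over time. By convention the reference for the
#' deviation is the atom's time-mean position (\code{reference =
#' "mean_position"}); the alternative \code{"initial_structure"} measures
#' deviations from frame 1 instead. The per-residue value is the mean over
#' the residue's selected atoms.
#'
#' @param traj a \code{trajectory} with at least 2 frames.
#' @param selection atoms profiled (default \code{"backbone"}).
#' @param align_selection atoms used for the superposition (default
#'   \code{"backbone"}).
#' @param reference \code{"mean_position"} or \code{"initial_structure"}.
#' @return data.frame of class \code{residue_profile} with columns
#'   \code{resseq}, \code{resname}, \code{value} (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = "backbone",
                         align_selection = "backbone",
                         reference = c("mean_position", "initial_structure")) {
  reference <- match.arg(reference)
  if (n_frames(traj) < 2) stop("RMSF requires at least 2 frames")
  sel <- resolve_selection(traj$topology, selection)
  asel <- resolve_selection(traj$topology, align_selection)
  if (!length(sel) || !length(asel)) stop("empty selection")
  nf <- n_frames(traj)
  ref_all <- frame_coords(traj, 1)
  aligned <- array(NA_real_, dim = c(length(sel), 3, nf))
  for (f in seq_len(nf)) {
    sp <- kabsch_superpose(traj$coords[asel, , f], ref_all[asel, , drop = FALSE])
    aligned[, , f] <- apply_superposition(sp, traj$coords[sel, , f])
  }
  center <- if (reference == "mean_position") {
    apply(aligned, c(1, 2), mean)
  } else {
    ref_all[sel, , drop = FALSE]
  }
  dev2 <- sweep(aligned, c(1, 2), center)^2
  msf <- rowMeans(apply(dev2, c(1, 3), sum))  # time-mean squared 3-D deviation
  atom_rmsf <- sqrt(msf)
  rid <- traj$topology$atoms$residue_id[sel]
  res <- traj$topology$residues
  val <- tapply(atom_rmsf, rid, mean)
  out <- data.frame(
    resseq = res$resseq[match(as.integer(names(val)), res$residue_id)],
    resname = res$resname[match(as.integer(names(val)), res$residue_id)],
    value = as.numeric(val)
  )
  out <- out[order(out$resseq), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' Radius of gyration
#'
#' Rg = sqrt( sum w_i |r_i - rbar|^2 / sum w_i ) with rbar the weighted
#' centroid; mass-weighted by default. For a trajectory a time series with a
#' converged-window summary is returned; for a single coordinate matrix, a
#' scalar.
#'
#' @param x a \code{trajectory} or an n x 3 coordinate matrix.
#' @param topology required when \code{x} is a matrix and masses are needed.
#' @param selection selection name or indices (default \code{"protein"}).
#' @param mass_weighted logical (default TRUE).
#' @param window fractional converged window for the trajectory summary.
#' @return scalar Angstrom, or a \code{metric_series} for trajectories.
#' @export
radius_of_gyration <- function(x, topology = NULL, selection = "protein",
                               mass_weighted = TRUE, window = c(0.25, 1)) {
  if (inherits(x, "trajectory")) {
    sel <- resolve_selection(x$topology, selection)
    if (!length(sel)) stop("empty selection")
    w <- if (mass_weighted) x$topology$atoms$mass[sel] else rep(1, length(sel))
    vals <- vapply(seq_len(n_frames(x)), function(f) {
      .rg_one(x$coords[sel, , f], w)
    }, numeric(1))
    return(.metric_series(x, vals, window, label = "rg", units = "Angstrom"))
  }
  coords <- as.matrix(x)
  sel <- if (is.null(topology)) seq_len(nrow(coords))
         else resolve_selection(topology, selection)
  if (!length(sel)) stop("empty selection")
  w <- if (mass_weighted && !is.null(topology)) topology$atoms$mass[sel]
       else rep(1, length(sel))
  .rg_one(coords[sel, , drop = FALSE], w)
}

.rg_one <- function(coords, w) {
  if (sum(w) <= 0) stop("zero total weight")
  wn <- w / sum(w)
  ctr <- colSums(coords * wn)
  sqrt(sum(wn * rowSums(sweep(coords, 2, ctr)^2)))
}
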