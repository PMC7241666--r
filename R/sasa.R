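#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom's van der Waals sphere is inflated by the probe
#' radius and covered with a deterministic golden-spiral point set; a point
#' is accessible when it lies outside every neighbor's inflated sphere. The
#' atom's area is the accessible fraction of \code{4 * pi * (r + probe)^2}.
#' Neighbor candidates come from a cell-list search over the inflated-radius
#' interaction distance.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe_radius probe sphere radius, default 1.4 Angstrom (water).
#' @param n_points sphere points per atom, default 960.
#' @return numeric vector of per-atom areas in Angstrom^2.
#' @export
shrake_rupley <- function(coords, radii, probe_radius = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("radii must match atom count")
  if (probe_radius < 0) stop("probe_radius must be non-negative")
  if (n_points < 1) stop("n_points must be positive")
  pts <- golden_spiral_points(n_points)
  R <- radii + probe_radius
  # candidate neighbor pairs within the largest possible interaction distance
  max_cut <- 2 * max(R)
  nb <- if (n > 1) {
    neighbor_pairs(coords, seq_len(n), cutoff = max_cut, method = "cell")
  } else {
    data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  }
  nb <- rbind(nb, data.frame(i = nb$j, j = nb$i, dist = nb$dist))
  nb <- nb[nb$dist < R[nb$i] + R[nb$j], , drop = FALSE]
  nb_by_atom <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    surf <- pts * R[i]
    surf <- sweep(surf, 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb_by_atom[[i]]) {
      if (!any(exposed)) break
      d2 <- rowSums(sweep(surf[exposed, , drop = FALSE], 2, coords[j, ])^2)
      exposed[exposed] <- d2 >= R[j]^2
    }
    areas[i] <- sum(exposed) / n_points * 4 * pi * R[i]^2
  }
  areas
}

#' Deterministic golden-spiral point set on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  theta <- pi * (1 + sqrt(5)) * k
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Aggregate per-atom SASA into the study's class breakdown
#'
#' Sums per-atom areas over the protein by residue class: hydrophobic
#' residues vs hydrophilic residues (everything else, so the two components
#' add to the total), plus the catalytic-set area. Class components are
#' reported in nm^2 (Angstrom^2 / 100); the catalytic area is kept in
#' Angstrom^2, where a few residues' areas are of order tens.
#'
#' @param areas per-atom areas in Angstrom^2 (protein atoms included).
#' @param topology a \code{topology}.
#' @param catalytic_set residue sequence numbers of the catalytic residues.
#' @return list of class \code{sasa_breakdown}: \code{total}, \code{hydrophobic},
#'   \code{hydrophilic} (nm^2), \code{catalytic} (Angstrom^2) and
#'   \code{per_residue} (a \code{residue_profile}, Angstrom^2).
#' @export
aggregate_sasa <- function(areas, topology, catalytic_set = default_catalytic_set()) {
  prot <- topology$selections$protein
  at <- topology$atoms
  a <- areas[prot]
  pho <- classify_residue(at$resname[prot], quiet = TRUE) == "hydrophobic"
  total <- sum(a)
  hydrophobic <- sum(a[pho])
  cat_idx <- at$resseq[prot] %in% catalytic_set
  if (length(catalytic_set) && !any(at$resseq[prot] %in% catalytic_set)) {
    warning("catalytic set absent from topology; catalytic SASA = 0")
  }
  rid <- at$residue_id[prot]
  per_res <- tapply(a, rid, sum)
  res <- topology$residues
  prof <- data.frame(
    resseq = res$resseq[match(as.integer(names(per_res)), res$residue_id)],
    resname = res$resname[match(as.integer(names(per_res)), res$residue_id)],
    value = as.numeric(per_res)
  )
  prof <- prof[order(prof$resseq), , drop = FALSE]
  rownames(prof) <- NULL
  class(prof) <- c("residue_profile", "data.frame")
  structure(list(
    total = total / 100, hydrophobic = hydrophobic / 100,
    hydrophilic = (total - hydrophobic) / 100,
    catalytic = sum(a[cat_idx]),
    per_residue = prof
  ), class = "sasa_breakdown")
}

#' Per-frame SASA series with class breakdown
#'
#' Computes the Shrake-Rupley area on the protein atoms of every frame
#' (waters and ions excluded from both surface and occlusion) and aggregates
#' per frame, returning the per-frame table plus converged-window summaries.
#'
#' @param traj a \code{trajectory}.
#' @param probe_radius,n_points passed to \code{\link{shrake_rupley}}.
#' @param include_hydrogens include hydrogens as surface/occluding atoms
#'   (default TRUE; hydrogen-stripped mode eases cross-tool comparison).
#' @param catalytic_set catalytic residue numbers.
#' @param window fractional converged window for summaries.
#' @param stride analyze every \code{stride}-th frame.
#' @return list of class \code{sasa_series}: \code{series} (data.frame with
#'   frame, time_ns, sasa_total, sasa_pho, sasa_phil in nm^2, sasa_catalytic
#'   in Angstrom^2), and \code{window_mean}/\code{window_sd} (named vectors).
#' @export
sasa_series <- function(traj, probe_radius = 1.4, n_points = 960,
                        include_hydrogens = TRUE,
                        catalytic_set = default_catalytic_set(),
                        window = c(0.25, 1), stride = 1L) {
  topo <- traj$topology
  prot <- topo$selections$protein
  if (!include_hydrogens) prot <- prot[topo$atoms$element[prot] != "H"]
  frames <- seq(1L, n_frames(traj), by = stride)
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    areas_prot <- shrake_rupley(traj$coords[prot, , f],
                                topo$atoms$vdw[prot],
                                probe_radius = probe_radius,
                                n_points = n_points)
    areas <- numeric(nrow(topo$atoms))
    areas[prot] <- areas_prot
    bd <- suppressWarnings(aggregate_sasa(areas, topo, catalytic_set))
    rows[[k]] <- data.frame(frame = f - 1L, time_ns = traj$times[f] / 1000,
                            sasa_total = bd$total, sasa_pho = bd$hydrophobic,
                            sasa_phil = bd$hydrophilic,
                            sasa_catalytic = bd$catalytic)
  }
  series <- do.call(rbind, rows)
  in_win <- .window_mask(traj$times[frames], window)
  cols <- c("sasa_total", "sasa_pho", "sasa_phil", "sasa_catalytic")
  structure(list(
    series = series,
    window_mean = vapply(series[in_win, cols], mean, numeric(1)),
    window_sd = vapply(series[in_win, cols], stats::sd, numeric(1)),
    window = window, condition = traj$condition
  ), class = "sasa_series")
}

#' Histogram of a SASA time series with the modal-bin summary
#'
#' Bins the per-frame total SASA into fixed-width bins whose centers sit on
#' odd integers (width 2 nm^2 by default), reports the full histogram and the
#' major peak: the modal bin's center and the percentage of frames in it.
#' Ties between equally occupied bins resolve to the lowest center and are
#' flagged.
#'
#' @param values per-frame SASA values (nm^2).
#' @param bin_width bin width in nm^2 (default 2).
#' @return list of class \code{sasa_distribution}: \code{histogram}
#'   (data.frame center, count, pct), \code{peak_center}, \code{peak_pct},
#'   \code{tie}.
#' @export
sasa_distribution <- function(values, bin_width = 2) {
  if (!length(values)) stop("no values")
  if (bin_width <= 0) stop("bin_width must be positive")
  # centers at odd multiples of bin_width/2 * ... anchor: center = bin_width * k
  # with edges offset so that for width 2 the centers are odd integers
  centers <- bin_width * floor(values / bin_width) + bin_width / 2
  tab <- table(centers)
  cts <- as.integer(tab)
  ctr <- as.numeric(names(tab))
  ord <- order(ctr)
  ctr <- ctr[ord]; cts <- cts[ord]
  hist <- data.frame(center = ctr, count = cts,
                     pct = 100 * cts / length(values))
  best <- which(cts == max(cts))
  tie <- length(best) > 1
  peak <- best[1]  # lowest center on ties
  structure(list(histogram = hist, peak_center = ctr[peak],
                 peak_pct = hist$pct[peak], tie = tie),
            class = "sasa_distribution")
}
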