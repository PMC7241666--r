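#' Enumerate hydrogen-bond donors and acceptors
#'
#' Donors are nitrogen or oxygen atoms carrying at least one covalently
#' bonded hydrogen (one donor-hydrogen pair per bonded hydrogen, so e.g. a
#' lysine NZ with three hydrogens yields three candidates); acceptors are all
#' nitrogen and oxygen atoms. Water oxygens act as both donor (via their two
#' hydrogens) and acceptor.
#'
#' @param topology a \code{topology}.
#' @return list with \code{donors} (data.frame donor, hydrogen: atom indices)
#'   and \code{acceptors} (integer atom indices).
#' @export
enumerate_donors_acceptors <- function(topology) {
  at <- topology$atoms
  is_no <- at$element %in% c("N", "O")
  h_idx <- which(at$element == "H")
  if (!length(h_idx)) {
    stop("topology has no hydrogens; hydrogen-bond analysis requires a ",
         "protonated input structure")
  }
  b <- topology$bonds
  dh <- rbind(b[at$element[b[, 1]] == "H" & is_no[b[, 2]], c(2, 1), drop = FALSE],
              b[at$element[b[, 2]] == "H" & is_no[b[, 1]], c(1, 2), drop = FALSE])
  donors <- data.frame(donor = dh[, 1], hydrogen = dh[, 2])
  donors <- donors[order(donors$donor, donors$hydrogen), , drop = FALSE]
  rownames(donors) <- NULL
  list(donors = donors, acceptors = which(is_no))
}

#' Detect hydrogen bonds across a trajectory
#'
#' A hydrogen bond is present in a frame when the donor-acceptor distance is
#' at most \code{distance_cutoff} (3.5 Angstrom default, boundary inclusive)
#' and the donor-hydrogen-acceptor angle, measured at the hydrogen, is
#' strictly larger than \code{angle_cutoff} (120 degrees default). Pairs
#' within one residue are excluded, as are water-water pairs.
#'
#' Two engines produce identical presence bits: \code{"brute"} evaluates
#' every donor-acceptor combination with frame-vectorized arithmetic;
#' \code{"cell"} runs a per-frame cell-list neighbor search over the distance
#' criterion before applying the angle test.
#'
#' @param traj a \code{trajectory}.
#' @param distance_cutoff donor-acceptor maximum distance, Angstrom.
#' @param angle_cutoff minimum D-H-A angle, degrees (exclusive).
#' @param method \code{"brute"} or \code{"cell"}.
#' @return object of class \code{pair_series} holding the candidate table,
#'   the per-frame presence matrix and donor-acceptor distance matrix.
#' @export
detect_hbonds <- function(traj, distance_cutoff = 3.5, angle_cutoff = 120,
                          method = c("brute", "cell")) {
  method <- match.arg(method)
  if (distance_cutoff <= 0 || angle_cutoff <= 0) stop("cutoffs must be positive")
  topo <- traj$topology
  at <- topo$atoms
  da <- enumerate_donors_acceptors(topo)
  is_water <- at$resname %in% .water_resnames
  # candidate triples: all donor-H x acceptor, different residues, not water-water
  nd <- nrow(da$donors)
  cand <- data.frame(
    donor = rep(da$donors$donor, each = length(da$acceptors)),
    hydrogen = rep(da$donors$hydrogen, each = length(da$acceptors)),
    acceptor = rep(da$acceptors, nd)
  )
  keep <- at$residue_id[cand$donor] != at$residue_id[cand$acceptor] &
    !(is_water[cand$donor] & is_water[cand$acceptor])
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  nf <- n_frames(traj)
  np <- nrow(cand)
  presence <- matrix(FALSE, np, nf)
  dist <- matrix(NA_real_, np, nf)
  if (method == "brute") {
    for (p in seq_len(np)) {
      d <- .pair_distance_series(traj$coords, cand$donor[p], cand$acceptor[p])
      dist[p, ] <- d
      close <- which(d <= distance_cutoff)
      if (length(close)) {
        ang <- .dha_angle(traj$coords, cand$donor[p], cand$hydrogen[p],
                          cand$acceptor[p], close)
        presence[p, close] <- ang > angle_cutoff
      }
    }
  } else {
    key <- paste(cand$donor, cand$acceptor)
    for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      nb <- neighbor_pairs(co, unique(cand$donor), da$acceptors,
                           cutoff = distance_cutoff, method = "cell")
      if (!nrow(nb)) next
      hit <- match(paste(nb$i, nb$j), key)
      ok <- !is.na(hit)
      for (m in which(ok)) {
        rows <- which(key == paste(nb$i[m], nb$j[m]))
        for (p in rows) {
          ang <- .dha_angle(traj$coords, cand$donor[p], cand$hydrogen[p],
                            cand$acceptor[p], f)
          presence[p, f] <- ang > angle_cutoff
          dist[p, f] <- nb$dist[m]
        }
      }
    }
    # fill remaining distances for parity with the brute engine
    for (p in seq_len(np)) {
      miss <- is.na(dist[p, ])
      if (any(miss)) {
        dist[p, miss] <- .pair_distance_series(
          traj$coords[, , miss, drop = FALSE], cand$donor[p], cand$acceptor[p])
      }
    }
  }
  pairs <- data.frame(
    cand,
    donor_res = at$resseq[cand$donor],
    donor_resname = at$resname[cand$donor],
    donor_atom = at$name[cand$donor],
    h_atom = at$name[cand$hydrogen],
    acceptor_res = at$resseq[cand$acceptor],
    acceptor_resname = at$resname[cand$acceptor],
    acceptor_atom = at$name[cand$acceptor],
    stringsAsFactors = FALSE
  )
  .pair_series("hbond", pairs, presence, dist, topo)
}

.dha_angle <- function(coords_arr, d, h, a, frames) {
  u <- coords_arr[d, , frames, drop = FALSE] - coords_arr[h, , frames, drop = FALSE]
  v <- coords_arr[a, , frames, drop = FALSE] - coords_arr[h, , frames, drop = FALSE]
  u <- array(u, dim = dim(u)[2:3]); v <- array(v, dim = dim(v)[2:3])
  cosang <- colSums(u * v) / sqrt(colSums(u^2) * colSums(v^2))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

.pair_series <- function(type, pairs, presence, dist, topology) {
  structure(list(type = type, pairs = pairs, presence = presence,
                 distance = dist, n_frames = ncol(presence),
                 topology = topology),
            class = "pair_series")
}

#' @export
print.pair_series <- function(x, ...) {
  cat("<pair_series> ", x$type, ": ", nrow(x$pairs), " candidates x ",
      x$n_frames, " frames (", sum(rowSums(x$presence) > 0),
      " ever present)\n", sep = "")
  invisible(x)
}

#' Deduplicate hydrogen bonds sharing donor and acceptor atoms
#'
#' Candidates with the same (donor atom, acceptor atom) but different
#' hydrogens are redundant; only the one with the highest occupancy is kept.
#' Exact ties resolve to the lowest hydrogen atom index, deterministically.
#'
#' @param ps a \code{pair_series} from \code{\link{detect_hbonds}}.
#' @return a \code{pair_series} whose \code{pairs} carry an \code{occupancy}
#'   column, with one row per (donor, acceptor) atom pair.
#' @export
dedupe_hbonds <- function(ps) {
  stopifnot(inherits(ps, "pair_series"), ps$type == "hbond")
  occ <- occupancy_pct(ps$presence, ps$n_frames)
  key <- paste(ps$pairs$donor, ps$pairs$acceptor)
  ord <- order(key, -occ, ps$pairs$hydrogen)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  pairs <- ps$pairs[keep, , drop = FALSE]
  pairs$occupancy <- occ[keep]
  rownames(pairs) <- NULL
  out <- .pair_series("hbond", pairs, ps$presence[keep, , drop = FALSE],
                      ps$distance[keep, , drop = FALSE], ps$topology)
  out$deduped <- TRUE
  out
}

#' Classify hydrogen bonds by backbone role, residue chemistry and partner
#'
#' Adds three labels to every record: \code{backbone_class} (MM, MS or SS --
#' whether donor and acceptor heavy atoms are main-chain (N, C, O, OXT) or
#' side-chain atoms), \code{chem_class} (symmetric residue-class pair:
#' chr-chr, pho-pho, phi-phi, pho-phi; any pairing involving a residue of
#' class "other", or a charged residue with a non-charged one, is "other";
#' for protein-water bonds the protein residue's class gives chr-water /
#' pho-water / phi-water), and \code{partner_kind} (protein or water).
#'
#' @param ps a deduplicated hydrogen-bond \code{pair_series}.
#' @return the \code{pair_series} with classification columns added.
#' @export
classify_hbonds <- function(ps) {
  stopifnot(inherits(ps, "pair_series"), ps$type == "hbond")
  at <- ps$topology$atoms
  p <- ps$pairs
  main_names <- c("N", "C", "O", "OXT")
  d_main <- p$donor_atom %in% main_names
  a_main <- p$acceptor_atom %in% main_names
  d_water <- p$donor_resname %in% .water_resnames
  a_water <- p$acceptor_resname %in% .water_resnames
  water <- d_water | a_water
  p$partner_kind <- ifelse(water, "water", "protein")
  p$backbone_class <- ifelse(d_main & a_main, "MM",
                       ifelse(!d_main & !a_main, "SS", "MS"))
  cls_abbrev <- c(charged = "chr", hydrophobic = "pho", polar = "phi",
                  other = "other")
  d_cls <- cls_abbrev[classify_residue(p$donor_resname, quiet = TRUE)]
  a_cls <- cls_abbrev[classify_residue(p$acceptor_resname, quiet = TRUE)]
  chem <- character(nrow(p))
  both <- cbind(d_cls, a_cls)
  pair_lab <- apply(both, 1, function(z) paste(sort(z), collapse = "-"))
  chem[pair_lab == "chr-chr"] <- "chr-chr"
  chem[pair_lab == "pho-pho"] <- "pho-pho"
  chem[pair_lab == "phi-phi"] <- "phi-phi"
  chem[pair_lab == "phi-pho"] <- "pho-phi"
  chem[chem == ""] <- "other"
  # protein-water: classify by the protein residue's class
  prot_cls <- ifelse(d_water, a_cls, d_cls)
  chem[water] <- paste0(prot_cls[water], "-water")
  p$chem_class <- chem
  # water-side backbone assignment: M-water/S-water by the protein atom
  prot_main <- ifelse(d_water, a_main, d_main)
  p$backbone_class[water] <- ifelse(prot_main[water], "M-water", "S-water")
  ps$pairs <- p
  ps
}

#' Mean per-frame hydrogen-bond counts by category
#'
#' For each category the mean count per frame is the sum of all per-frame
#' presences of the category's records divided by the frame count. Intra-
#' protein categories: total, MM, MS, SS, chr-chr, pho-pho, phi-phi, pho-phi,
#' other. Protein-water categories: total, M-water, S-water, chr-water,
#' pho-water, phi-water.
#'
#' @param ps a classified, deduplicated hydrogen-bond \code{pair_series}.
#' @return list with data.frames \code{protein} and \code{water} (columns
#'   category, mean_count).
#' @export
mean_hbond_counts <- function(ps) {
  stopifnot(inherits(ps, "pair_series"), !is.null(ps$pairs$backbone_class))
  p <- ps$pairs
  nf <- ps$n_frames
  pres_sum <- rowSums(ps$presence)
  mean_of <- function(mask) sum(pres_sum[mask]) / nf
  prot <- p$partner_kind == "protein"
  protein <- data.frame(
    category = c("total", "MM", "MS", "SS",
                 "chr-chr", "pho-pho", "phi-phi", "pho-phi", "other"),
    mean_count = c(
      mean_of(prot),
      mean_of(prot & p$backbone_class == "MM"),
      mean_of(prot & p$backbone_class == "MS"),
      mean_of(prot & p$backbone_class == "SS"),
      mean_of(prot & p$chem_class == "chr-chr"),
      mean_of(prot & p$chem_class == "pho-pho"),
      mean_of(prot & p$chem_class == "phi-phi"),
      mean_of(prot & p$chem_class == "pho-phi"),
      mean_of(prot & p$chem_class == "other")
    )
  )
  wat <- !prot
  water <- data.frame(
    category = c("total", "M-water", "S-water",
                 "chr-water", "pho-water", "phi-water"),
    mean_count = c(
      mean_of(wat),
      mean_of(wat & p$backbone_class == "M-water"),
      mean_of(wat & p$backbone_class == "S-water"),
      mean_of(wat & p$chem_class == "chr-water"),
      mean_of(wat & p$chem_class == "pho-water"),
      mean_of(wat & p$chem_class == "phi-water")
    )
  )
  list(protein = protein, water = water)
}

#' Per-frame hydrogen-bond count series
#' @param ps a \code{pair_series}.
#' @param mask optional logical record mask restricting the count.
#' @return integer vector, one count per frame.
#' @export
count_series <- function(ps, mask = NULL) {
  pres <- ps$presence
  if (!is.null(mask)) pres <- pres[mask, , drop = FALSE]
  colSums(pres)
}
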