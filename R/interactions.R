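.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_atoms  <- list(ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"))

# PDB spellings of the Greek-letter hydrophobic-carbon list
.hydrophobic_carbons <- c("C", "CA", "CB", "CD", "CD1", "CD2", "CE", "CE1",
                          "CE2", "CE3", "CG", "CG1", "CG2", "CZ", "CZ2",
                          "CZ3", "CH2")

.one_letter <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                 GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                 LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                 SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Detect salt bridges across a trajectory
#'
#' A salt-bridge event is present in a frame when the distance between a
#' side-chain carboxylate oxygen of an acidic residue (OD1/OD2 of Asp,
#' OE1/OE2 of Glu) and a side-chain nitrogen of a basic residue (NE/NH1/NH2
#' of Arg, NZ of Lys) is strictly below the cutoff (4 Angstrom default).
#' Every acidic-oxygen/basic-nitrogen atom combination of every residue pair
#' is evaluated.
#'
#' @param traj a \code{trajectory}.
#' @param cutoff Angstrom, exclusive bound (default 4.0; 3.9 is the common
#'   literature alternative).
#' @param method \code{"brute"} (frame-vectorized all pairs) or \code{"cell"}
#'   (per-frame cell-list search); identical results.
#' @return a \code{pair_series} of atom-pair events.
#' @export
detect_salt_bridges <- function(traj, cutoff = 4.0, method = c("brute", "cell")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- traj$topology$atoms
  acid <- which(mapply(function(rn, an) {
    !is.null(.acidic_atoms[[rn]]) && an %in% .acidic_atoms[[rn]]
  }, at$resname, at$name))
  base <- which(mapply(function(rn, an) {
    !is.null(.basic_atoms[[rn]]) && an %in% .basic_atoms[[rn]]
  }, at$resname, at$name))
  cand <- expand.grid(o = acid, n = base)
  nf <- n_frames(traj)
  np <- nrow(cand)
  presence <- matrix(FALSE, np, nf)
  dist <- matrix(NA_real_, np, nf)
  if (np) {
    if (method == "brute") {
      for (p in seq_len(np)) {
        d <- .pair_distance_series(traj$coords, cand$o[p], cand$n[p])
        dist[p, ] <- d
        presence[p, ] <- d < cutoff
      }
    } else {
      key <- paste(cand$o, cand$n)
      for (p in seq_len(np)) {
        dist[p, ] <- .pair_distance_series(traj$coords, cand$o[p], cand$n[p])
      }
      for (f in seq_len(nf)) {
        nb <- neighbor_pairs(frame_coords(traj, f), acid, base,
                             cutoff = cutoff, method = "cell")
        nb <- nb[nb$dist < cutoff, , drop = FALSE]  # strict bound
        hit <- match(paste(nb$i, nb$j), key)
        presence[hit[!is.na(hit)], f] <- TRUE
      }
    }
  }
  pairs <- data.frame(
    o = cand$o, n = cand$n,
    acidic_res = at$resseq[cand$o], acidic_resname = at$resname[cand$o],
    acidic_atom = at$name[cand$o],
    basic_res = at$resseq[cand$n], basic_resname = at$resname[cand$n],
    basic_atom = at$name[cand$n],
    stringsAsFactors = FALSE
  )
  .pair_series("saltbridge", pairs, presence, dist, traj$topology)
}

#' Collapse salt-bridge events to unique residue pairs
#'
#' Atom-pair events between the same two residues are redundant; the atom
#' pair with the highest occupancy represents the residue pair, and its mean
#' and standard deviation of distance over the frames where it is present
#' are recorded. A union-of-atom-pairs occupancy (residue pair present when
#' any atom combination is in range) is reported alongside for reference.
#'
#' @param ps a salt-bridge \code{pair_series}.
#' @return data.frame of class \code{saltbridge_records}: \code{pair} (label
#'   like "D317-R378"), residue/atom identities, \code{occupancy} (best atom
#'   pair, percent), \code{occupancy_union}, \code{mean_dist}, \code{sd_dist};
#'   sorted by decreasing occupancy then label.
#' @export
unique_salt_bridges <- function(ps) {
  stopifnot(inherits(ps, "pair_series"), ps$type == "saltbridge")
  p <- ps$pairs
  if (!nrow(p)) {
    out <- data.frame(pair = character(0), acidic_res = integer(0),
                      basic_res = integer(0), acidic_atom = character(0),
                      basic_atom = character(0), occupancy = numeric(0),
                      occupancy_union = numeric(0), mean_dist = numeric(0),
                      sd_dist = numeric(0))
    class(out) <- c("saltbridge_records", "data.frame")
    return(out)
  }
  occ <- occupancy_pct(ps$presence, ps$n_frames)
  key <- paste(p$acidic_res, p$basic_res)
  ord <- order(key, -occ, p$o, p$n)
  keep <- sort(ord[!duplicated(key[ord])])
  rows <- lapply(keep, function(k) {
    members <- which(key == key[k])
    union_pres <- colSums(ps$presence[members, , drop = FALSE]) > 0
    d <- ps$distance[k, ps$presence[k, ]]
    data.frame(
      pair = paste0(.one_letter[p$acidic_resname[k]], p$acidic_res[k], "-",
                    .one_letter[p$basic_resname[k]], p$basic_res[k]),
      acidic_res = p$acidic_res[k], basic_res = p$basic_res[k],
      acidic_atom = p$acidic_atom[k], basic_atom = p$basic_atom[k],
      occupancy = occ[k],
      occupancy_union = occupancy_pct(union_pres),
      mean_dist = if (length(d)) mean(d) else NA_real_,
      sd_dist = if (length(d) > 1) stats::sd(d) else
        if (length(d) == 1) 0 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$occupancy > 0 | out$occupancy_union > 0, , drop = FALSE]
  out <- out[order(-out$occupancy, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("saltbridge_records", "data.frame")
  out
}

#' Detect hydrophobic contacts across a trajectory
#'
#' A residue pair is in hydrophobic contact in a frame when any pair of
#' designated carbon atoms (backbone C/CA and the side-chain carbons CB, CG,
#' CD, CE, CZ families) across the two residues lies within the cutoff
#' (4 Angstrom default, inclusive). One presence record is kept per residue
#' pair ("without redundancy"); same-residue and sequence-adjacent pairs
#' (|delta resseq| <= 1 on one chain) are excluded, since neighboring
#' backbones are trivially in range.
#'
#' @param traj a \code{trajectory}.
#' @param cutoff Angstrom, inclusive bound (default 4.0).
#' @param restrict_to_hydrophobic only consider residues of the hydrophobic
#'   class (default FALSE: all residues carry the designated carbons).
#' @param method \code{"brute"} or \code{"cell"}; identical results.
#' @return a \code{pair_series} keyed by residue pair, whose \code{pairs}
#'   table records the atom pair with the highest in-range count.
#' @export
detect_hydrophobic_contacts <- function(traj, cutoff = 4.0,
                                        restrict_to_hydrophobic = FALSE,
                                        method = c("brute", "cell")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  topo <- traj$topology
  at <- topo$atoms
  prot <- topo$selections$protein
  carbons <- prot[at$name[prot] %in% .hydrophobic_carbons &
                    at$element[prot] == "C"]
  if (restrict_to_hydrophobic) {
    carbons <- carbons[classify_residue(at$resname[carbons], quiet = TRUE) ==
                         "hydrophobic"]
  }
  nf <- n_frames(traj)
  if (length(carbons) < 2) {
    return(.pair_series("contact",
                        data.frame(res_a = integer(0), res_b = integer(0)),
                        matrix(FALSE, 0, nf), matrix(NA_real_, 0, nf), topo))
  }
  cp <- t(utils::combn(carbons, 2))
  ra <- at$residue_id[cp[, 1]]; rb <- at$residue_id[cp[, 2]]
  res <- topo$residues
  seq_a <- res$resseq[match(ra, res$residue_id)]
  seq_b <- res$resseq[match(rb, res$residue_id)]
  ch_a <- res$chain[match(ra, res$residue_id)]
  ch_b <- res$chain[match(rb, res$residue_id)]
  keep <- ra != rb & !(ch_a == ch_b & abs(seq_a - seq_b) <= 1)
  cp <- cp[keep, , drop = FALSE]
  seq_a <- seq_a[keep]; seq_b <- seq_b[keep]
  # order residue pair canonically
  flip <- seq_a > seq_b
  tmp <- cp[flip, 1]; cp[flip, 1] <- cp[flip, 2]; cp[flip, 2] <- tmp
  s <- pmin(seq_a, seq_b); t <- pmax(seq_a, seq_b)
  rkey <- paste(s, t)
  ukeys <- sort(unique(rkey))
  np <- length(ukeys)
  presence <- matrix(FALSE, np, nf)
  best_atoms <- character(np)
  mindist <- matrix(NA_real_, np, nf)
  for (u in seq_along(ukeys)) {
    rows <- which(rkey == ukeys[u])
    inr <- matrix(FALSE, length(rows), nf)
    dmin <- rep(Inf, nf)
    for (q in seq_along(rows)) {
      d <- .pair_distance_series(traj$coords, cp[rows[q], 1], cp[rows[q], 2])
      inr[q, ] <- d <= cutoff
      dmin <- pmin(dmin, d)
    }
    presence[u, ] <- colSums(inr) > 0
    mindist[u, ] <- dmin
    q_best <- which.max(rowSums(inr))
    best_atoms[u] <- paste(at$name[cp[rows[q_best], 1]],
                           at$name[cp[rows[q_best], 2]], sep = "-")
  }
  if (method == "cell") {
    # recompute presence per frame via cell lists; must agree with the loop
    presence_cell <- matrix(FALSE, np, nf)
    k2 <- paste(pmin(cp[, 1], cp[, 2]), pmax(cp[, 1], cp[, 2]))
    for (f in seq_len(nf)) {
      nb <- neighbor_pairs(frame_coords(traj, f), carbons,
                           cutoff = cutoff, method = "cell")
      if (!nrow(nb)) next
      k1 <- paste(pmin(nb$i, nb$j), pmax(nb$i, nb$j))
      hit <- unique(match(k1, k2))
      hit <- hit[!is.na(hit)]
      presence_cell[match(rkey[hit], ukeys), f] <- TRUE
    }
    presence <- presence_cell
  }
  parts <- strsplit(ukeys, " ")
  res_a <- as.integer(vapply(parts, `[`, character(1), 1))
  res_b <- as.integer(vapply(parts, `[`, character(1), 2))
  name_of <- function(sq) res$resname[match(sq, res$resseq)]
  pairs <- data.frame(
    res_a = res_a, res_b = res_b,
    resname_a = name_of(res_a), resname_b = name_of(res_b),
    atoms = best_atoms,
    stringsAsFactors = FALSE
  )
  .pair_series("contact", pairs, presence, mindist, topo)
}

#' Hydrophobic-contact record table
#'
#' @param ps a contact \code{pair_series}.
#' @return data.frame: \code{pair}, residues, representative atom pair,
#'   \code{occupancy} (percent), sorted by decreasing occupancy; pairs never
#'   in contact are dropped.
#' @export
contact_records <- function(ps) {
  stopifnot(inherits(ps, "pair_series"), ps$type == "contact")
  occ <- occupancy_pct(ps$presence, ps$n_frames)
  p <- ps$pairs
  out <- data.frame(
    pair = paste0(.abbrev_res(p$resname_a), p$res_a, "-",
                  .abbrev_res(p$resname_b), p$res_b),
    res_a = p$res_a, res_b = p$res_b, atoms = p$atoms,
    occupancy = occ, stringsAsFactors = FALSE
  )
  out <- out[out$occupancy > 0, , drop = FALSE]
  out <- out[order(-out$occupancy, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.abbrev_res <- function(resname) {
  ol <- .one_letter[resname]
  ifelse(is.na(ol), resname, ol)
}

#' Monitor the distance between two named atoms
#'
#' Tracks the per-frame distance between two atoms given as (residue number,
#' atom name) and summarizes the fraction of frames at or below a threshold
#' -- the stability summary used for individual hydrogen bonds of interest.
#'
#' @param traj a \code{trajectory}.
#' @param res_a,atom_a first atom: residue sequence number and atom name.
#' @param res_b,atom_b second atom.
#' @param threshold Angstrom (inclusive), default 3.5.
#' @return list of class \code{distance_monitor}: \code{series} (data.frame
#'   frame, time_ns, distance), \code{fraction_below} in [0, 1],
#'   \code{threshold}.
#' @export
monitor_distance <- function(traj, res_a, atom_a, res_b, atom_b,
                             threshold = 3.5) {
  ia <- atom_index(traj$topology, res_a, atom_a)
  ib <- atom_index(traj$topology, res_b, atom_b)
  d <- .pair_distance_series(traj$coords, ia, ib)
  structure(list(
    series = data.frame(frame = seq_along(d) - 1L,
                        time_ns = traj$times / 1000, distance = d),
    fraction_below = mean(d <= threshold),
    threshold = threshold,
    label = paste0(res_a, ":", toupper(atom_a), "-", res_b, ":",
                   toupper(atom_b))
  ), class = "distance_monitor")
}
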