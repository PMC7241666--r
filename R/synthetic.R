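# Idealized per-residue template geometry for the toy peptide builder.
# Coordinates are offsets (Angstrom) from the residue origin; the chain is
# laid out extended along x (3.8 A per residue) with side chains along +y and
# branches split in z, spaced so that geometric bond perception recovers the
# intended connectivity and non-bonded atoms stay > 1.9 A apart.
.bb_template <- data.frame(
  name = c("N", "H", "CA", "C", "O"),
  x = c(0, 0, 1.25, 2.5, 2.5),
  y = c(0, -1.0, 0.5, 0, -1.2),
  z = c(0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

.sc_templates <- list(
  GLY = NULL,
  ALA = rbind(c("CB", 1.25, 2.0, 0)),
  VAL = rbind(c("CB", 1.25, 2.0, 0), c("CG1", 1.25, 3.0, 1.1),
              c("CG2", 1.25, 3.0, -1.1)),
  LEU = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD1", 1.25, 4.5, 1.1), c("CD2", 1.25, 4.5, -1.1)),
  ILE = rbind(c("CB", 1.25, 2.0, 0), c("CG1", 1.25, 3.0, 1.1),
              c("CG2", 1.25, 3.0, -1.1), c("CD1", 1.25, 4.3, 1.4)),
  MET = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("SD", 1.25, 5.0, 0), c("CE", 1.25, 6.5, 0)),
  PRO = rbind(c("CB", 1.25, 2.0, 0), c("CG", 0.5, 3.0, 0),
              c("CD", 0.0, 1.4, 0)),
  PHE = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD1", 1.25, 4.3, 1.1), c("CD2", 1.25, 4.3, -1.1),
              c("CE1", 1.25, 5.6, 1.1), c("CE2", 1.25, 5.6, -1.1),
              c("CZ", 1.25, 6.4, 0)),
  TYR = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD1", 1.25, 4.3, 1.1), c("CD2", 1.25, 4.3, -1.1),
              c("CE1", 1.25, 5.6, 1.1), c("CE2", 1.25, 5.6, -1.1),
              c("CZ", 1.25, 6.4, 0), c("OH", 1.25, 7.75, 0),
              c("HH", 1.25, 8.7, 0)),
  TRP = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD1", 1.25, 4.3, 1.1), c("CD2", 1.25, 4.3, -1.1),
              c("NE1", 1.25, 5.6, 1.1), c("HE1", 1.25, 5.9, 2.0),
              c("CE2", 1.25, 5.6, 0), c("CE3", 1.25, 5.6, -1.1),
              c("CZ2", 1.25, 6.9, 0.6), c("CZ3", 1.25, 6.9, -0.6),
              c("CH2", 1.25, 7.8, 0)),
  SER = rbind(c("CB", 1.25, 2.0, 0), c("OG", 1.25, 3.4, 0),
              c("HG", 1.25, 4.35, 0)),
  THR = rbind(c("CB", 1.25, 2.0, 0), c("OG1", 1.25, 3.0, 1.1),
              c("HG1", 1.25, 3.6, 1.85), c("CG2", 1.25, 3.0, -1.1)),
  CYS = rbind(c("CB", 1.25, 2.0, 0), c("SG", 1.25, 3.8, 0)),
  ASN = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("OD1", 1.25, 4.4, 1.1), c("ND2", 1.25, 4.4, -1.1),
              c("HD21", 1.25, 5.35, -1.3), c("HD22", 1.25, 4.0, -2.0)),
  GLN = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD", 1.25, 5.0, 0), c("OE1", 1.25, 5.9, 1.1),
              c("NE2", 1.25, 5.9, -1.1), c("HE21", 1.25, 6.85, -1.3),
              c("HE22", 1.25, 5.5, -2.0)),
  ASP = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("OD1", 1.25, 4.4, 1.1), c("OD2", 1.25, 4.4, -1.1)),
  GLU = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD", 1.25, 5.0, 0), c("OE1", 1.25, 5.9, 1.1),
              c("OE2", 1.25, 5.9, -1.1)),
  LYS = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD", 1.25, 5.0, 0), c("CE", 1.25, 6.5, 0),
              c("NZ", 1.25, 7.9, 0), c("HZ1", 1.25, 8.5, 0.8),
              c("HZ2", 1.25, 8.5, -0.8), c("HZ3", 1.25, 8.9, 0)),
  ARG = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("CD", 1.25, 5.0, 0), c("NE", 1.25, 6.4, 0),
              c("HE", 1.25, 6.9, 0.85), c("CZ", 1.25, 7.7, 0),
              c("NH1", 1.25, 8.6, 1.1), c("HH11", 1.25, 9.55, 1.3),
              c("HH12", 1.25, 8.2, 2.0), c("NH2", 1.25, 8.6, -1.1),
              c("HH21", 1.25, 9.55, -1.3), c("HH22", 1.25, 8.2, -2.0)),
  HIS = rbind(c("CB", 1.25, 2.0, 0), c("CG", 1.25, 3.5, 0),
              c("ND1", 1.25, 4.4, 1.1), c("CD2", 1.25, 4.4, -1.1),
              c("CE1", 1.25, 5.7, 0.7), c("NE2", 1.25, 5.7, -0.7),
              c("HE2", 1.25, 6.6, -1.0))
)

#' Build an idealized toy peptide topology
#'
#' Constructs an extended-chain peptide with PDB-standard atom names,
#' explicit hydrogens on donor heteroatoms, an optional water shell placed
#' at least 4 Angstrom from the protein, and an optional divalent calcium
#' ion. The internal geometry is idealized (not physical) but spaced so
#' covalent-bond perception, donor enumeration and every detector atom
#' whitelist behave exactly as on real structures.
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param n_waters number of water molecules (default 0).
#' @param include_ion add one Ca2+ ion (default FALSE).
#' @return list with \code{topology} and \code{coords} (reference frame).
#' @export
build_toy_topology <- function(sequence, n_waters = 0, include_ion = FALSE) {
  sequence <- toupper(sequence)
  unknown <- setdiff(sequence, names(.sc_templates))
  if (length(unknown)) stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  rows <- list()
  for (i in seq_along(sequence)) {
    x0 <- 3.8 * (i - 1)
    rn <- sequence[i]
    bb <- .bb_template
    if (rn == "PRO") bb <- bb[bb$name != "H", , drop = FALSE]
    for (k in seq_len(nrow(bb))) {
      rows[[length(rows) + 1L]] <- list(bb$name[k], rn, i, "A",
                                        x0 + bb$x[k], bb$y[k], bb$z[k])
    }
    sc <- .sc_templates[[rn]]
    if (!is.null(sc)) {
      for (k in seq_len(nrow(sc))) {
        rows[[length(rows) + 1L]] <- list(sc[k, 1], rn, i, "A",
                                          x0 + as.numeric(sc[k, 2]),
                                          as.numeric(sc[k, 3]),
                                          as.numeric(sc[k, 4]))
      }
    }
  }
  nres <- length(sequence)
  if (n_waters > 0) {
    for (w in seq_len(n_waters)) {
      ox <- 3.5 * (w - 1)
      oy <- -6.0
      oz <- if (w %% 2 == 0) 3.0 else 0.0
      wr <- nres + w
      rows[[length(rows) + 1L]] <- list("O",  "WAT", wr, "W", ox, oy, oz)
      rows[[length(rows) + 1L]] <- list("H1", "WAT", wr, "W", ox + 0.96, oy, oz)
      rows[[length(rows) + 1L]] <- list("H2", "WAT", wr, "W", ox - 0.32, oy + 0.93, oz)
    }
  }
  if (include_ion) {
    rows[[length(rows) + 1L]] <- list("CA", "CA", nres + n_waters + 1L, "I",
                                      -8.0, -8.0, 8.0)
  }
  atoms <- data.frame(
    serial = seq_along(rows),
    name = vapply(rows, function(r) r[[1]], character(1)),
    resname = vapply(rows, function(r) r[[2]], character(1)),
    resseq = vapply(rows, function(r) r[[3]], numeric(1)),
    chain = vapply(rows, function(r) r[[4]], character(1)),
    stringsAsFactors = FALSE
  )
  coords <- cbind(vapply(rows, function(r) r[[5]], numeric(1)),
                  vapply(rows, function(r) r[[6]], numeric(1)),
                  vapply(rows, function(r) r[[7]], numeric(1)))
  list(topology = build_topology(atoms, coords), coords = coords)
}

#' Interaction schedule constructors
#'
#' A schedule plants one interaction with a designed occupancy: in exactly
#' \code{round(occupancy/100 * n_frames)} frames (chosen by a seeded
#' permutation, so recovery is exact rather than binomial) the mobile
#' partner is placed at \code{in_distance} from its stationary counterpart
#' -- collinear with the donor-hydrogen axis for hydrogen bonds, so the
#' D-H-A angle criterion is met -- and at \code{out_distance} otherwise.
#' Only the mobile tip (partner atom plus its bonded hydrogens, or the whole
#' water molecule) is displaced, leaving all other metrics unperturbed;
#' such frames are diagnostic fixtures, not physical conformations.
#'
#' @param donor_res,donor_atom donor residue number and heavy-atom name.
#' @param acceptor_res,acceptor_atom acceptor identity (the mobile side
#'   unless it is the donor water that moves).
#' @param occupancy designed occupancy, percent in (0, 100].
#' @param in_distance,out_distance placement distances, Angstrom.
#' @param direction unit-ish placement direction for out-of-range parking
#'   (and in-range placement of distance-only schedules); the default +z
#'   points into empty space in the extended-chain layout, keeping parked
#'   atoms clear of unrelated residues.
#' @return a schedule specification list.
#' @name schedules
#' @export
hbond_schedule <- function(donor_res, donor_atom, acceptor_res, acceptor_atom,
                           occupancy, in_distance = 2.9, out_distance = 6.0,
                           direction = c(0, 0, 1)) {
  .check_sched_occ(occupancy)
  list(type = "hbond", donor_res = donor_res, donor_atom = toupper(donor_atom),
       acceptor_res = acceptor_res, acceptor_atom = toupper(acceptor_atom),
       occupancy = occupancy, in_distance = in_distance,
       out_distance = out_distance, direction = direction / sqrt(sum(direction^2)))
}

#' @rdname schedules
#' @param acidic_res,basic_res salt-bridge residue numbers.
#' @param acidic_atom,basic_atom atom names (defaults: first carboxylate
#'   oxygen, first basic nitrogen of the residue type).
#' @export
saltbridge_schedule <- function(acidic_res, basic_res, occupancy,
                                acidic_atom = NULL, basic_atom = NULL,
                                in_distance = 3.2, out_distance = 6.0,
                                direction = c(0, 0, 1)) {
  .check_sched_occ(occupancy)
  list(type = "saltbridge", acidic_res = acidic_res, basic_res = basic_res,
       acidic_atom = acidic_atom, basic_atom = basic_atom,
       occupancy = occupancy, in_distance = in_distance,
       out_distance = out_distance, direction = direction / sqrt(sum(direction^2)))
}

#' @rdname schedules
#' @param res_a,atom_a stationary partner.
#' @param res_b,atom_b mobile partner.
#' @export
contact_schedule <- function(res_a, atom_a, res_b, atom_b, occupancy,
                             in_distance = 3.8, out_distance = 6.0,
                             direction = c(0, 0, 1)) {
  .check_sched_occ(occupancy)
  list(type = "contact", res_a = res_a, atom_a = toupper(atom_a),
       res_b = res_b, atom_b = toupper(atom_b), occupancy = occupancy,
       in_distance = in_distance, out_distance = out_distance,
       direction = direction / sqrt(sum(direction^2)))
}

.check_sched_occ <- function(occ) {
  if (occ <= 0 || occ > 100) stop("schedule occupancy must lie in (0, 100]")
}

.bonded_hydrogens <- function(topology, idx) {
  b <- topology$bonds
  h <- c(b[b[, 1] == idx, 2], b[b[, 2] == idx, 1])
  h[topology$atoms$element[h] == "H"]
}

.resolve_schedule <- function(topology, s) {
  at <- topology$atoms
  water_of <- function(i) {
    rid <- at$residue_id[i]
    which(at$residue_id == rid)
  }
  if (s$type == "hbond") {
    d <- atom_index(topology, s$donor_res, s$donor_atom)
    a <- atom_index(topology, s$acceptor_res, s$acceptor_atom)
    hs <- sort(.bonded_hydrogens(topology, d))
    if (!length(hs)) stop("scheduled donor has no bonded hydrogen")
    h <- hs[1]
    d_water <- at$resname[d] %in% .water_resnames
    a_water <- at$resname[a] %in% .water_resnames
    if (d_water && a_water) stop("water-water schedules are not supported")
    if (d_water) {
      list(kind = "hbond_water_donor", d = d, h = h, a = a,
           mobile = water_of(d), anchor = d,
           stationary = a, s = s)
    } else {
      mobile <- if (a_water) water_of(a) else c(a, .bonded_hydrogens(topology, a))
      list(kind = "hbond", d = d, h = h, a = a, mobile = mobile, anchor = a,
           stationary = c(d, h), s = s)
    }
  } else if (s$type == "saltbridge") {
    arn <- at$resname[at$resseq == s$acidic_res][1]
    brn <- at$resname[at$resseq == s$basic_res][1]
    aatom <- if (is.null(s$acidic_atom)) .acidic_atoms[[arn]][1] else s$acidic_atom
    batom <- if (is.null(s$basic_atom)) .basic_atoms[[brn]][1] else s$basic_atom
    if (is.null(aatom) || is.null(batom)) {
      stop("salt-bridge schedule on non-acidic/basic residues")
    }
    o <- atom_index(topology, s$acidic_res, aatom)
    n <- atom_index(topology, s$basic_res, batom)
    list(kind = "pairdist", o = o, n = n,
         mobile = c(n, .bonded_hydrogens(topology, n)), anchor = n,
         stationary = o, s = s)
  } else {
    a <- atom_index(topology, s$res_a, s$atom_a)
    b <- atom_index(topology, s$res_b, s$atom_b)
    list(kind = "pairdist", o = a, n = b,
         mobile = c(b, .bonded_hydrogens(topology, b)), anchor = b,
         stationary = a, s = s)
  }
}

#' Generate a synthetic trajectory with designed ground truth
#'
#' Frames are the reference coordinates plus independent isotropic Gaussian
#' jitter per atom (standard deviation set per residue), optionally with
#' planted interaction schedules applied on top (see
#' \code{\link{hbond_schedule}}). With \code{exact_schedule = TRUE} the
#' in-range frames of each schedule are an exact-count seeded permutation,
#' so a detector recovers the designed occupancy exactly; the Bernoulli
#' alternative draws each frame independently for stress testing.
#'
#' @param topo list with \code{topology} and \code{coords} as returned by
#'   \code{\link{build_toy_topology}}.
#' @param n_frames frame count (default 2000).
#' @param sigma per-residue jitter standard deviation, Angstrom: scalar or a
#'   vector of length \code{nrow(topology$residues)}.
#' @param schedules list of schedule specifications.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param time_step ps between frames (default 10).
#' @param condition condition label.
#' @param exact_schedule exact-count (TRUE) or Bernoulli (FALSE) scheduling.
#' @return list with \code{trajectory} and \code{ground_truth} (designed
#'   sigma per residue, schedule table with designed occupancies and
#'   realized in-frame counts, seed).
#' @export
synthetic_trajectory <- function(topo, n_frames = 2000, sigma = 0.25,
                                 schedules = list(), seed = 1,
                                 time_step = 10, condition = "",
                                 exact_schedule = TRUE) {
  topology <- topo$topology
  ref <- topo$coords
  na <- nrow(topology$atoms)
  nres <- nrow(topology$residues)
  if (length(sigma) == 1) sigma <- rep(sigma, nres)
  if (length(sigma) != nres) stop("sigma must be scalar or one value per residue")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  set.seed(seed)
  atom_sigma <- sigma[topology$atoms$residue_id]
  noise <- array(stats::rnorm(na * 3 * n_frames), dim = c(na, 3, n_frames)) *
    array(atom_sigma, dim = c(na, 3, n_frames))
  coords <- array(rep(ref, n_frames), dim = c(na, 3, n_frames)) + noise
  resolved <- lapply(schedules, .resolve_schedule, topology = topology)
  if (length(resolved) > 1) {
    mob <- lapply(resolved, `[[`, "mobile")
    stat <- lapply(resolved, function(r) r$stationary)
    allmob <- unlist(mob)
    if (anyDuplicated(allmob)) stop("conflicting schedules share a mobile atom")
    if (length(intersect(allmob, unlist(stat)))) {
      stop("a schedule's stationary atom is mobile in another schedule")
    }
  }
  sched_rows <- list()
  for (si in seq_along(resolved)) {
    r <- resolved[[si]]
    s <- r$s
    n_in <- round(s$occupancy / 100 * n_frames)
    in_frames <- if (exact_schedule) {
      sort(sample.int(n_frames)[seq_len(n_in)])
    } else {
      which(stats::runif(n_frames) < s$occupancy / 100)
    }
    in_mask <- rep(FALSE, n_frames)
    in_mask[in_frames] <- TRUE
    for (f in seq_len(n_frames)) {
      dist <- if (in_mask[f]) s$in_distance else s$out_distance
      co <- coords[, , f]
      if (r$kind == "hbond") {
        # in range: collinear with the (jittered) donor-hydrogen axis so the
        # angle criterion holds exactly; out of range: park along `direction`
        u <- if (in_mask[f]) {
          v <- co[r$h, ] - co[r$d, ]
          v / sqrt(sum(v^2))
        } else s$direction
        target <- co[r$d, ] + dist * u
        delta <- target - co[r$anchor, ]
      } else if (r$kind == "hbond_water_donor") {
        if (in_mask[f]) {
          v <- co[r$h, ] - co[r$d, ]
          v <- v / sqrt(sum(v^2))
          target <- co[r$a, ] - dist * v
        } else {
          target <- co[r$a, ] + dist * s$direction
        }
        delta <- target - co[r$anchor, ]
      } else {  # pairdist: salt bridge or contact; only distance matters
        target <- co[r$o, ] + dist * s$direction
        delta <- target - co[r$anchor, ]
      }
      coords[r$mobile, , f] <- sweep(co[r$mobile, , drop = FALSE], 2, -delta)
    }
    sched_rows[[si]] <- data.frame(
      id = si, type = s$type, occupancy = s$occupancy,
      n_in = length(in_frames),
      realized_occupancy = 100 * length(in_frames) / n_frames
    )
  }
  traj <- trajectory(topology, coords,
                     times = (seq_len(n_frames) - 1) * time_step,
                     condition = condition)
  gt <- list(
    sigma_per_residue = data.frame(resseq = topology$residues$resseq,
                                   sigma = sigma),
    schedules = if (length(sched_rows)) do.call(rbind, sched_rows)
                else data.frame(),
    seed = seed, n_frames = n_frames
  )
  list(trajectory = traj, ground_truth = gt)
}

#' Default multi-condition study layout
#'
#' Six conditions mirroring a three-temperature design with and without the
#' structural divalent ion. The jitter scale factor grows with temperature
#' (1.0, 1.2, 1.5) and losing the ion multiplies it by 1.2, emulating the
#' destabilization the full analysis is designed to detect.
#'
#' @return data.frame: \code{label}, \code{temp_factor}, \code{with_ion},
#'   \code{factor} (the final sigma multiplier).
#' @export
synthetic_conditions <- function() {
  base <- data.frame(
    label = c("298K", "318K", "343K", "298K_noCa", "318K_noCa", "343K_noCa"),
    temp_factor = rep(c(1.0, 1.2, 1.5), 2),
    with_ion = rep(c(TRUE, FALSE), each = 3),
    stringsAsFactors = FALSE
  )
  base$factor <- base$temp_factor * ifelse(base$with_ion, 1.0, 1.2)
  base
}

#' Default synthetic study specification
#'
#' A 16-residue peptide containing acidic, basic, polar, aromatic and
#' hydrophobic residues, a 6-water shell, 2000 frames at 10 ps, baseline
#' jitter 0.25 Angstrom, and a set of planted interactions spanning the
#' designed occupancies 5, 25, 55, 75 and 95 percent, plus two salt bridges
#' whose occupancy trajectories across the temperature series exercise the
#' differential classifier (one weakening, one comparable) and two
#' hydrophobic contacts.
#'
#' @param n_frames frames per condition (default 2000).
#' @param base_sigma baseline per-residue jitter, Angstrom.
#' @param seed integer seed; per-condition seeds derive from it.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_frames = 2000, base_sigma = 0.25, seed = 1) {
  sequence <- c("MET", "GLY", "ASP", "ALA", "LEU", "SER", "ARG", "VAL",
                "GLU", "ILE", "LYS", "THR", "ASN", "PHE", "HIS", "TRP")
  # per-condition occupancy tables for the two designed salt bridges
  sb_occ <- list(
    weakening  = c(`298K` = 95, `318K` = 85, `343K` = 65,
                   `298K_noCa` = 85, `318K_noCa` = 75, `343K_noCa` = 55),
    comparable = c(`298K` = 90, `318K` = 88, `343K` = 86,
                   `298K_noCa` = 88, `318K_noCa` = 86, `343K_noCa` = 84)
  )
  structure(list(
    sequence = sequence, n_waters = 6, n_frames = n_frames,
    base_sigma = base_sigma, seed = seed,
    conditions = synthetic_conditions(),
    hb_occupancies = c(95, 75, 55, 25, 5),
    sb_occ = sb_occ
  ), class = "synthetic_spec")
}

.study_schedules <- function(spec, label) {
  hb <- spec$hb_occupancies
  list(
    hbond_schedule(15, "NE2", 9, "OE1", hb[1]),        # HIS -> GLU, SS
    hbond_schedule(13, "ND2", 9, "OE2", hb[2]),        # ASN -> GLU, SS
    hbond_schedule(6, "OG", 13, "OD1", hb[3]),         # SER -> ASN, phi-phi
    hbond_schedule(2, "N", 14, "O", hb[4]),            # GLY -> PHE, MM
    hbond_schedule(16, "NE1", 17, "O", hb[5]),         # TRP -> water
    hbond_schedule(18, "O", 12, "OG1", 60),            # water -> THR
    saltbridge_schedule(3, 7, spec$sb_occ$weakening[[label]],
                        acidic_atom = "OD1", basic_atom = "NH1"),
    saltbridge_schedule(3, 11, spec$sb_occ$comparable[[label]],
                        acidic_atom = "OD2", basic_atom = "NZ",
                        direction = c(0, 0, -1)),
    contact_schedule(5, "CD1", 10, "CD1", 85),
    contact_schedule(8, "CG1", 14, "CZ", 8)
  )
}

#' Generate the full multi-condition synthetic study
#'
#' Builds one toy system per condition (the ion present only in the
#' with-ion conditions) and generates its trajectory with the
#' condition's jitter factor and the planted schedules.
#'
#' @param spec a \code{synthetic_spec}.
#' @return named list (by condition label) of
#'   \code{list(trajectory, ground_truth)} entries.
#' @export
synthetic_study <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- list()
  for (k in seq_len(nrow(spec$conditions))) {
    cond <- spec$conditions[k, ]
    topo <- build_toy_topology(spec$sequence, n_waters = spec$n_waters,
                               include_ion = cond$with_ion)
    sched <- .study_schedules(spec, cond$label)
    out[[cond$label]] <- synthetic_trajectory(
      topo, n_frames = spec$n_frames,
      sigma = spec$base_sigma * cond$factor,
      schedules = sched, seed = spec$seed + k,
      condition = cond$label
    )
  }
  out
}
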