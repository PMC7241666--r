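#' Build a topology from an atom table
#'
#' A \code{topology} is the static description of the system: an ordered atom
#' table, the residue structure, covalent bonds perceived from the reference
#' coordinates, and the named selections (protein, backbone, side chain,
#' water, ions) every downstream analysis uses.
#'
#' Bonds are perceived geometrically from the reference frame: each hydrogen
#' is bonded to the nearest heavy atom of its own residue within 1.3 Angstrom;
#' heavy-atom pairs within one residue bond below 1.9 Angstrom, as do
#' backbone C--N pairs of consecutive residues. This handles both standard
#' and modified residues uniformly without residue templates.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{resname}, \code{resseq}, \code{chain}; optional \code{element}
#'   (inferred from names when absent).
#' @param coords numeric matrix (n_atoms x 3) of reference coordinates in
#'   Angstrom, used for bond perception.
#' @return object of class \code{topology}: list with \code{atoms} (the table
#'   augmented with \code{element}, \code{mass}, \code{vdw}), \code{residues},
#'   \code{bonds} (2-column index matrix) and \code{selections}.
#' @export
build_topology <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3) {
    stop("coords must be an n_atoms x 3 matrix matching the atom table")
  }
  if (!all(is.finite(coords))) stop("non-finite reference coordinates")
  atoms$name    <- toupper(atoms$name)
  atoms$resname <- toupper(atoms$resname)
  if (is.null(atoms$element)) {
    atoms$element <- guess_element(atoms$name, atoms$resname)
  }
  atoms$element <- toupper(atoms$element)
  atoms$mass <- atomic_mass(atoms$element)
  atoms$vdw  <- vdw_radius(atoms$element)
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  key <- paste(atoms$chain, atoms$resseq, atoms$name)
  if (anyDuplicated(key)) stop("duplicate (chain, resseq, name) atom identity")

  # residue id advances whenever (chain, resseq, resname) changes
  rkey <- paste(atoms$chain, atoms$resseq, atoms$resname)
  rid <- cumsum(c(TRUE, rkey[-1] != rkey[-length(rkey)]))
  atoms$residue_id <- rid
  first <- tapply(seq_len(nrow(atoms)), rid, min)
  residues <- data.frame(
    residue_id = as.integer(names(first)),
    resname = atoms$resname[first],
    resseq  = atoms$resseq[first],
    chain   = atoms$chain[first],
    first   = as.integer(first),
    last    = as.integer(tapply(seq_len(nrow(atoms)), rid, max)),
    stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$residue_id), , drop = FALSE]
  rownames(residues) <- NULL

  topo <- structure(
    list(atoms = atoms, residues = residues, bonds = NULL, selections = NULL,
         ref_coords = coords),
    class = "topology"
  )
  topo$bonds <- .perceive_bonds(topo, coords)
  topo$selections <- build_selections(topo)
  topo
}

.perceive_bonds <- function(topo, coords) {
  atoms <- topo$atoms
  n <- nrow(atoms)
  is_h <- atoms$element == "H"
  out <- vector("list", nrow(topo$residues) + 1L)
  for (k in seq_len(nrow(topo$residues))) {
    idx <- topo$residues$first[k]:topo$residues$last[k]
    hh <- idx[is_h[idx]]
    heavy <- idx[!is_h[idx]]
    b <- NULL
    if (length(hh) && length(heavy)) {
      for (h in hh) {
        d2 <- colSums((t(coords[heavy, , drop = FALSE]) - coords[h, ])^2)
        j <- heavy[which.min(d2)]
        if (min(d2) <= 1.3^2) b <- rbind(b, c(j, h))
      }
    }
    if (length(heavy) > 1) {
      prs <- utils::combn(heavy, 2)
      d2 <- rowSums((coords[prs[1, ], , drop = FALSE] -
                       coords[prs[2, ], , drop = FALSE])^2)
      keep <- d2 <= 1.9^2
      if (any(keep)) b <- rbind(b, t(prs[, keep, drop = FALSE]))
    }
    out[[k]] <- b
  }
  # inter-residue peptide bonds: C(i) -- N(i+1), same chain, consecutive resseq
  res <- topo$residues
  pep <- NULL
  if (nrow(res) > 1) {
    for (k in seq_len(nrow(res) - 1L)) {
      if (res$chain[k] != res$chain[k + 1L]) next
      ci <- which(atoms$residue_id == res$residue_id[k] & atoms$name == "C")
      ni <- which(atoms$residue_id == res$residue_id[k + 1L] & atoms$name == "N")
      if (length(ci) == 1 && length(ni) == 1 &&
          sum((coords[ci, ] - coords[ni, ])^2) <= 1.9^2) {
        pep <- rbind(pep, c(ci, ni))
      }
    }
  }
  out[[length(out)]] <- pep
  bonds <- do.call(rbind, out)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("a", "b")
  bonds
}

#' Compute the named atom selections of a topology
#'
#' Selections: \code{protein} (everything that is not water or a monoatomic
#' ion), \code{backbone} (the four heavy atoms named N, CA, C, O in protein
#' residues), \code{side_chain} (protein minus backbone, so hydrogens and OXT
#' land here), \code{water} (residues WAT/HOH) and \code{ions}.
#'
#' @param topology a \code{topology}.
#' @return named list of integer atom-index vectors. The backbone and side
#'   chain sets partition the protein set.
#' @export
build_selections <- function(topology) {
  atoms <- topology$atoms
  water <- which(atoms$resname %in% .water_resnames)
  ions  <- which(atoms$resname %in% .ion_resnames)
  protein <- setdiff(seq_len(nrow(atoms)), c(water, ions))
  if (length(protein) == 0) stop("empty protein selection")
  bb_names <- c("N", "CA", "C", "O")
  backbone <- protein[atoms$name[protein] %in% bb_names]
  side_chain <- setdiff(protein, backbone)
  list(protein = protein, backbone = backbone, side_chain = side_chain,
       water = water, ions = ions)
}

#' Resolve a selection argument to atom indices
#'
#' @param topology a \code{topology}.
#' @param selection either a character scalar naming a stored selection
#'   ("protein", "backbone", "side_chain", "water", "ions"), or an integer
#'   vector of atom indices.
#' @return integer vector of atom indices.
#' @export
resolve_selection <- function(topology, selection) {
  if (is.character(selection)) {
    if (length(selection) != 1 || !selection %in% names(topology$selections)) {
      stop("unknown selection name: ", paste(selection, collapse = ", "))
    }
    return(topology$selections[[selection]])
  }
  idx <- as.integer(selection)
  if (any(idx < 1 | idx > nrow(topology$atoms))) stop("selection index out of range")
  idx
}

#' Look up an atom index by residue number and atom name
#' @param topology a \code{topology}.
#' @param resseq residue sequence number.
#' @param name atom name.
#' @return integer atom index (scalar).
#' @export
atom_index <- function(topology, resseq, name) {
  i <- which(topology$atoms$resseq == resseq & topology$atoms$name == toupper(name))
  if (length(i) != 1) {
    stop("atom not found (or ambiguous): residue ", resseq, " atom ", name)
  }
  i
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms, ", nrow(x$residues), " residues (",
      length(x$selections$protein), " protein atoms, ",
      length(x$selections$water), " water atoms, ",
      length(x$selections$ions), " ions)\n", sep = "")
  invisible(x)
}

#' Construct a trajectory object
#'
#' @param topology a \code{topology}.
#' @param coords numeric array n_atoms x 3 x n_frames.
#' @param times frame times in ps (default: 10 ps per frame, matching a
#'   typical coordinate-save interval).
#' @param condition free-text condition label (e.g. "298K", "343K_noCa").
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(topology, coords, times = NULL, condition = "") {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords)) == 2) coords <- array(coords, dim = c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology$atoms)) {
    stop("coordinate array does not match topology atom count")
  }
  if (dim(coords)[3] < 1) stop("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (is.null(times)) times <- (seq_len(dim(coords)[3]) - 1) * 10
  if (length(times) != dim(coords)[3] || any(diff(times) <= 0)) {
    stop("frame times must match frame count and increase strictly")
  }
  structure(list(topology = topology, coords = coords, times = times,
                 condition = condition),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", dim(x$coords)[1], " atoms",
      if (nzchar(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates
#' @param traj a \code{trajectory}.
#' @param i frame index (1-based).
#' @return n_atoms x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]
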