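#' Read a PDB structure into a topology and reference frame
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d), applies the
#' alternate-location policy (keep blank or 'A' altLocs, warn when others are
#' dropped), infers missing element symbols from atom names, and builds the
#' topology with its bonds and selections. When the file holds several
#' MODELs, only the first model's coordinates become the reference frame.
#'
#' @param path PDB file path.
#' @return list with components \code{topology} and \code{coords}
#'   (n_atoms x 3 reference coordinates, Angstrom).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " alternate-location records (keeping 'A'/blank)")
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  missing_e <- is.na(elem) | !nzchar(trimws(elem))
  elem[missing_e] <- guess_element(at$elety[missing_e], at$resid[missing_e])
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = trimws(elem),
    resname = at$resid,
    resseq = at$resno,
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  coords <- cbind(at$x, at$y, at$z)
  topo <- build_topology(atoms, coords)
  list(topology = topo, coords = coords)
}

#' Trajectory file specification
#'
#' @param path file path.
#' @param format \code{"pdb_multimodel"} or \code{"xyz_frames"}.
#' @param stride keep every \code{stride}-th frame (default 1).
#' @param time_step ps between saved frames before striding (default 10 ps,
#'   a common coordinate-save interval).
#' @return list of class \code{trajectory_file_spec}.
#' @export
trajectory_file_spec <- function(path, format = c("pdb_multimodel", "xyz_frames"),
                                 stride = 1L, time_step = 10) {
  format <- match.arg(format)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (time_step <= 0) stop("time_step must be positive")
  structure(list(path = path, format = format, stride = stride,
                 time_step = time_step),
            class = "trajectory_file_spec")
}

#' Read a coordinate trajectory
#'
#' Supported formats: multi-model PDB (one MODEL per frame, atom order
#' matching the topology) and the plain-text \code{xyz_frames} dialect: a
#' header line \code{"natoms nframes"}, then per frame one comment line
#' followed by \code{natoms} lines of \code{"x y z"} in topology atom order.
#' Frame times are \code{index * stride * time_step} ps.
#'
#' @param spec a \code{trajectory_file_spec} (or a path, taken as
#'   pdb_multimodel with defaults).
#' @param topology the \code{topology} the frames belong to.
#' @param condition condition label stored on the trajectory.
#' @return a \code{trajectory}.
#' @export
read_trajectory <- function(spec, topology, condition = "") {
  if (is.character(spec)) spec <- trajectory_file_spec(spec)
  stopifnot(inherits(spec, "trajectory_file_spec"))
  if (!file.exists(spec$path)) stop("no such file: ", spec$path)
  n_atoms <- nrow(topology$atoms)
  coords <- switch(spec$format,
    pdb_multimodel = {
      pdb <- bio3d::read.pdb(spec$path, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (ncol(xyz) != 3 * n_atoms) {
        stop("frame atom count (", ncol(xyz) / 3,
             ") does not match topology (", n_atoms, ") at frame 0")
      }
      arr <- array(NA_real_, dim = c(n_atoms, 3, nrow(xyz)))
      for (f in seq_len(nrow(xyz))) {
        arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      }
      arr
    },
    xyz_frames = .read_xyz_frames(spec$path, n_atoms)
  )
  nf <- dim(coords)[3]
  keep <- seq(1L, nf, by = spec$stride)
  coords <- coords[, , keep, drop = FALSE]
  times <- (keep - 1L) * spec$time_step
  trajectory(topology, coords, times = times, condition = condition)
}

.read_xyz_frames <- function(path, n_atoms) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) < 2) stop("malformed xyz_frames header in ", path)
  na_file <- as.integer(header[1]); nf <- as.integer(header[2])
  if (na_file != n_atoms) {
    stop("frame atom count (", na_file, ") does not match topology (",
         n_atoms, ") at frame 0")
  }
  arr <- array(NA_real_, dim = c(n_atoms, 3, nf))
  pos <- 2L
  for (f in seq_len(nf)) {
    pos <- pos + 1L  # skip the per-frame comment line
    block <- lines[pos:(pos + n_atoms - 1L)]
    if (length(block) != n_atoms || anyNA(block)) {
      stop("truncated coordinates at frame ", f - 1L)
    }
    vals <- as.numeric(unlist(strsplit(trimws(block), "\\s+")))
    if (length(vals) != 3 * n_atoms || anyNA(vals)) {
      stop("truncated coordinates at frame ", f - 1L)
    }
    arr[, , f] <- matrix(vals, ncol = 3, byrow = TRUE)
    pos <- pos + n_atoms
  }
  arr
}

#' Write a trajectory in the xyz_frames dialect
#'
#' @param traj a \code{trajectory}.
#' @param path output path.
#' @param digits coordinate decimals (default 3, PDB-equivalent precision).
#' @return invisibly, the path.
#' @export
write_xyz_frames <- function(traj, path, digits = 3) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(na, nf), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("# frame %d time_ps %s", f - 1L,
                       format(traj$times[f], trim = TRUE)), con)
    m <- format(round(traj$coords[, , f], digits), nsmall = digits, trim = TRUE)
    writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Write a topology + trajectory as (multi-model) PDB
#'
#' @param topology a \code{topology}.
#' @param coords n x 3 matrix or n x 3 x nf array.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb_frames <- function(topology, coords, path) {
  at <- topology$atoms
  if (length(dim(coords)) == 2) coords <- array(coords, dim = c(dim(coords), 1))
  xyz <- t(apply(coords, 3, function(m) as.numeric(t(m))))
  if (dim(coords)[3] == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = ifelse(at$resname %in% c(.water_resnames, .ion_resnames),
                                 "HETATM", "ATOM"),
                   resno = at$resseq, resid = at$resname, eleno = at$serial,
                   elety = at$name, chain = at$chain, elesy = at$element)
  invisible(path)
}

#' Write a result table to CSV or JSON
#'
#' CSV output carries a header row, formats floating-point columns at 4
#' decimals, and preserves the row order given (tables produced by the
#' pipeline are pre-sorted on their documented keys, so output is
#' deterministic).
#'
#' @param records data.frame of homogeneous records (may have zero rows).
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return invisibly, the path.
#' @export
write_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "csv") {
    out <- records
    for (cn in names(out)) {
      if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
        out[[cn]] <- formatC(out[[cn]], digits = 4, format = "f")
      }
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
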