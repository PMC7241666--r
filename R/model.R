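#' Residue chemistry classes
#'
#' Chemical classification of the 20 standard amino acids used throughout the
#' interaction bookkeeping: charged (Arg, Lys, Asp, Glu), polar (Gln, Asn,
#' Ser, Thr, Tyr, Cys) and hydrophobic (Ala, Ile, Leu, Phe, Val, Pro, Gly,
#' Met, Trp). Histidine and any residue not in these lists fall into
#' \code{"other"}. For surface-area partitioning, "hydrophilic" means every
#' protein residue that is not hydrophobic, so the hydrophobic + hydrophilic
#' split covers the whole protein.
#'
#' @name residue-classes
#' @keywords internal
NULL

.residue_class_table <- local({
  charged     <- c("ARG", "LYS", "ASP", "GLU")
  polar       <- c("GLN", "ASN", "SER", "THR", "TYR", "CYS")
  hydrophobic <- c("ALA", "ILE", "LEU", "PHE", "VAL", "PRO", "GLY", "MET", "TRP")
  stats::setNames(
    c(rep("charged", length(charged)),
      rep("polar", length(polar)),
      rep("hydrophobic", length(hydrophobic))),
    c(charged, polar, hydrophobic)
  )
})

.water_resnames <- c("WAT", "HOH")
.ion_resnames   <- c("NA", "CA", "MG", "ZN", "CL", "K")

#' Classify residues by chemical character
#'
#' @param resname character vector of 3-letter residue codes (case-insensitive).
#' @param quiet suppress the warning emitted for unrecognized residue names.
#' @return character vector with values \code{"charged"}, \code{"polar"},
#'   \code{"hydrophobic"} or \code{"other"}. Unknown names (e.g. modified
#'   residues) classify as \code{"other"} with a warning rather than an error,
#'   so nonstandard residues never abort a run.
#' @examples
#' classify_residue(c("ARG", "GLY", "HIS"))
#' @export
classify_residue <- function(resname, quiet = FALSE) {
  resname <- toupper(resname)
  out <- unname(.residue_class_table[resname])
  unknown <- is.na(out) &
    !(resname %in% names(.residue_class_table)) &
    !(resname %in% c("HIS", .water_resnames, .ion_resnames))
  if (any(unknown) && !quiet) {
    warning("unrecognized residue name(s) classified as 'other': ",
            paste(unique(resname[unknown]), collapse = ", "))
  }
  out[is.na(out)] <- "other"
  out
}

#' Is a residue hydrophilic (surface-area convention)?
#'
#' Hydrophilic is defined as "protein residue that is not hydrophobic", so
#' that hydrophobic and hydrophilic areas add up to the total protein area.
#'
#' @param resname character vector of 3-letter codes.
#' @return logical vector.
#' @export
is_hydrophilic <- function(resname) {
  classify_residue(resname, quiet = TRUE) != "hydrophobic"
}

#' Default catalytic residue set
#'
#' The catalytic machinery of the target debranching enzyme: the nucleophile
#' (Asp473), the general acid/base (Glu510) and the transition-state
#' stabilizer (Asp642). Overridable wherever a catalytic set is accepted.
#'
#' @return integer vector of residue sequence numbers.
#' @export
default_catalytic_set <- function() c(473L, 510L, 642L)

# Bondi van der Waals radii (Angstrom) by element; 1.7 fallback for unknowns.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39)

.mass_table <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
                 "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38)

#' Van der Waals radius lookup
#' @param element character vector of element symbols.
#' @param fallback radius used for elements absent from the table (Angstrom).
#' @return numeric vector of radii in Angstrom (Bondi set).
#' @export
vdw_radius <- function(element, fallback = 1.7) {
  r <- unname(.vdw_table[toupper(element)])
  r[is.na(r)] <- fallback
  r
}

#' Atomic mass lookup
#' @param element character vector of element symbols.
#' @param fallback mass used for unknown elements (amu).
#' @return numeric vector of masses in amu.
#' @export
atomic_mass <- function(element, fallback = 12.011) {
  m <- unname(.mass_table[toupper(element)])
  m[is.na(m)] <- fallback
  m
}

#' Infer element symbols from atom names
#'
#' PDB files in the wild often lack the element column. The first alphabetic
#' character of the digit-stripped atom name is used, except for monoatomic
#' ions, where the residue name identifies a two-letter element (NA, CA, MG,
#' ZN, CL, K as HETATM residues).
#'
#' @param name atom name vector (e.g. "CA", "OD1", "1HB").
#' @param resname residue name vector, same length; used to spot ions.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name, resname = NULL) {
  stripped <- gsub("[0-9']", "", name)
  elem <- toupper(substr(stripped, 1, 1))
  if (!is.null(resname)) {
    ion <- toupper(resname) %in% .ion_resnames & toupper(name) == toupper(resname)
    elem[ion] <- toupper(resname[ion])
  }
  elem
}
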