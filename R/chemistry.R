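# Element and residue property tables used throughout the surface and
# contact calculations. Radii are Bondi van der Waals radii (A); masses in
# unified atomic mass units; hydrophobicities on the Eisenberg consensus
# scale (positive = hydrophobic).

.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971
)

.eisenberg_scale <- c(
  ALA = 0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90, CYS = 0.29,
  GLN = -0.85, GLU = -0.74, GLY = 0.48, HIS = -0.40, ILE = 1.38,
  LEU = 1.06, LYS = -1.50, MET = 0.64, PHE = 1.19, PRO = 0.12,
  SER = -0.18, THR = -0.05, TRP = 0.81, TYR = 0.26, VAL = 1.08
)

#' Van der Waals radii for element symbols
#'
#' @param elements Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @keywords internal
vdw_radius <- function(elements) {
  key <- toupper(elements)
  unknown <- unique(key[!key %in% names(.vdw_radii)])
  if (length(unknown) > 0) {
    stop_vhh("no van der Waals radius for element(s): ",
             paste(unknown, collapse = ", "))
  }
  unname(.vdw_radii[key])
}

atomic_mass <- function(elements) {
  key <- toupper(elements)
  unknown <- unique(key[!key %in% names(.atomic_masses)])
  if (length(unknown) > 0) {
    stop_vhh("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  }
  unname(.atomic_masses[key])
}

#' Eisenberg consensus hydrophobicity of residue types
#'
#' @param resnames Character vector of three-letter residue codes.
#' @return Numeric vector; `NA` for residue types not on the scale.
#' @export
#' @examples
#' eisenberg_score(c("LEU", "ASP"))
eisenberg_score <- function(resnames) {
  out <- .eisenberg_scale[toupper(resnames)]
  names(out) <- resnames
  out
}

guess_element <- function(elety) {
  # PDB atom names put the element in columns 13-14; after whitespace
  # stripping the element is the leading alphabetic part minus any
  # remoteness/digit suffix (e.g. "CA" -> C for standard amino-acid atoms).
  nm <- toupper(gsub("[^A-Z]", "", toupper(elety)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "SE") , two, one)
}
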