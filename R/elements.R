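#' Van der Waals radii (Bondi-type) by element symbol
#'
#' Radii in Angstrom for the elements that occur in protein/membrane/water
#' systems. Elements missing from the table fall back to 1.70 Angstrom
#' (carbon) with a warning, since trajectory formats do not carry radii.
#'
#' @format Named numeric vector, Angstrom.
#' @keywords internal
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  NA_ = 2.27, K = 2.75, MG = 1.73, CA_ = 2.31, ZN = 1.39, FE = 2.00
)

#' Look up van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param default radius used for unknown elements (Angstrom).
#' @return numeric vector of radii, Angstrom.
#' @export
vdw_radius_of <- function(element, default = 1.70) {
  key <- toupper(trimws(element))
  # metals whose symbols clash with R reserved-ish names in the table
  key[key == "NA"] <- "NA_"
  key[key == "CA"] <- "CA_"
  r <- unname(.vdw_table[key])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using default vdW radius ", default, " A")
    r[unknown] <- default
  }
  r
}

#' Guess the element symbol from a PDB atom name
#'
#' Strips digits and primes, then takes the leading letter; two-letter
#' halogens/metals common in simulations (CL, NA, MG, ZN, FE, BR) are
#' recognized by full prefix.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", trimws(name)))
  two <- c("CL", "BR", "ZN", "FE", "MG")
  out <- substr(nm, 1, 1)
  hit <- substr(nm, 1, 2) %in% two
  out[hit] <- substr(nm[hit], 1, 2)
  out
}

#' Water residue names recognized by the pipeline
#'
#' @param resname character vector of residue names.
#' @return logical vector.
#' @export
is_water <- function(resname) {
  toupper(trimws(resname)) %in% c("TIP3", "TIP3P", "TIP", "HOH", "WAT", "SPC", "SOL")
}
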