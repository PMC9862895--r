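# Built-in element tables: van der Waals radii (Angstrom, Bondi-style values
# common in docking descriptors) and single-bond covalent radii used for
# distance-based bond perception in ligands.

.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, B = 1.92, SE = 1.90,
  MG = 1.73, ZN = 1.39, MN = 1.39, CA = 1.97, FE = 1.94,
  "NA" = 2.27, K = 2.75, CU = 1.40, NI = 1.63, CO = 1.53, CD = 1.58
)

.cov_table <- c(
  H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.03, P = 1.06,
  F = 0.71, CL = 0.99, BR = 1.14, I = 1.33, B = 0.82, SE = 1.16
)

#' Van der Waals radius of an element
#'
#' Values come from a fixed built-in table; elements not in the table get
#' the carbon radius so that every atom still contributes excluded volume.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdw_table[el]
  r[is.na(r)] <- .vdw_table[["C"]]
  unname(r)
}

cov_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .cov_table[el]
  r[is.na(r)] <- 1.2
  unname(r)
}

.metal_elements <- c("MG", "ZN", "MN", "CA", "FE")

# infer an element symbol from a PDB atom name when the element column is
# blank: strip digits, take the leading alphabetic part, prefer two-letter
# matches for known elements
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  vapply(nm, function(s) {
    if (nchar(s) == 0) return("C")
    two <- substr(s, 1, 2)
    if (two %in% names(.vdw_table) && !substr(s, 1, 1) %in% c("C", "N", "O", "S", "P", "H")) {
      return(two)
    }
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}
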