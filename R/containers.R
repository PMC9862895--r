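#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup n across left_join row_number desc
#' @importFrom purrr map map_dbl map_int map_lgl map_chr keep imap
#' @importFrom rlang abort warn .data
#' @importFrom stats quantile sd rnorm runif setNames predict
#' @importFrom utils head tail
NULL

#' Construct a ligand object
#'
#' A ligand is one hetero group: its component identifier and an atom table.
#' The heavy-atom count is derived from the table, never passed in.
#'
#' @param het_id Residue/component identifier (e.g. `"ATP"`).
#' @param atoms Tibble with columns `name`, `element`, `x`, `y`, `z`,
#'   `is_heavy`, `vdw_radius`.
#' @param resno Residue number of the group in its source file.
#' @param source_chain Chain label the group carried in the source file.
#' @return An object of class `ligand`.
#' @export
new_ligand <- function(het_id, atoms, resno = NA_integer_, source_chain = NA_character_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  structure(
    list(
      het_id = het_id,
      resno = resno,
      source_chain = source_chain,
      atoms = as_tibble(atoms),
      heavy_atom_count = sum(atoms$is_heavy)
    ),
    class = "ligand"
  )
}

#' Construct a chain entry
#'
#' The unit of all processing: one polymer chain with its one-letter sequence
#' (one letter per C-alpha-bearing residue), full atom table, C-alpha
#' coordinates and attached ligands.
#'
#' @param structure_id Structure identifier (PDB id or file stem).
#' @param chain_id Single-character chain label.
#' @param sequence Amino-acid one-letter string.
#' @param atoms Tibble of the chain's atoms (columns as in [new_ligand()],
#'   plus `resid`, `resno`, `insert`).
#' @param ca_coords Numeric matrix, one row per residue with a C-alpha.
#' @param ligands List of [new_ligand()] objects.
#' @return An object of class `chain_entry`.
#' @export
new_chain_entry <- function(structure_id, chain_id, sequence, atoms, ca_coords,
                            ligands = list()) {
  stopifnot(nchar(sequence) >= 1, nrow(ca_coords) == nchar(sequence))
  structure(
    list(
      structure_id = structure_id,
      chain_id = chain_id,
      sequence = sequence,
      atoms = as_tibble(atoms),
      ca_coords = ca_coords,
      ligands = ligands
    ),
    class = "chain_entry"
  )
}

#' @export
print.chain_entry <- function(x, ...) {
  cat(sprintf(
    "<chain_entry> %s:%s  %d aa, %d atoms, %d ligand(s)\n",
    x$structure_id, x$chain_id, nchar(x$sequence), nrow(x$atoms),
    length(x$ligands)
  ))
  invisible(x)
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf(
    "<ligand> %s  %d atoms (%d heavy)\n",
    x$het_id, nrow(x$atoms), x$heavy_atom_count
  ))
  invisible(x)
}

#' Summarise chain entries as a tibble
#'
#' One row per chain: identifiers, sequence length, atom and ligand counts.
#'
#' @param entries List of [new_chain_entry()] objects.
#' @return A tibble with one row per entry.
#' @export
chain_summary <- function(entries) {
  tibble(
    structure_id = map_chr(entries, "structure_id"),
    chain_id = map_chr(entries, "chain_id"),
    n_residues = map_int(entries, ~ nchar(.x$sequence)),
    n_atoms = map_int(entries, ~ nrow(.x$atoms)),
    n_ligands = map_int(entries, ~ length(.x$ligands)),
    ligand_atoms = map_int(entries, ~ sum(map_int(.x$ligands, ~ nrow(.x$atoms))))
  )
}

lig_coords <- function(lig) as.matrix(lig$atoms[, c("x", "y", "z")])

atom_coords <- function(entry) as.matrix(entry$atoms[, c("x", "y", "z")])

# minimum Euclidean distance between the rows of two coordinate matrices
min_pair_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
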