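#' Parse a PDB structure into chain entries
#'
#' Reads ATOM/HETATM records, builds one [new_chain_entry()] per polymer
#' chain, and attaches each non-water hetero group to the chain whose
#' C-alpha set it is nearest to. Waters (HOH/WAT/DOD) are always dropped.
#' Alternate locations other than blank/'A' are dropped; nonstandard
#' polymer residues (e.g. MSE) are mapped to the closest standard one-letter
#' code, X if unknown. Chains without any C-alpha atom are skipped with a
#' warning.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param structure_id Identifier stored on the entries; defaults to the
#'   file stem (or `"STRUCT"` for literal text input).
#' @return List of `chain_entry` objects, one per polymer chain.
#' @export
parse_structure <- function(pdb, structure_id = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|ent)$", "", basename(pdb))
    }
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    if (is.null(structure_id)) structure_id <- "STRUCT"
  }
  validate_pdb_lines(lines)
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  writeLines(lines, path)
  p <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- as_tibble(p$atom)
  at <- filter(at, is.na(.data$alt) | .data$alt %in% c("", "A"))
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy) | trimws(at$elesy) == ""] <-
    element_from_name(at$elety[is.na(at$elesy) | trimws(at$elesy) == ""])
  at$element <- toupper(trimws(at$elesy))
  at$is_heavy <- !(at$element %in% c("H", "D"))
  at$vdw_radius <- vdw_radius(at$element)

  prot <- filter(at, .data$type == "ATOM")
  het <- filter(
    at, .data$type == "HETATM",
    !(toupper(.data$resid) %in% c("HOH", "WAT", "DOD"))
  )

  entries <- list()
  for (ch in unique(prot$chain)) {
    pc <- filter(prot, .data$chain == ch)
    # residues in file order, keyed by (resno, insert); keep C-alpha-bearing ones
    key <- paste(pc$resno, pc$insert, sep = "_")
    res_order <- unique(key)
    ca <- filter(pc, trimws(.data$elety) == "CA")
    ca_key <- paste(ca$resno, ca$insert, sep = "_")
    keep_res <- res_order[res_order %in% ca_key]
    if (length(keep_res) == 0) {
      warn(sprintf("chain %s has no C-alpha atoms; skipped", ch))
      next
    }
    ca <- ca[match(keep_res, ca_key), ]
    seq1 <- paste(suppressWarnings(bio3d::aa321(ca$resid)), collapse = "")
    pc <- filter(pc, key %in% keep_res)
    atoms <- select(
      pc, name = "elety", "element", "x", "y", "z",
      "is_heavy", "vdw_radius", "resid", "resno", "insert"
    )
    atoms$name <- trimws(atoms$name)
    entries[[length(entries) + 1]] <- new_chain_entry(
      structure_id = structure_id, chain_id = ch, sequence = seq1,
      atoms = atoms, ca_coords = as.matrix(ca[, c("x", "y", "z")])
    )
  }
  if (length(entries) == 0) return(entries)

  # group hetero atoms into ligands and attach each to the nearest chain
  if (nrow(het) > 0) {
    het$group <- paste(het$resid, het$chain, het$resno, het$insert, sep = "|")
    for (g in unique(het$group)) {
      ga <- filter(het, .data$group == g)
      lig <- new_ligand(
        het_id = ga$resid[1],
        atoms = {
          a <- select(
            ga, name = "elety", "element", "x", "y", "z",
            "is_heavy", "vdw_radius"
          )
          a$name <- trimws(a$name)
          a
        },
        resno = ga$resno[1], source_chain = ga$chain[1]
      )
      d <- map_dbl(entries, ~ min_pair_dist(lig_coords(lig), .x$ca_coords))
      i <- which.min(d)
      entries[[i]]$ligands <- c(entries[[i]]$ligands, list(lig))
    }
  }
  entries
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed %s record at line %d: too short", trimws(rec[i]), i))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz) || !all(is.finite(xyz))) {
      abort(sprintf("malformed %s record at line %d: bad coordinates", trimws(rec[i]), i))
    }
  }
  invisible(TRUE)
}

#' Write a chain entry back to PDB format
#'
#' Emits the chain's ATOM records, a TER record, and one HETATM block per
#' attached ligand, in fixed-width PDB columns (coordinates at 3 decimals).
#'
#' @param entry A `chain_entry`.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_chain_pdb <- function(entry, path = NULL) {
  fmt_name <- function(name, element) {
    # element-aligned atom-name field (columns 13-16)
    ifelse(
      nchar(name) >= 4, substr(name, 1, 4),
      ifelse(nchar(element) == 2, sprintf("%-4s", name), sprintf(" %-3s", name))
    )
  }
  a <- entry$atoms
  serial <- seq_len(nrow(a))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    serial, fmt_name(a$name, a$element), a$resid, entry$chain_id,
    a$resno, ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, a$element
  )
  lines <- c(lines, "TER")
  ser <- nrow(a)
  for (k in seq_along(entry$ligands)) {
    lig <- entry$ligands[[k]]
    la <- lig$atoms
    resno <- if (is.na(lig$resno)) 900 + k else lig$resno
    lines <- c(lines, sprintf(
      "HETATM%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      ser + seq_len(nrow(la)), fmt_name(la$name, la$element),
      substr(lig$het_id, 1, 3), entry$chain_id, resno,
      la$x, la$y, la$z, la$element
    ))
    ser <- ser + nrow(la)
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Keep chains with at least a minimum number of residues
#'
#' @param entries List of `chain_entry` objects.
#' @param min_residues Inclusive lower bound on sequence length (default 28).
#' @return The filtered list, order preserved.
#' @export
filter_chains <- function(entries, min_residues = 28) {
  stopifnot(min_residues >= 1)
  keep(entries, ~ nchar(.x$sequence) >= min_residues)
}

#' Filter a chain's ligands by size and contact distance
#'
#' A ligand is retained iff it has at least `min_heavy` non-hydrogen atoms
#' and the minimum distance between any of its atoms (hydrogens included,
#' if present) and the chain's C-alpha atoms is at most `max_min_dist`.
#' Both thresholds are inclusive.
#'
#' @param entry A `chain_entry`.
#' @param min_heavy Minimum heavy-atom count (default 7).
#' @param max_min_dist Maximum ligand-to-C-alpha minimum distance in
#'   Angstrom (default 5).
#' @return The entry with non-qualifying ligands removed.
#' @export
filter_ligands <- function(entry, min_heavy = 7, max_min_dist = 5.0) {
  entry$ligands <- keep(entry$ligands, function(lig) {
    lig$heavy_atom_count >= min_heavy &&
      min_pair_dist(lig_coords(lig), entry$ca_coords) <= max_min_dist
  })
  entry
}

#' Apply both chain and ligand filters to a set of entries
#'
#' @inheritParams filter_chains
#' @inheritParams filter_ligands
#' @return Filtered list of entries.
#' @export
filter_entries <- function(entries, min_residues = 28, min_heavy = 7,
                           max_min_dist = 5.0) {
  entries <- filter_chains(entries, min_residues)
  map(entries, filter_ligands, min_heavy = min_heavy, max_min_dist = max_min_dist)
}
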