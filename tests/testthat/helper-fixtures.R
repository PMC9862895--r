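# Shared fixtures, built once per test run.
.fix <- new.env(parent = emptyenv())

toy_entry <- function(seed = 42, n_residues = 45, n_pockets = 1, ...) {
  key <- paste("entry", seed, n_residues, n_pockets, sep = "_")
  if (is.null(.fix[[key]])) {
    fx <- make_toy_protein(
      fixture_spec(seed = seed, n_residues = n_residues,
                   n_pockets = n_pockets, ...)
    )
    .fix[[key]] <- parse_structure(fx$pdb, sprintf("toy%d", seed))[[1]]
  }
  .fix[[key]]
}

toy_featurized <- function(seed = 42, level = 1) {
  key <- paste("feat", seed, level, sep = "_")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- featurize_chain(toy_entry(seed), tessellation_level = level)
  }
  .fix[[key]]
}

# a minimal hand-built chain: n C-alpha atoms on a line, optional ligand
line_chain <- function(n = 30, id = "LIN", chain = "A", lig_at = NULL,
                       lig_n = 8, step = 3.8) {
  atoms <- tibble::tibble(
    name = "CA", element = "C",
    x = step * (seq_len(n) - 1), y = 0, z = 0,
    is_heavy = TRUE, vdw_radius = 1.7,
    resid = "ALA", resno = seq_len(n), insert = ""
  )
  ligs <- list()
  if (!is.null(lig_at)) {
    la <- tibble::tibble(
      name = paste0("C", seq_len(lig_n)), element = "C",
      x = lig_at[1] + 1.5 * (seq_len(lig_n) - 1), y = lig_at[2], z = lig_at[3],
      is_heavy = TRUE, vdw_radius = 1.7
    )
    ligs <- list(new_ligand("LIG", la, resno = 900))
  }
  new_chain_entry(id, chain, strrep("A", n), atoms,
                  as.matrix(atoms[, c("x", "y", "z")]), ligs)
}

# rotation matrix about z
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# apply a rigid motion to a chain entry (all atoms, C-alphas, ligands)
move_entry <- function(entry, R = diag(3), t = c(0, 0, 0)) {
  mv <- function(m) sweep(m %*% t(R), 2, t, "+")
  xyz <- mv(as.matrix(entry$atoms[, c("x", "y", "z")]))
  entry$atoms$x <- xyz[, 1]; entry$atoms$y <- xyz[, 2]; entry$atoms$z <- xyz[, 3]
  entry$ca_coords <- mv(entry$ca_coords)
  entry$ligands <- lapply(entry$ligands, function(lg) {
    lx <- mv(as.matrix(lg$atoms[, c("x", "y", "z")]))
    lg$atoms$x <- lx[, 1]; lg$atoms$y <- lx[, 2]; lg$atoms$z <- lx[, 3]
    lg
  })
  entry
}
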