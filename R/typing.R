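# Atom typing: every atom gets exactly one type code
#   C  aliphatic carbon        A  aromatic carbon
#   NA nitrogen acceptor       NS nitrogen acceptor (ring)
#   OA oxygen acceptor         OS oxygen acceptor (ester-like)
#   SA sulfur acceptor         HD polar hydrogen    HS other hydrogen
#   MG ZN MN CA FE metals      other: everything else
# and an 8-bit channel membership derived from the type:
#   hydrophobicity (C/A), aromaticity (A), H-acceptor (NA/NS/OA/OS/SA),
#   H-donor (HD/HS on N or O), positive/negative ionizable (formal
#   charges), metal, excluded volume (all atoms).

channel_names <- function() {
  c("hydrophobicity", "aromaticity", "h_acceptor", "h_donor",
    "positive", "negative", "metal", "excluded")
}

.arom_ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.pos_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.neg_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Assign chemistry-aware atom types and property channels
#'
#' Protein atoms are typed from residue templates (aromatic ring membership,
#' formal charges on Lys/Arg side-chain nitrogens and Asp/Glu carboxylates,
#' the C-terminal OXT); ligand atoms from element plus distance-based bond
#' perception with planarity-checked ring aromaticity. Unknown elements get
#' type `other` and contribute only to the excluded-volume channel. Metal
#' cofactor elements are typed as metals and marked positive ionizable.
#'
#' @param x A `chain_entry` or a `ligand`.
#' @return A tibble of typed atoms: coordinates, `vdw_radius`, `type_code`,
#'   and one logical column per channel (see `channel_names()`).
#' @export
assign_atom_types <- function(x) {
  if (inherits(x, "chain_entry")) {
    typed <- type_protein_atoms(x$atoms)
  } else if (inherits(x, "ligand")) {
    typed <- type_ligand_atoms(x$atoms)
  } else {
    abort("x must be a chain_entry or a ligand")
  }
  typed
}

finish_channels <- function(at, aromatic, positive, negative, h_polar_NO) {
  el <- at$element
  metal <- el %in% .metal_elements
  type_code <- rep("other", nrow(at))
  type_code[el == "C"] <- "C"
  type_code[el == "C" & aromatic] <- "A"
  type_code[el == "N"] <- "NA"
  type_code[el == "O"] <- "OA"
  type_code[el == "S"] <- "SA"
  type_code[el %in% c("H", "D")] <- ifelse(h_polar_NO[el %in% c("H", "D")], "HD", "HS")
  type_code[metal] <- el[metal]
  out <- tibble(
    name = at$name, element = el,
    x = at$x, y = at$y, z = at$z, vdw_radius = at$vdw_radius,
    type_code = type_code,
    hydrophobicity = type_code %in% c("C", "A"),
    aromaticity = type_code == "A",
    h_acceptor = type_code %in% c("NA", "NS", "OA", "OS", "SA"),
    h_donor = type_code %in% c("HD", "HS") & h_polar_NO,
    positive = positive | metal,
    negative = negative,
    metal = metal,
    excluded = TRUE
  )
  out
}

type_protein_atoms <- function(at) {
  nm <- at$name
  res <- at$resid
  aromatic <- map_lgl(seq_len(nrow(at)), function(i) {
    ring <- .arom_ring_atoms[[res[i]]]
    !is.null(ring) && nm[i] %in% ring && at$element[i] == "C"
  })
  positive <- map_lgl(seq_len(nrow(at)), function(i) {
    p <- .pos_atoms[[res[i]]]
    !is.null(p) && nm[i] %in% p
  })
  negative <- map_lgl(seq_len(nrow(at)), function(i) {
    p <- .neg_atoms[[res[i]]]
    (!is.null(p) && nm[i] %in% p) || nm[i] == "OXT"
  })
  h_polar <- h_partner_is_NO(at)
  finish_channels(at, aromatic, positive, negative, h_polar)
}

# for hydrogens: TRUE when the nearest heavy atom (the bonded partner)
# is nitrogen or oxygen
h_partner_is_NO <- function(at) {
  isH <- at$element %in% c("H", "D")
  out <- rep(FALSE, nrow(at))
  if (!any(isH) || all(isH)) return(out)
  hxyz <- as.matrix(at[isH, c("x", "y", "z")])
  heavy <- at[!isH, ]
  hvxyz <- as.matrix(heavy[, c("x", "y", "z")])
  for (k in seq_len(nrow(hxyz))) {
    d <- sqrt(colSums((t(hvxyz) - hxyz[k, ])^2))
    out[which(isH)[k]] <- heavy$element[which.min(d)] %in% c("N", "O")
  }
  out
}

# distance-based bond perception between heavy atoms
perceive_bonds <- function(at) {
  n <- nrow(at)
  if (n < 2) return(matrix(integer(), ncol = 2))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rc <- cov_radius(at$element)
  idx <- utils::combn(n, 2)
  d <- sqrt(rowSums((xyz[idx[1, ], , drop = FALSE] - xyz[idx[2, ], , drop = FALSE])^2))
  lim <- 1.3 * (rc[idx[1, ]] + rc[idx[2, ]])
  t(idx[, d < lim & d > 0.4, drop = FALSE])
}

# rings of size 3..6 via per-edge shortest alternative path
find_small_rings <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0) return(list())
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  rings <- list()
  for (e in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, bonds[e, ]))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, bonds[e, 1], bonds[e, 2])$vpath[[1]]
    )
    if (length(sp) >= 3 && length(sp) <= 6) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = "-")
      rings[[key]] <- ring
    }
  }
  unname(rings)
}

ring_is_planar <- function(xyz, tol = 0.15) {
  c0 <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, c0))
  normal <- s$v[, 3]
  max(abs(sweep(xyz, 2, c0) %*% normal)) < tol
}

type_ligand_atoms <- function(at) {
  heavy_idx <- which(at$is_heavy)
  hv <- at[heavy_idx, ]
  bonds <- perceive_bonds(hv)
  nbr <- vector("list", nrow(hv))
  for (k in seq_len(nrow(bonds))) {
    nbr[[bonds[k, 1]]] <- c(nbr[[bonds[k, 1]]], bonds[k, 2])
    nbr[[bonds[k, 2]]] <- c(nbr[[bonds[k, 2]]], bonds[k, 1])
  }
  aromatic_h <- rep(FALSE, nrow(hv))
  rings <- find_small_rings(nrow(hv), bonds)
  for (ring in rings) {
    if (length(ring) < 5) next
    els <- hv$element[ring]
    if (!all(els %in% c("C", "N"))) next
    if (any(map_int(nbr[ring], length) > 3)) next
    xyz <- as.matrix(hv[ring, c("x", "y", "z")])
    if (ring_is_planar(xyz)) aromatic_h[ring] <- TRUE
  }
  # carboxylate / phosphate-like oxygens: O with a single neighbor that
  # carries at least two oxygen neighbors
  negative_h <- map_lgl(seq_len(nrow(hv)), function(i) {
    if (hv$element[i] != "O" || length(nbr[[i]]) != 1) return(FALSE)
    ctr <- nbr[[i]][1]
    if (!hv$element[ctr] %in% c("C", "P", "S")) return(FALSE)
    sum(hv$element[nbr[[ctr]]] == "O") >= 2
  })
  # quaternary nitrogen
  positive_h <- map_lgl(seq_len(nrow(hv)), function(i) {
    hv$element[i] == "N" && length(nbr[[i]]) >= 4
  })
  aromatic <- positive <- negative <- rep(FALSE, nrow(at))
  aromatic[heavy_idx] <- aromatic_h
  positive[heavy_idx] <- positive_h
  negative[heavy_idx] <- negative_h
  finish_channels(at, aromatic, positive, negative, h_partner_is_NO(at))
}
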