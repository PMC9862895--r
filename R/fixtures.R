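# Synthetic fixtures: toy protein structures with planted pockets,
# sequence families with controlled divergence, and prediction fields
# with planted blobs. All generators are pure functions of their
# arguments (the seed included), so fixtures are reproducible anywhere.

#' Specification for a synthetic structure fixture
#'
#' @param seed Integer RNG seed.
#' @param n_residues Residues per chain (default 60).
#' @param n_pockets Pockets (ligands) per chain (default 1).
#' @param pocket_radius Carving radius around each pocket anchor,
#'   Angstrom (default 4).
#' @param ligand_size Heavy atoms per planted ligand (default 12).
#' @param sequence_mutation_rate Per-position substitution rate for
#'   sequence families (default 0.05).
#' @param noise_sigma Gaussian noise scale for prediction fields
#'   (default 0.1).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_residues = 60, n_pockets = 1,
                         pocket_radius = 4, ligand_size = 12,
                         sequence_mutation_rate = 0.05, noise_sigma = 0.1) {
  stopifnot(n_residues >= 10, n_pockets >= 0, ligand_size >= 1,
            sequence_mutation_rate >= 0, sequence_mutation_rate <= 1)
  structure(
    list(seed = seed, n_residues = n_residues, n_pockets = n_pockets,
         pocket_radius = pocket_radius, ligand_size = ligand_size,
         sequence_mutation_rate = sequence_mutation_rate,
         noise_sigma = noise_sigma),
    class = "fixture_spec"
  )
}

.aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
                 "M", "F", "P", "S", "T", "W", "Y", "V")
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
# side-chain pseudo-atom element per residue letter (C/N/O/S only, so
# featurization is fully typed)
.sc_element <- c(A = "C", R = "N", N = "N", D = "O", C = "S", Q = "N",
                 E = "O", G = "C", H = "N", I = "C", K = "N", L = "C",
                 M = "S", F = "C", P = "C", S = "O", T = "O", W = "C",
                 Y = "O", V = "C")

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# compact self-avoiding C-alpha walk: 3.8 A steps, biased back toward
# the origin once outside the target globule radius
toy_ca_trace <- function(n_res) {
  target_r <- 4.2 * n_res^(1 / 3)
  for (restart in 1:100) {
    ca <- matrix(0, n_res, 3)
    failed <- FALSE
    for (i in 2:n_res) {
      placed <- FALSE
      for (try in 1:100) {
        dir <- rand_unit()
        if (sqrt(sum(ca[i - 1, ]^2)) > target_r) {
          pull <- -ca[i - 1, ] / sqrt(sum(ca[i - 1, ]^2))
          dir <- dir + 1.5 * pull
          dir <- dir / sqrt(sum(dir^2))
        }
        cand <- ca[i - 1, ] + 3.8 * dir
        if (i > 2) {
          d <- sqrt(colSums((t(ca[1:(i - 2), , drop = FALSE]) - cand)^2))
          if (min(d) < 3.4) next
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        failed <- TRUE
        break
      }
    }
    if (!failed) return(ca)
  }
  abort("could not place a self-avoiding walk; change the seed")
}

#' Generate a toy protein structure with planted pockets
#'
#' Builds a compact self-avoiding C-alpha walk with one side-chain
#' pseudo-atom per residue, carves `n_pockets` concave pockets by
#' removing side-chain atoms near surface anchors, and places a rigid
#' ligand of `ligand_size` heavy atoms in each pocket within 5 Angstrom
#' of a C-alpha. Ground truth is the ligand placement. Deterministic in
#' `spec$seed` (byte-identical PDB text for equal seeds).
#'
#' @param spec A [fixture_spec()].
#' @param n_chains Number of chains to emit (chains B, C, ... are
#'   independent walks offset in space; default 1).
#' @param structure_id Identifier written into the fixture (default
#'   `"TOY"`).
#' @return List with `pdb` (character vector of PDB lines), `truth`
#'   (tibble: `chain`, `pocket`, ligand centroid `x`, `y`, `z`), and
#'   `spec`.
#' @export
make_toy_protein <- function(spec = fixture_spec(), n_chains = 1,
                             structure_id = "TOY") {
  set.seed(spec$seed)
  chains <- LETTERS[seq_len(n_chains)]
  all_lines <- character()
  truth <- list()
  serial <- 0L
  for (ci in seq_len(n_chains)) {
    offset <- c(60 * (ci - 1), 0, 0)
    seq_letters <- sample(.aa_letters, spec$n_residues, replace = TRUE)
    ca <- toy_ca_trace(spec$n_residues)
    centroid <- colMeans(ca)
    # side-chain pseudo-atoms point away from the centroid
    sc <- t(vapply(seq_len(spec$n_residues), function(i) {
      out <- ca[i, ] - centroid
      nrm <- sqrt(sum(out^2))
      dir <- if (nrm < 1e-6) rand_unit() else out / nrm + 0.4 * rand_unit()
      ca[i, ] + 2.0 * dir / sqrt(sum(dir^2))
    }, numeric(3)))
    keep_sc <- rep(TRUE, spec$n_residues)
    lining <- rep(FALSE, spec$n_residues)
    ligands <- list()
    anchors <- integer()
    if (spec$n_pockets > 0) {
      d_cen <- sqrt(colSums((t(ca) - centroid)^2))
      ord <- order(-d_cen)
      for (k in seq_len(spec$n_pockets)) {
        cand <- ord[!ord %in% anchors]
        if (length(anchors) > 0) {
          far <- map_lgl(cand, function(i) {
            min(sqrt(colSums((t(ca[anchors, , drop = FALSE]) - ca[i, ])^2))) > 14
          })
          cand <- cand[far]
        }
        if (length(cand) == 0) abort("could not separate pockets; reduce n_pockets")
        anchor <- cand[1]
        anchors <- c(anchors, anchor)
        outward <- ca[anchor, ] - centroid
        outward <- outward / sqrt(sum(outward^2))
        # the pocket mouth sits just above the anchor residue; carving out
        # the nearby side chains leaves a concave dent for the ligand
        pocket_center <- ca[anchor, ] + 2.2 * outward
        d_sc <- sqrt(colSums((t(sc) - pocket_center)^2))
        keep_sc <- keep_sc & d_sc > spec$pocket_radius
        # pocket mouths get an acidic lining (a common feature of real
        # binding sites) so pockets are chemically, not just geometrically,
        # distinctive; a fixed lining size keeps the cue strength uniform
        # across fixtures
        lig_xyz <- place_toy_ligand(
          pocket_center, spec$ligand_size,
          rbind(ca, sc[keep_sc, , drop = FALSE]), outward = outward, ca = ca
        )
        ligands[[k]] <- lig_xyz
        # acidic residues line the whole ligand footprint (pocket or groove)
        d_lig <- sqrt(outer(rowSums(sc^2), rowSums(lig_xyz^2), "+") -
                        2 * tcrossprod(sc, lig_xyz))
        lining <- lining | (keep_sc & apply(d_lig, 1, min) <= 5.0)
      }
    }
    seq_letters[lining & seq_letters != "G"] <- "D"
    # emit PDB records
    for (i in seq_len(spec$n_residues)) {
      res3 <- .aa3[[seq_letters[i]]]
      serial <- serial + 1L
      all_lines <- c(all_lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, res3, chains[ci], i,
        ca[i, 1] + offset[1], ca[i, 2] + offset[2], ca[i, 3] + offset[3]
      ))
      if (keep_sc[i] && seq_letters[i] != "G") {
        is_lining <- lining[i]
        el <- if (is_lining) "O" else .sc_element[[seq_letters[i]]]
        nm <- if (is_lining) "OD1" else "CB "
        serial <- serial + 1L
        all_lines <- c(all_lines, sprintf(
          "ATOM  %5d  %s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, res3, chains[ci], i,
          sc[i, 1] + offset[1], sc[i, 2] + offset[2], sc[i, 3] + offset[3], el
        ))
      }
    }
    all_lines <- c(all_lines, "TER")
    for (k in seq_along(ligands)) {
      lg <- ligands[[k]]
      for (j in seq_len(nrow(lg))) {
        serial <- serial + 1L
        all_lines <- c(all_lines, sprintf(
          "HETATM%5d %s LIG %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial,
          ifelse(j == 1 && attr(lg, "has_o"), " O1 ", sprintf(" C%-2d", j)),
          chains[ci], 800 + k,
          lg[j, 1] + offset[1], lg[j, 2] + offset[2], lg[j, 3] + offset[3],
          ifelse(j == 1 && attr(lg, "has_o"), " O", " C")
        ))
      }
      ctr <- colMeans(lg)
      truth[[length(truth) + 1]] <- tibble(
        chain = chains[ci], pocket = k,
        x = ctr[1] + offset[1], y = ctr[2] + offset[2], z = ctr[3] + offset[3]
      )
    }
  }
  all_lines <- c(all_lines, "END")
  list(
    pdb = all_lines,
    truth = if (length(truth)) bind_rows(truth) else
      tibble(chain = character(), pocket = integer(), x = numeric(),
             y = numeric(), z = numeric()),
    spec = spec
  )
}

# Rigid ligand placed at a pocket. Small ligands are compact blobs grown
# by a short-step random walk; large ones (>= 16 heavy atoms) hug the
# surface as elongated groove binders, so planted sites range from
# sphere-like to stretched — mirroring the shape diversity of real
# binding sites.
place_toy_ligand <- function(center, n_atoms, chain_coords, outward = NULL,
                             ca = NULL) {
  if (n_atoms >= 16 && !is.null(outward)) {
    g <- place_groove_ligand(center, n_atoms, chain_coords, outward, ca)
    if (!is.null(g)) return(g)
  }
  max_r <- 1.4 + 0.2 * n_atoms
  xyz <- matrix(0, n_atoms, 3)
  xyz[1, ] <- center
  for (j in seq_len(n_atoms - 1) + 1) {
    ok <- FALSE
    for (try in 1:300) {
      cand <- xyz[j - 1, ] + 1.5 * rand_unit()
      if (sqrt(sum((cand - center)^2)) > max_r) next
      if (j > 2 && min(sqrt(colSums((t(xyz[1:(j - 2), , drop = FALSE]) - cand)^2))) < 1.4) next
      if (min(sqrt(colSums((t(chain_coords) - cand)^2))) < 2.6) next
      xyz[j, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) abort("could not pack the ligand; change the seed or shrink it")
  }
  attr(xyz, "has_o") <- TRUE
  xyz
}

# elongated ligand along a surface tangent, at a roughly constant height
# over the chain; NULL when no clash-free tangent is found
place_groove_ligand <- function(center, n_atoms, chain_coords, outward, ca) {
  step <- 1.45
  for (try in 1:60) {
    t0 <- rand_unit()
    t0 <- t0 - sum(t0 * outward) * outward
    nrm <- sqrt(sum(t0^2))
    if (nrm < 1e-3) next
    t0 <- t0 / nrm
    offs <- (seq_len(n_atoms) - (n_atoms + 1) / 2) * step
    xyz <- t(vapply(offs, function(o) {
      p <- center + o * t0
      # keep a constant hover height over the nearest chain atom
      d <- sqrt(colSums((t(chain_coords) - p)^2))
      j <- which.min(d)
      lift <- p - chain_coords[j, ]
      # signed correction: hover at a constant 3 A over the curved surface
      p + lift / sqrt(sum(lift^2)) * (3.0 - d[j])
    }, numeric(3)))
    dmin_chain <- min(sqrt(outer(rowSums(xyz^2), rowSums(chain_coords^2), "+") -
                             2 * tcrossprod(xyz, chain_coords)))
    d_ca <- sqrt(outer(rowSums(xyz^2), rowSums(ca^2), "+") - 2 * tcrossprod(xyz, ca))
    if (dmin_chain < 2.4) next
    if (min(d_ca) > 4.8) next
    attr(xyz, "has_o") <- TRUE
    return(xyz)
  }
  NULL
}

#' Generate a family of related amino-acid sequences
#'
#' One random base sequence; each member substitutes every position
#' independently with probability `mutation_rate` (to a uniformly chosen
#' different letter). Expected pairwise identity between members is
#' about `(1 - rate)^2 + rate^2 / 19`.
#'
#' @param base_len Base sequence length (>= 10).
#' @param n_members Number of family members.
#' @param mutation_rate Per-position substitution probability.
#' @param seed Integer RNG seed.
#' @return Named character vector of sequences (`member1`, ...).
#' @export
make_sequence_family <- function(base_len, n_members, mutation_rate, seed = 1) {
  stopifnot(base_len >= 10)
  set.seed(seed)
  base <- sample(.aa_letters, base_len, replace = TRUE)
  out <- vapply(seq_len(n_members), function(m) {
    s <- base
    hit <- runif(base_len) < mutation_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(old) {
        sample(setdiff(.aa_letters, old), 1)
      }, character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  setNames(out, sprintf("member%d", seq_len(n_members)))
}

#' Generate a synthetic prediction field with planted binding sites
#'
#' Base prediction 0.9 inside the planted sites and 0.05 outside, plus
#' Gaussian noise clipped to \[0, 1\].
#'
#' @param points Point coordinates (only the count is used).
#' @param planted_sites List of integer index vectors into `points`.
#' @param noise_sigma Noise standard deviation.
#' @param seed Integer RNG seed.
#' @return Numeric prediction vector aligned with `points`.
#' @export
make_prediction_field <- function(points, planted_sites, noise_sigma = 0.1,
                                  seed = 1) {
  n <- if (is.matrix(points)) nrow(points) else nrow(as_tibble(points))
  set.seed(seed)
  yp <- rep(0.05, n)
  yp[unlist(planted_sites)] <- 0.9
  pmin(pmax(yp + rnorm(n, sd = noise_sigma), 0), 1)
}
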