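#' Sort chains by ligand count, then total ligand atoms
#'
#' Stable descending sort: primary key is the number of bound ligands,
#' secondary key the total number of atoms in those ligands; fully tied
#' chains keep their input order.
#'
#' @param cluster List of `chain_entry` objects.
#' @return The reordered list.
#' @export
sort_chains <- function(cluster) {
  n_lig <- map_int(cluster, ~ length(.x$ligands))
  n_atoms <- map_int(cluster, ~ sum(map_int(.x$ligands, ~ nrow(.x$atoms))))
  cluster[order(-n_lig, -n_atoms)]
}

# any heavy-atom pair closer than `clash_dist` counts as a steric clash
clashes <- function(coords_a, coords_b, clash_dist = 1.5) {
  min_pair_dist(coords_a, coords_b) < clash_dist
}

heavy_coords <- function(atoms) {
  as.matrix(atoms[atoms$is_heavy, c("x", "y", "z"), drop = FALSE])
}

#' Merge ligands of similar chains onto representative chains
#'
#' Within one sequence cluster: chains are sorted by [sort_chains()]; the
#' first chain that superposes (RMSD strictly below `rmsd_max`) onto at
#' least half of the remaining cluster members becomes the representative.
#' Each mergeable chain's ligands are transformed with its superposition
#' and added to the representative unless they clash (heavy-atom pair
#' closer than `clash_dist`) with an already-kept ligand or with the
#' representative chain, or end up farther than `max_min_dist` from every
#' representative C-alpha. Chains that could not be merged form a new
#' working set and the procedure repeats, so the output may contain
#' several representatives.
#'
#' @param cluster List of `chain_entry` objects (one sequence cluster).
#' @param seqid,overlap Superposition gates, see [superpose()].
#' @param rmsd_max Strict RMSD upper bound for merging (default 2).
#' @param clash_dist Heavy-atom clash distance in Angstrom (default 1.5).
#' @param max_min_dist Ligand-to-C-alpha contact rule reused from
#'   filtering (default 5).
#' @return List of representative `chain_entry` objects; each carries a
#'   tibble attribute `"manifest"` mapping kept ligands to their source
#'   structure/chain.
#' @export
merge_cluster <- function(cluster, seqid = 0.9, overlap = 0.9, rmsd_max = 2.0,
                          clash_dist = 1.5, max_min_dist = 5.0) {
  stopifnot(length(cluster) >= 1)
  reps <- list()
  working <- cluster
  while (length(working) > 0) {
    sorted <- sort_chains(working)
    n <- length(sorted)
    sup <- vector("list", n)
    ref_i <- NULL
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      sups_i <- map(others, function(j) superpose(sorted[[i]], sorted[[j]], seqid, overlap))
      ok <- map_lgl(sups_i, ~ !is.null(.x) && .x$rmsd < rmsd_max)
      if (length(others) == 0 || sum(ok) >= ceiling(length(others) / 2)) {
        ref_i <- i
        sup[others] <- sups_i
        break
      }
    }
    if (is.null(ref_i)) {
      # no chain aligns to half its peers: the top-sorted chain stands alone
      ref_i <- 1
      others <- setdiff(seq_len(n), 1)
      sup[others] <- map(others, function(j) superpose(sorted[[1]], sorted[[j]], seqid, overlap))
    }
    ref <- sorted[[ref_i]]
    kept <- ref$ligands
    manifest <- tibble(
      het_id = map_chr(kept, "het_id"),
      source_structure = rep(ref$structure_id, length(kept)),
      source_chain = rep(ref$chain_id, length(kept))
    )
    merged_idx <- integer()
    ref_heavy <- heavy_coords(ref$atoms)
    for (j in setdiff(seq_len(n), ref_i)) {
      sp <- sup[[j]]
      if (is.null(sp) || sp$rmsd >= rmsd_max) next
      donor <- sorted[[j]]
      ligs <- donor$ligands
      if (length(ligs) > 0) {
        ligs <- ligs[order(-map_int(ligs, "heavy_atom_count"))]
        for (lig in ligs) {
          moved <- lig
          xyz <- apply_transform(lig_coords(lig), sp$rotation, sp$translation)
          moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
          mh <- heavy_coords(moved$atoms)
          hit_kept <- any(map_lgl(kept, ~ clashes(mh, heavy_coords(.x$atoms), clash_dist)))
          if (hit_kept) next
          if (clashes(mh, ref_heavy, clash_dist)) next
          if (min_pair_dist(as.matrix(moved$atoms[, c("x", "y", "z")]),
                            ref$ca_coords) > max_min_dist) next
          kept <- c(kept, list(moved))
          manifest <- bind_rows(manifest, tibble(
            het_id = lig$het_id, source_structure = donor$structure_id,
            source_chain = donor$chain_id
          ))
        }
      }
      merged_idx <- c(merged_idx, j)
    }
    ref$ligands <- kept
    attr(ref, "manifest") <- manifest
    reps <- c(reps, list(ref))
    working <- sorted[setdiff(seq_len(n), c(ref_i, merged_idx))]
  }
  reps
}

#' Merge every cluster of a clustered chain set
#'
#' @param entries List of `chain_entry` objects.
#' @param cluster_set A `cluster_set` from [build_cluster_set()] whose
#'   members correspond positionally to `entries`.
#' @param ... Passed to [merge_cluster()].
#' @return List of representative `chain_entry` objects across clusters.
#' @export
merge_all_clusters <- function(entries, cluster_set, ...) {
  cl <- cluster_set$members$cluster_id
  stopifnot(length(cl) == length(entries))
  out <- list()
  for (k in sort(unique(cl))) {
    out <- c(out, merge_cluster(entries[cl == k], ...))
  }
  out
}
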