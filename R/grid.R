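#' Occupancy of a point by an atom
#'
#' The occupancy field `1 - exp(-(r_vdw / d)^12)` is 1 at the atom center,
#' about 0.63 at one van der Waals radius, and crosses 1e-4 at about 2.15
#' radii — so the ligandability labeling threshold sits at roughly twice
#' the atomic radius. Strictly decreasing in distance.
#'
#' @param distance Distance(s) from the atom center, Angstrom.
#' @param vdw_radius Van der Waals radius (recycled).
#' @return Occupancy values in \[0, 1\].
#' @export
occupancy <- function(distance, vdw_radius) {
  out <- 1 - exp(-(vdw_radius / distance)^12)
  out[distance == 0] <- 1
  out
}

#' Compute an 8-channel chemical property grid around a point
#'
#' An axis-aligned cube of `size^3` voxels centered on `center`, voxel
#' centers at `center + spacing * (i - (size-1)/2)`. The value of channel
#' k at a voxel is the maximum, over the atoms belonging to that channel,
#' of the occupancy at the voxel center; contributions below 1e-8 are
#' treated as zero.
#'
#' @param typed_atoms Tibble from [assign_atom_types()].
#' @param center Numeric 3-vector, Angstrom.
#' @param spacing Voxel spacing, Angstrom (default 1).
#' @param size Voxels per axis (default 19).
#' @return A `property_grid`: list with `values` (array
#'   `size x size x size x 8`), `center`, `spacing`.
#' @export
compute_grid <- function(typed_atoms, center, spacing = 1.0, size = 19) {
  stopifnot(spacing > 0, length(center) == 3)
  prep <- grid_inputs(typed_atoms)
  vals <- grid_values(prep, center, spacing, size)
  structure(
    list(values = vals, center = as.numeric(center), spacing = spacing),
    class = "property_grid"
  )
}

# hoist the per-chain conversions out of per-point grid loops
grid_inputs <- function(typed_atoms) {
  ch <- as.matrix(typed_atoms[, channel_names()])
  storage.mode(ch) <- "integer"
  list(
    coords = as.matrix(typed_atoms[, c("x", "y", "z")]),
    radii = typed_atoms$vdw_radius, chan = ch
  )
}

grid_values <- function(prep, center, spacing = 1.0, size = 19) {
  vals <- occupancy_grid_cpp(
    prep$coords, prep$radii, prep$chan, as.numeric(center), spacing,
    as.integer(size)
  )
  dim(vals) <- c(size, size, size, ncol(prep$chan))
  dimnames(vals) <- list(NULL, NULL, NULL, channel_names())
  vals
}

#' @export
print.property_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<property_grid> %dx%dx%d voxels x %d channels, spacing %g A\n",
    d[1], d[2], d[3], d[4], x$spacing
  ))
  invisible(x)
}

#' Label surface points as ligandable from bound ligands
#'
#' A point is ligandable iff the excluded-volume occupancy of some ligand
#' atom at the point exceeds `threshold` (strictly). With the default
#' 1e-4 this reaches about 2.15 van der Waals radii from each ligand atom.
#'
#' @param points A `surface_points` tibble.
#' @param ligands List of `ligand` objects.
#' @param threshold Strict occupancy threshold (default 1e-4).
#' @return `points` with the `ligandable` column filled.
#' @export
label_ligandability <- function(points, ligands, threshold = 1e-4) {
  n <- nrow(points)
  lab <- rep(FALSE, n)
  if (length(ligands) > 0 && n > 0) {
    pm <- point_matrix(points)
    for (lig in ligands) {
      lm <- lig_coords(lig)
      rad <- lig$atoms$vdw_radius
      for (k in seq_len(nrow(lm))) {
        d <- sqrt(colSums((t(pm) - lm[k, ])^2))
        lab <- lab | occupancy(d, rad[k]) > threshold
      }
    }
  }
  points$ligandable <- lab
  points
}

#' Per-ligand labeled point sets (ground-truth binding sites)
#'
#' One candidate site per ligand — the surface points that ligand labels;
#' sites sharing points are merged.
#'
#' @inheritParams label_ligandability
#' @return List of integer index vectors into `points`, pairwise disjoint.
#' @export
true_site_indices <- function(points, ligands, threshold = 1e-4) {
  per_lig <- map(ligands, function(lig) {
    which(label_ligandability(points, list(lig), threshold)$ligandable)
  })
  per_lig <- per_lig[map_int(per_lig, length) > 0]
  # merge sites that share points
  merged <- list()
  for (s in per_lig) {
    hit <- which(map_lgl(merged, ~ length(intersect(.x, s)) > 0))
    if (length(hit) == 0) {
      merged <- c(merged, list(s))
    } else {
      pooled <- sort(unique(c(s, unlist(merged[hit]))))
      merged <- c(merged[-hit], list(pooled))
    }
  }
  merged
}

#' Serialize surface points to TSV
#' @param points A `surface_points` tibble.
#' @param path Output path.
#' @export
write_points_tsv <- function(points, path) {
  utils::write.table(
    points[, c("x", "y", "z", "ligandable", "prediction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read surface points from TSV
#' @param path Input path written by [write_points_tsv()].
#' @return A `surface_points` tibble.
#' @export
read_points_tsv <- function(path) {
  df <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  class(df) <- c("surface_points", class(df))
  df
}
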