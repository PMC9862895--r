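# Unit icosphere vertices by recursive triangle subdivision of a regular
# icosahedron; level L has 10*4^L + 2 vertices.
icosphere_vertices <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (l in seq_len(level)) {
    mid_cache <- new.env(parent = emptyenv())
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid_cache[[key]]
      if (!is.null(m)) return(m)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      m <- nrow(v)
      assign(key, m, envir = mid_cache)
      m
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(c_, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  unname(v)
}

#' Solvent-accessible dot surface of a chain
#'
#' Candidate points are placed on spheres of radius `vdw + solvent_radius`
#' around every heavy atom, on the vertices of a recursively subdivided
#' icosahedron; a point is kept iff it lies outside every other atom's
#' expanded sphere. The result is the chain's solvent-accessible dot
#' surface.
#'
#' @param entry A `chain_entry`, or an atom tibble with columns `x`, `y`,
#'   `z`, `vdw_radius`, `is_heavy`.
#' @param solvent_radius Solvent probe radius in Angstrom (default 1.4).
#' @param tessellation_level Icosahedron subdivision level; a single free
#'   atom yields `10 * 4^level + 2` points (default 4).
#' @return A `surface_points` tibble: `x`, `y`, `z`, `atom` (index of the
#'   generating atom), `ligandable` (logical, `NA` until labeled) and
#'   `prediction` (numeric, `NA` until predicted).
#' @export
sas_points <- function(entry, solvent_radius = 1.4, tessellation_level = 4) {
  at <- if (inherits(entry, "chain_entry")) entry$atoms else entry
  at <- at[at$is_heavy, , drop = FALSE]
  stopifnot(nrow(at) >= 1, solvent_radius >= 0, tessellation_level >= 0)
  unit <- icosphere_vertices(tessellation_level)
  centers <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$vdw_radius + solvent_radius
  out <- vector("list", nrow(at))
  for (i in seq_len(nrow(at))) {
    pts <- sweep(unit * rad[i], 2, centers[i, ], "+")
    # only atoms whose expanded sphere can reach atom i's surface matter
    dc <- sqrt(colSums((t(centers) - centers[i, ])^2))
    nb <- which(dc < rad[i] + rad & seq_len(nrow(at)) != i)
    keep <- rep(TRUE, nrow(pts))
    for (j in nb) {
      dj2 <- colSums((t(pts) - centers[j, ])^2)
      # strictly-inside test with a small slack so points exactly on a
      # coincident sphere survive floating-point rounding
      keep <- keep & dj2 >= rad[j]^2 - 1e-9
      if (!any(keep)) break
    }
    if (any(keep)) {
      out[[i]] <- tibble(
        x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3], atom = i
      )
    }
  }
  res <- bind_rows(out)
  # coincident atoms generate coincident boundary points; keep one copy
  res <- res[!duplicated(res[, c("x", "y", "z")]), ]
  res$ligandable <- NA
  res$prediction <- NA_real_
  class(res) <- c("surface_points", class(res))
  if (inherits(entry, "chain_entry")) {
    attr(res, "chain_ref") <- paste(entry$structure_id, entry$chain_id, sep = ":")
  }
  res
}

point_matrix <- function(points) {
  as.matrix(points[, c("x", "y", "z")])
}
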