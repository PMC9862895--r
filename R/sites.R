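site_props_one <- function(xyz) {
  ctr <- colMeans(xyz)
  d <- sqrt(colSums((t(xyz) - ctr)^2))
  list(center = ctr, size = nrow(xyz), avg_dist = mean(d),
       std_dist = if (nrow(xyz) > 1) sd(d) else 0)
}

#' Shape statistics of a set of binding sites
#'
#' Empirical 10th and 90th percentiles (linear interpolation between
#' order statistics) of three per-site properties: number of points,
#' average distance of the points from the geometric center, and the
#' standard deviation of that distance (small for sphere-like sites,
#' large for elongated ones).
#'
#' @param sites A tibble with columns `size`, `avg_dist`, `std_dist`
#'   (e.g. from [binding_sites()] or [true_sites_table()]).
#' @return A `site_stats` object with elements `qv`, `qa`, `qs`, each a
#'   `(10th, 90th)` percentile pair.
#' @export
site_statistics <- function(sites) {
  if (nrow(sites) < 2) abort("need at least 2 sites for percentile bounds")
  q <- function(v) unname(quantile(v, c(0.1, 0.9), type = 7))
  st <- list(qv = q(sites$size), qa = q(sites$avg_dist), qs = q(sites$std_dist))
  if (any(map_dbl(st, ~ .x[2] - .x[1]) <= 0)) {
    abort(paste(
      "degenerate percentile bounds (all sites have identical shape);",
      "provide a more varied site collection"
    ))
  }
  class(st) <- "site_stats"
  st
}

#' @export
print.site_stats <- function(x, ...) {
  cat(sprintf(
    "<site_stats> size [%.2f, %.2f], avg dist [%.2f, %.2f] A, sd dist [%.2f, %.2f] A\n",
    x$qv[1], x$qv[2], x$qa[1], x$qa[2], x$qs[1], x$qs[2]
  ))
  invisible(x)
}

#' Connected components of a point cloud
#'
#' Two points are connected iff their distance is strictly below
#' `cutoff`; components are taken over the transitive closure.
#'
#' @param points Matrix (or tibble with `x`, `y`, `z`) of 3D points.
#' @param cutoff Distance cutoff in Angstrom (default 4, strict).
#' @return List of integer index vectors, one per component.
#' @export
components <- function(points, cutoff = 4.0) {
  xyz <- if (is.matrix(points)) points else point_matrix(points)
  n <- nrow(xyz)
  if (n == 0) return(list())
  edges <- list()
  blk <- 512L
  for (s in seq(1, n, by = blk)) {
    rows <- s:min(s + blk - 1, n)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * tcrossprod(xyz[rows, , drop = FALSE], xyz)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    hit[, 1] <- rows[hit[, 1]]
    edges[[length(edges) + 1]] <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  unname(split(seq_len(n), memb))
}

#' Indices of points whose prediction exceeds a threshold
#'
#' @param yp Numeric predictions in \[0, 1\].
#' @param c Threshold (strict: kept iff `yp > c`).
#' @return Integer indices.
#' @export
select_ligandable_points <- function(yp, c) {
  which(yp > c)
}

#' Decision ladder for the adaptive grouping loop
#'
#' Evaluated after each iteration, in order: iteration cap (hard stop
#' after 20), clustered fraction above 0.2 (raise the threshold), no
#' clusters (lower it), then the three shape properties of the current
#' clusters against the 10th/90th percentile bounds; anything else lowers
#' the threshold.
#'
#' @param cluster_props Tibble with one row per current cluster
#'   (`size`, `avg_dist`, `std_dist`).
#' @param iteration Completed iteration count.
#' @param n_points Remaining (non-extracted) point count.
#' @param stats A [site_statistics()] object.
#' @param avg_upper_literal The average-distance upper-bound branch admits
#'   two readings; the default `FALSE` uses the symmetric one (above the
#'   90th percentile raises the threshold), `TRUE` the literal alternative
#'   (below the 90th percentile raises it, which shadows the lower-bound
#'   branch).
#' @return One of `"break"`, `"increase_a"`, `"decrease_b"`.
#' @export
compute_condition <- function(cluster_props, iteration, n_points, stats,
                              avg_upper_literal = FALSE) {
  total_clustered <- sum(cluster_props$size)
  frac <- if (total_clustered == 0) 0 else total_clustered / max(n_points, 1e-12)
  if (iteration > 20) return("break")
  if (frac > 0.2) return("increase_a")
  if (nrow(cluster_props) == 0) return("decrease_b")
  if (max(cluster_props$size) < stats$qv[1]) return("decrease_b")
  if (max(cluster_props$size) > stats$qv[2]) return("increase_a")
  if (max(cluster_props$avg_dist) < stats$qa[1]) return("decrease_b")
  au <- if (avg_upper_literal) {
    max(cluster_props$avg_dist) < stats$qa[2]
  } else {
    max(cluster_props$avg_dist) > stats$qa[2]
  }
  if (au) return("increase_a")
  if (max(cluster_props$std_dist) < stats$qs[1]) return("decrease_b")
  if (max(cluster_props$std_dist) > stats$qs[2]) return("increase_a")
  "decrease_b"
}

#' Group pointwise ligandability predictions into binding sites
#'
#' Adaptive thresholding loop: points predicted above the threshold `c`
#' are clustered into connected components (4 Angstrom cutoff); clusters
#' whose size, average center distance and distance standard deviation
#' all fall inclusively within the 10th-90th percentile bounds of
#' `stats` are accepted as binding sites and their points removed. The
#' threshold is then moved inside the interval `(a, b)` — raised
#' (`a <- a + 0.2 (b - a)`) when clusters are too large or too loose,
#' lowered (`b <- b + 0.2 (a - b)`) when they are too small or absent,
#' with `c = (a + b) / 2` — and the loop repeats until the decision
#' ladder says stop (at most 21 iterations).
#'
#' @param yp Numeric vector of per-point predictions in \[0, 1\].
#' @param points Matrix or tibble of the corresponding 3D points.
#' @param stats A [site_statistics()] object.
#' @param cutoff Component distance cutoff (default 4).
#' @param a0,b0,c0 Initial threshold interval and threshold
#'   (defaults 0.3, 1, 0.5).
#' @param avg_upper_literal See [compute_condition()].
#' @return A `binding_sites` tibble, ordered by descending size:
#'   `site_id`, `point_indices` (list of indices into `points`),
#'   `x`, `y`, `z` (geometric center), `size`, `avg_dist`, `std_dist`.
#'   The iteration trace (`iteration`, `a`, `b`, `c`, `condition`,
#'   `n_accepted`) is attached as attribute `"trace"`.
#' @export
binding_sites <- function(yp, points, stats, cutoff = 4.0, a0 = 0.3, b0 = 1,
                          c0 = 0.5, avg_upper_literal = FALSE) {
  xyz <- if (is.matrix(points)) points else point_matrix(points)
  stopifnot(length(yp) == nrow(xyz), all(yp >= 0 & yp <= 1))
  a <- a0; b <- b0; cc <- c0
  remaining <- seq_len(nrow(xyz))
  lig <- remaining[yp[remaining] > cc]
  accepted <- list()
  iteration <- 0
  condition <- "continue"
  trace <- list()
  while (condition != "break") {
    cl <- if (length(lig) > 0) {
      map(components(xyz[lig, , drop = FALSE], cutoff), ~ lig[.x])
    } else {
      list()
    }
    props <- if (length(cl) > 0) {
      bind_rows(map(cl, function(idx) {
        p <- site_props_one(xyz[idx, , drop = FALSE])
        tibble(size = p$size, avg_dist = p$avg_dist, std_dist = p$std_dist)
      }))
    } else {
      tibble(size = numeric(), avg_dist = numeric(), std_dist = numeric())
    }
    fits <- props$size >= stats$qv[1] & props$size <= stats$qv[2] &
      props$avg_dist >= stats$qa[1] & props$avg_dist <= stats$qa[2] &
      props$std_dist >= stats$qs[1] & props$std_dist <= stats$qs[2]
    n_acc <- sum(fits)
    if (n_acc > 0) {
      accepted <- c(accepted, cl[fits])
      remaining <- setdiff(remaining, unlist(cl[fits]))
    }
    if (condition == "increase_a") {
      a <- 0.2 * (b - a) + a
    } else if (condition == "decrease_b") {
      b <- 0.2 * (a - b) + b
    }
    cc <- (a + b) / 2
    iteration <- iteration + 1
    lig <- remaining[yp[remaining] > cc]
    condition <- compute_condition(props, iteration, length(remaining), stats,
                                   avg_upper_literal)
    trace[[iteration]] <- tibble(
      iteration = iteration, a = a, b = b, c = cc, condition = condition,
      n_accepted = n_acc
    )
  }
  out <- sites_from_indices(accepted, xyz)
  attr(out, "trace") <- bind_rows(trace)
  out
}

#' Build a binding-sites table from index sets
#'
#' @param index_sets List of integer vectors indexing into `points`.
#' @param points Matrix or tibble of 3D points.
#' @return A `binding_sites` tibble ordered by descending size.
#' @export
sites_from_indices <- function(index_sets, points) {
  xyz <- if (is.matrix(points)) points else point_matrix(points)
  rows <- map(index_sets, function(idx) {
    p <- site_props_one(xyz[idx, , drop = FALSE])
    tibble(
      point_indices = list(sort(idx)), x = p$center[1], y = p$center[2],
      z = p$center[3], size = p$size, avg_dist = p$avg_dist,
      std_dist = p$std_dist
    )
  })
  out <- if (length(rows) > 0) bind_rows(rows) else tibble(
    point_indices = list(), x = numeric(), y = numeric(), z = numeric(),
    size = integer(), avg_dist = numeric(), std_dist = numeric()
  )
  out <- out[order(-out$size), ]
  out <- mutate(out, site_id = row_number(), .before = 1)
  class(out) <- c("binding_sites", class(out))
  out
}

#' Ground-truth binding sites of a labeled chain
#'
#' One site per retained ligand (the points it labels), sites sharing
#' points merged; returned in the same tabular form as predictions.
#'
#' @param points Labeled `surface_points`.
#' @param ligands The chain's ligands.
#' @param threshold Labeling threshold (default 1e-4).
#' @return A `binding_sites` tibble.
#' @export
true_sites_table <- function(points, ligands, threshold = 1e-4) {
  sites_from_indices(true_site_indices(points, ligands, threshold), points)
}
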