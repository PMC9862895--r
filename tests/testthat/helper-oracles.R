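# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Exhaustive local-alignment score: enumerate every monotone matching of
# positions (each matched pair is an aligned column; unmatched residues
# between consecutive columns go into affine gaps, one run per sequence,
# which is the cheapest arrangement). The local score is the best over
# all non-empty matchings, floored at 0.
sw_enumerate <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  best <- 0
  for (k in seq_len(min(m, n))) {
    ia <- utils::combn(seq_len(m), k)
    ib <- utils::combn(seq_len(n), k)
    gapcost <- function(idx) {
      if (k == 1) return(numeric(ncol(idx)))
      d <- idx[-1, , drop = FALSE] - idx[-k, , drop = FALSE] - 1
      colSums(ifelse(d > 0, gap_open + gap_extend * d, 0))
    }
    ga <- gapcost(ia)
    gb <- gapcost(ib)
    for (ci in seq_len(ncol(ia))) {
      subm <- matrix(
        sub[cbind(rep(av[ia[, ci]], times = ncol(ib)), bv[as.vector(ib)])],
        nrow = k
      )
      sc <- colSums(subm) - ga[ci] - gb
      best <- max(best, max(sc))
    }
  }
  best
}

# connected components by boolean-matrix transitive closure
components_closure <- function(xyz, cutoff = 4) {
  n <- nrow(xyz)
  adj <- as.matrix(dist(xyz)) < cutoff
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  memb <- integer(n)
  lab <- 0
  for (i in seq_len(n)) {
    if (memb[i] == 0) {
      lab <- lab + 1
      memb[which(adj[i, ])] <- lab
    }
  }
  unname(split(seq_len(n), memb))
}

# union-find over an edge list
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1])
      rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), match(roots, unique(roots))))
}

# canonical form for comparing partitions
canon_partition <- function(parts) {
  parts <- lapply(unname(parts), function(p) as.integer(sort(p)))
  parts[order(vapply(parts, min, 1L))]
}
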