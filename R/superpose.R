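#' Root mean square deviation of paired points
#'
#' `sqrt(mean(squared distances))` over matched pairs.
#'
#' @param p1,p2 Numeric matrices of matched 3D points (same dimensions).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(p1, p2) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  if (!all(dim(p1) == dim(p2))) abort("point lists must have equal length")
  if (nrow(p1) < 1) abort("need at least one pair")
  sqrt(mean(rowSums((p1 - p2)^2)))
}

# Kabsch least-squares rigid-body fit: rotation + translation mapping
# `mobile` onto `fixed`, proper rotation enforced (det = +1)
kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  H <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cf - as.vector(R %*% cm)
  list(rotation = R, translation = t_vec)
}

apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

#' Superpose a mobile chain onto a reference chain
#'
#' The two sequences are locally aligned; if similarity and covering (on
#' both chains) exceed the gates, the C-alpha pairs from aligned non-gap
#' columns are fitted with a Kabsch least-squares rigid-body superposition.
#'
#' @param ref,mobile `chain_entry` objects with at least 3 C-alpha atoms.
#' @param seqid Similarity gate (strict lower bound, default 0.9).
#' @param overlap Covering gate on both chains (strict, default 0.9).
#' @return An object of class `superposition` with fields `rotation`
#'   (3x3, det +1), `translation`, `matched_pairs` (two-column index
#'   matrix into the chains' C-alpha lists), and `rmsd`; or `NULL` when a
#'   gate fails or fewer than 3 pairs match.
#' @export
superpose <- function(ref, mobile, seqid = 0.9, overlap = 0.9) {
  aln <- smith_waterman(ref$sequence, mobile$sequence)
  if (aln$N == 0) return(NULL)
  s <- similarity(aln)
  c_ref <- covering(nchar(ref$sequence), aln$span_a)
  c_mob <- covering(nchar(mobile$sequence), aln$span_b)
  if (s <= seqid || c_ref <= overlap || c_mob <= overlap) return(NULL)
  va <- strsplit(aln$aligned_a, "")[[1]]
  vb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- aln$span_a[1] - 1 + cumsum(va != "-")
  ib <- aln$span_b[1] - 1 + cumsum(vb != "-")
  both <- va != "-" & vb != "-"
  pairs <- cbind(ref = ia[both], mobile = ib[both])
  if (nrow(pairs) < 3) return(NULL)
  fit <- kabsch(ref$ca_coords[pairs[, 1], , drop = FALSE],
                mobile$ca_coords[pairs[, 2], , drop = FALSE])
  moved <- apply_transform(mobile$ca_coords[pairs[, 2], , drop = FALSE],
                           fit$rotation, fit$translation)
  structure(
    list(
      rotation = fit$rotation, translation = fit$translation,
      matched_pairs = pairs,
      rmsd = rmsd(ref$ca_coords[pairs[, 1], , drop = FALSE], moved)
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d matched pairs, rmsd %.4f A\n",
              nrow(x$matched_pairs), x$rmsd))
  invisible(x)
}
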