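#' Cluster sequences by alignment similarity and covering
#'
#' All unordered pairs are aligned once (inputs in lexicographic order, so
#' results are symmetric); an edge joins sequences i and j iff the three
#' strict inequalities hold: similarity `S > s_bar` and covering `> c_bar`
#' on both sequences. Clusters are the connected components of that graph;
#' singletons are allowed.
#'
#' @param seqs Character vector of sequences (optionally named).
#' @param s_bar Similarity lower bound (strict; default 0.8).
#' @param c_bar Covering lower bound (strict; default 0.9).
#' @param substitution,gap_open,gap_extend Passed to [smith_waterman()].
#' @return An object of class `cluster_set`: a tibble `members` with
#'   columns `sequence_id`, `cluster_id`, the pairwise table `pairs`
#'   (`i`, `j`, `similarity`, `cover_i`, `cover_j`, `edge`), and the
#'   thresholds in `params`.
#' @export
build_cluster_set <- function(seqs, s_bar = 0.8, c_bar = 0.9,
                              substitution = NULL, gap_open = 11,
                              gap_extend = 1) {
  stopifnot(length(seqs) >= 1)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(seqs))
  z <- length(seqs)
  pairs <- NULL
  if (z >= 2) {
    idx <- utils::combn(z, 2)
    rows <- map(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      # canonical input order guarantees S(A,B) = S(B,A)
      swap <- seqs[i] > seqs[j]
      a <- if (swap) seqs[j] else seqs[i]
      b <- if (swap) seqs[i] else seqs[j]
      aln <- smith_waterman(a, b, substitution, gap_open, gap_extend)
      ca <- covering(nchar(a), aln$span_a)
      cb <- covering(nchar(b), aln$span_b)
      tibble(
        i = i, j = j, similarity = similarity(aln),
        cover_i = if (swap) cb else ca,
        cover_j = if (swap) ca else cb
      )
    })
    pairs <- bind_rows(rows)
    pairs$edge <- pairs$similarity > s_bar & pairs$cover_i > c_bar &
      pairs$cover_j > c_bar
  } else {
    pairs <- tibble(
      i = integer(), j = integer(), similarity = numeric(),
      cover_i = numeric(), cover_j = numeric(), edge = logical()
    )
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$i[pairs$edge], to = pairs$j[pairs$edge]),
    directed = FALSE, vertices = data.frame(name = seq_len(z))
  )
  comp <- igraph::components(g)$membership
  members <- tibble(
    sequence_id = ids,
    cluster_id = as.integer(comp[as.character(seq_len(z))])
  )
  structure(
    list(members = members, pairs = pairs,
         params = list(s_bar = s_bar, c_bar = c_bar)),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d sequences in %d clusters (s_bar = %g, c_bar = %g)\n",
    nrow(x$members), length(unique(x$members$cluster_id)),
    x$params$s_bar, x$params$c_bar
  ))
  invisible(x)
}

#' @rdname build_cluster_set
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @export
tidy.cluster_set <- function(x, ...) x$members

#' @rdname build_cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  sizes <- table(x$members$cluster_id)
  tibble(
    n_sequences = nrow(x$members), n_clusters = length(sizes),
    n_singletons = sum(sizes == 1), max_cluster_size = max(sizes)
  )
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), sub("\\s.*", "", names(s)))
}

#' Write cluster assignments to a two-column TSV
#'
#' @param cs A `cluster_set`.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(cs, path) {
  utils::write.table(cs$members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
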