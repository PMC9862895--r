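#' Smith-Waterman local alignment of two amino-acid sequences
#'
#' Optimal local alignment under a substitution matrix with affine gaps:
#' a gap of length L costs `gap_open + L * gap_extend`. Letters outside the
#' 20-letter alphabet are mapped to X and scored with the matrix's X rows.
#' When no alignment scores positively the result has score 0 and empty
#' spans.
#'
#' @param a,b Amino-acid sequences (non-empty strings).
#' @param substitution 20+ letter score matrix; default BLOSUM62.
#' @param gap_open,gap_extend Affine gap costs (positive numbers; defaults
#'   11 and 1).
#' @return An object of class `alignment_result`: aligned strings (with
#'   `-` gap characters), `score`, 1-based inclusive spans `span_a`,
#'   `span_b`, and aligned length `N`.
#' @export
smith_waterman <- function(a, b, substitution = NULL, gap_open = 11,
                           gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  if (is.null(substitution)) substitution <- blosum62()
  clean <- function(s) {
    s <- toupper(s)
    letters_ok <- rownames(substitution)
    v <- strsplit(s, "")[[1]]
    v[!v %in% letters_ok] <- "X"
    paste(v, collapse = "")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(clean(a)), Biostrings::AAString(clean(b)),
    substitutionMatrix = substitution, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local"
  )
  sc <- Biostrings::score(aln)
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  if (sc <= 0 || nchar(pa) == 0) {
    return(structure(
      list(aligned_a = "", aligned_b = "", score = 0,
           span_a = c(NA_integer_, NA_integer_),
           span_b = c(NA_integer_, NA_integer_), N = 0L),
      class = "alignment_result"
    ))
  }
  structure(
    list(
      aligned_a = pa, aligned_b = pb, score = sc,
      span_a = c(Biostrings::start(Biostrings::pattern(aln)),
                 Biostrings::end(Biostrings::pattern(aln))),
      span_b = c(Biostrings::start(Biostrings::subject(aln)),
                 Biostrings::end(Biostrings::subject(aln))),
      N = nchar(pa)
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %g, N = %d\n", x$score, x$N))
  if (x$N > 0) cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

blosum62_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#' @return Integer score matrix over the extended amino-acid alphabet.
#' @export
blosum62 <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

#' Fraction of identical aligned positions
#'
#' The similarity of two sequences given their local alignment: the number
#' of positions where the aligned characters are equal (and neither is a
#' gap), divided by the aligned length N. An empty alignment has
#' similarity 0.
#'
#' @param aln An `alignment_result`.
#' @return A fraction in \[0, 1\].
#' @export
similarity <- function(aln) {
  if (aln$N == 0) return(0)
  va <- strsplit(aln$aligned_a, "")[[1]]
  vb <- strsplit(aln$aligned_b, "")[[1]]
  sum(va == vb & va != "-") / aln$N
}

#' Covering of a sequence by its aligned region
#'
#' For a sequence of length `n` whose locally aligned region spans 1-based
#' inclusive indices `(n1, n2)`, the covering is `(n2 - n1 + 1) / n`.
#'
#' @param seq_len Length of the original sequence.
#' @param span Integer pair `(n1, n2)`; an empty span (NA) gives covering 0.
#' @return A fraction in \[0, 1\].
#' @export
covering <- function(seq_len, span) {
  if (anyNA(span)) return(0)
  if (span[1] < 1 || span[2] < span[1] || span[2] > seq_len) {
    abort("span outside sequence")
  }
  (span[2] - span[1] + 1) / seq_len
}
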