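# Pairwise alignment primitives shared by compression, hit extension and
# the fine search. Dynamic programming lives in src/alignment.cpp; these
# wrappers validate inputs and assemble alignment_result objects.

.alignment_result <- function(score, aligned_a, aligned_b,
                              query_span, subject_span, evalue = NA_real_) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  len <- length(ca)
  ident <- if (len) sum(ca == cb & ca != "-") / len else 0
  structure(list(score = as.integer(score),
                 aligned_query = aligned_a,
                 aligned_subject = aligned_b,
                 identity_fraction = ident,
                 length = len,
                 query_span = as.integer(query_span),
                 subject_span = as.integer(subject_span),
                 evalue = evalue),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: score %d, length %d, identity %.1f%%\n",
              x$score, x$length, 100 * x$identity_fraction))
  if (x$length) {
    cat(" query  ", x$aligned_query, "\n", "subject", x$aligned_subject, "\n")
  }
  invisible(x)
}

.check_pair <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    stop("alignment takes two single strings", call. = FALSE)
  if (!nzchar(a) || !nzchar(b))
    stop("cannot align an empty sequence", call. = FALSE)
}

#' Needleman-Wunsch global alignment with a linear gap penalty
#'
#' Computes a maximum-score global alignment. Traceback ties are broken
#' deterministically (diagonal, then gap in subject, then gap in query), so
#' repeated runs give identical alignments.
#'
#' @param a,b amino-acid strings.
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_penalty positive cost per gapped residue (default 11).
#' @return An `alignment_result` with score, aligned strings, identity
#'   fraction and spans covering both full inputs.
#' @export
needleman_wunsch <- function(a, b, matrix = blosum62(), gap_penalty = 11L) {
  .check_pair(a, b)
  stopifnot(gap_penalty > 0)
  al <- .nw_align_cpp(a, b, matrix, as.integer(gap_penalty))
  .alignment_result(al$score, al$aligned_a, al$aligned_b,
                    query_span = c(1L, nchar(a)),
                    subject_span = c(1L, nchar(b)))
}

#' Global-alignment similarity (identity fraction)
#'
#' The fraction of identical columns over the full Needleman-Wunsch
#' alignment length, with the module's default matrix and gap penalty. This
#' is the quantity compared against the redundancy thresholds.
#'
#' @inheritParams needleman_wunsch
#' @return A number in `[0, 1]`.
#' @export
nw_similarity <- function(a, b, matrix = blosum62(), gap_penalty = 11L) {
  needleman_wunsch(a, b, matrix, gap_penalty)$identity_fraction
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Gotoh's algorithm; a gap of length k costs `gap_open + k * gap_extend`.
#' A best score of zero means no positive-scoring local alignment exists and
#' is reported as a no-hit result (empty alignment, spans of zero).
#'
#' @inheritParams needleman_wunsch
#' @param gap_open,gap_extend positive affine gap parameters (defaults 11, 1).
#' @return An `alignment_result`; `score == 0` encodes "no hit".
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 11L,
                           gap_extend = 1L) {
  .check_pair(a, b)
  stopifnot(gap_open > 0, gap_extend > 0)
  al <- .sw_align_cpp(a, b, matrix, as.integer(gap_open),
                      as.integer(gap_extend))
  .alignment_result(al$score, al$aligned_a, al$aligned_b,
                    query_span = c(al$a_start, al$a_end),
                    subject_span = c(al$b_start, al$b_end))
}

#' Ungapped x-drop extension around an anchored match
#'
#' Extends an anchor left and right without gaps, stopping a direction when
#' the running score falls more than `xdrop` below its running maximum, and
#' keeping the maximum-scoring extension in each direction.
#'
#' @param query,subject amino-acid strings.
#' @param q_anchor,s_anchor 1-based anchor start positions.
#' @param anchor_len anchor length (residues).
#' @param matrix substitution matrix.
#' @param xdrop positive drop-off threshold in raw score units (default 20).
#' @return A list with `score`, `q_span` and `s_span` (1-based inclusive).
#' @export
ungapped_xdrop_extend <- function(query, subject, q_anchor, s_anchor,
                                  anchor_len, matrix = blosum62(),
                                  xdrop = 20L) {
  .check_pair(query, subject)
  stopifnot(xdrop > 0)
  r <- .xdrop_extend_cpp(query, subject, as.integer(q_anchor),
                         as.integer(s_anchor), as.integer(anchor_len),
                         matrix, as.integer(xdrop))
  list(score = r$score,
       q_span = c(r$a_start, r$a_end),
       s_span = c(r$b_start, r$b_end))
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the standard published gapped
#' constants for BLOSUM62 with gap open 11 / extend 1
#' (`lambda = 0.267`, `K = 0.041`).
#'
#' @param raw_score non-negative raw alignment score.
#' @param query_len query length m (residues).
#' @param db_len total database residues n.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Expected number of chance alignments with at least this score.
#' @export
evalue <- function(raw_score, query_len, db_len, lambda = 0.267, K = 0.041) {
  stopifnot(all(raw_score >= 0), query_len > 0, db_len > 0)
  K * query_len * db_len * exp(-lambda * raw_score)
}

#' Hamming distance between equal-length strings
#'
#' @param a,b strings of equal length (typically reduced-alphabet seeds).
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("Hamming distance requires equal lengths", call. = FALSE)
  if (!nchar(a)) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
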