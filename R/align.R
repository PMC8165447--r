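# R-side wrappers over the affine-gap DP kernel in src/align.cpp.

.check_residues <- function(s, id, mat) {
  chars <- strsplit(s, "")[[1L]]
  bad <- which(!chars %in% rownames(mat))
  if (length(bad))
    stop(sprintf("scoring error: unknown residue '%s' at position %d in '%s'",
                 chars[bad[1L]], bad[1L], id))
  chars
}

.pair_score_matrix <- function(a_chars, b_chars, mat) {
  matrix(mat[cbind(rep(a_chars, times = length(b_chars)),
                   rep(b_chars, each = length(a_chars)))],
         nrow = length(a_chars))
}

.aligned_strings <- function(a_chars, b_chars, res) {
  a_row <- ifelse(res$a > 0L, a_chars[pmax(res$a, 1L)], "-")
  b_row <- ifelse(res$b > 0L, b_chars[pmax(res$b, 1L)], "-")
  list(a = paste(a_row, collapse = ""), b = paste(b_row, collapse = ""))
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Exact affine-gap local alignment: the first residue of a gap costs
#' `gapOpen + gapExtend`, each further residue `gapExtend`. Traceback is
#' deterministic, preferring diagonal, then up, then left, and gap openings
#' over extensions. A pair with no positive-scoring local alignment returns
#' score 0 and an empty alignment.
#'
#' @param query,subject protein sequences: `AAString`, single-record
#'   `AAStringSet`, or plain character.
#' @param substitutionMatrix residue score matrix (default BLOSUM62).
#' @param gapOpen,gapExtend positive gap penalties.
#' @return A list: `score`, gapped `query_aln`/`subject_aln` strings, and
#'   1-based inclusive `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (all `NA` for an empty alignment).
#' @export
#' @examples
#' smithWaterman("HEAGAWGHEE", "PAWHEAE")$score
smithWaterman <- function(query, subject, substitutionMatrix = blosum62(),
                          gapOpen = 10, gapExtend = 1) {
  q <- .as_seq_string(query); s <- .as_seq_string(subject)
  if (nchar(q) == 0L || nchar(s) == 0L) stop("sequences must be non-empty")
  qc <- .check_residues(q, "query", substitutionMatrix)
  sc <- .check_residues(s, "subject", substitutionMatrix)
  S <- .pair_score_matrix(qc, sc, substitutionMatrix)
  res <- .dp_align_cpp(S, gapOpen, gapExtend, TRUE)
  aln <- .aligned_strings(qc, sc, res)
  list(score = res$score, query_aln = aln$a, subject_aln = aln$b,
       query_start = res$a_start, query_end = res$a_end,
       subject_start = res$b_start, subject_end = res$b_end)
}

#' Optimal global alignment (Needleman-Wunsch)
#'
#' Affine-gap global alignment with end gaps charged; same gap convention and
#' tie-breaking as [smithWaterman()].
#'
#' @inheritParams smithWaterman
#' @param a,b sequences to align.
#' @return A list: `score`, gapped `a_aln`/`b_aln` strings, and `identity_pct`
#'   (identical columns / alignment length, in percent).
#' @export
globalAlign <- function(a, b, substitutionMatrix = blosum62(),
                        gapOpen = 10, gapExtend = 1) {
  as_ <- .as_seq_string(a); bs_ <- .as_seq_string(b)
  if (nchar(as_) == 0L || nchar(bs_) == 0L) stop("sequences must be non-empty")
  ac <- .check_residues(as_, "a", substitutionMatrix)
  bc <- .check_residues(bs_, "b", substitutionMatrix)
  S <- .pair_score_matrix(ac, bc, substitutionMatrix)
  res <- .dp_align_cpp(S, gapOpen, gapExtend, FALSE)
  aln <- .aligned_strings(ac, bc, res)
  cols_a <- strsplit(aln$a, "")[[1L]]
  cols_b <- strsplit(aln$b, "")[[1L]]
  ident <- 100 * sum(cols_a == cols_b & cols_a != "-") / length(cols_a)
  list(score = res$score, a_aln = aln$a, b_aln = aln$b, identity_pct = ident)
}

.as_seq_string <- function(x) {
  if (is.character(x)) return(toupper(x[[1L]]))
  if (is(x, "XStringSet")) return(as.character(x[[1L]]))
  as.character(x)
}
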