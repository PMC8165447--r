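# FASTA I/O. Reading goes through Biostrings and is tolerant of any line
# wrapping; validation enforces the declared molecule alphabet (DNA: ACGTN,
# protein: the 20 residues + X). Coordinates everywhere in this package are
# 1-based inclusive.

#' Read a FASTA file with alphabet validation
#'
#' @param path path to a FASTA file.
#' @param molecule `"dna"` or `"protein"`; controls the returned container
#'   (`DNAStringSet` / `AAStringSet`) and the permitted alphabet (DNA: ACGTN;
#'   protein: the 20 standard residues plus X).
#' @return A `DNAStringSet` or `AAStringSet`, names set to the first header
#'   token, with a `description` metadata column holding the header remainder.
#'   Residues are uppercased; record order is preserved.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a some gene", "ACGT"), tf)
#' readFasta(tf, "dna")
readFasta <- function(path, molecule = c("dna", "protein")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA format error: empty file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA format error: empty sequence id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("FASTA format error: duplicate id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("FASTA format error: empty sequence for id ",
         ids[which(nchar(seqs) == 0L)[1L]])
  allowed <- if (molecule == "dna") "ACGTN" else paste0(paste(AA20, collapse = ""), "X")
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("FASTA format error: illegal %s character '%s' at position %d in record '%s'",
                 molecule, substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  out <- if (molecule == "dna") DNAStringSet(setNames(seqs, ids))
         else AAStringSet(setNames(seqs, ids))
  mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' Writes 60-column wrapped FASTA; a `description` metadata column, when
#' present, is appended to the header after the id.
#'
#' @param x a `DNAStringSet` or `AAStringSet` with non-empty unique names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all records must be named")
  y <- x
  desc <- mcols(x)$description
  if (!is.null(desc)) {
    keep <- !is.na(desc) & desc != ""
    names(y)[keep] <- paste(names(x)[keep], desc[keep])
  }
  writeXStringSet(y, path, width = 60L)
  invisible(path)
}
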