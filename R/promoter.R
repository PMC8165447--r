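# Strand-aware promoter extraction and IUPAC consensus scanning. Promoter
# offsets are 1-based on the returned promoter string, which always reads
# 5' -> 3' toward the translation start (ATG).

#' Default cis-element motif table
#'
#' A PlantCARE-style inventory of named elements with IUPAC consensus strings
#' in the three functional categories (growth and development, stress,
#' hormone). The consensus strings are editable defaults: correctness of the
#' scanner is defined against whatever table is supplied, and no element's
#' consensus is a substring of another's, so planted occurrences stay
#' unambiguous.
#'
#' @return A [MotifTable-class].
#' @export
defaultMotifTable <- function() {
  MotifTable(
    element = c("ABRE", "CGTCA-motif", "TGACG-motif", "GARE-motif",
                "TATC-box", "TGA-element", "AuxRR-core", "TCA-element",
                "G-box", "Box4", "MRE", "O2-site", "circadian", "MSA-like",
                "MBS", "ARE", "LTR", "GC-motif", "TC-rich"),
    consensus = c("TACGTGTC", "CGTCA", "TGACG", "TCTGTTG",
                  "TATCCCA", "AACGAC", "GGTCCAT", "CCATCTTTTT",
                  "CACGTG", "ATTAAT", "AACCTAA", "GATGACATGG", "CAAAGATATC",
                  "TCCAACGGT",
                  "CAACTG", "AAACCA", "CCGAAA", "CCCCCG", "ATTTTCTTCA"),
    category = c(rep("hormone", 8L),
                 rep("growth_development", 6L),
                 rep("stress", 5L)))
}

#' Extract promoter sequences upstream of the translation start
#'
#' For a plus-strand gene the promoter is the `lengthBp` bases immediately 5'
#' of the first CDS base, in genomic orientation; for a minus-strand gene it
#' is the `lengthBp` bases immediately 3' (genomically) of the CDS end,
#' reverse-complemented. Either way the returned string reads 5' -> 3' toward
#' the ATG. Promoters running off the chromosome edge are truncated and
#' flagged.
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param genes gene models (`GRanges` from [geneModels()]); every gene needs
#'   at least one CDS part.
#' @param lengthBp promoter length in bp (default 1500; the study convention
#'   allows 1500-2000).
#' @return A `DNAStringSet` named by gene id with metadata columns
#'   `truncated` (logical), `genomic_start`, `genomic_end` (1-based inclusive
#'   genomic footprint; `NA` for empty promoters).
#' @export
extractPromoters <- function(genome, genes, lengthBp = 1500L) {
  lengthBp <- as.integer(lengthBp)
  ids <- mcols(genes)$gene_id
  seqs <- character(length(genes))
  trunc <- logical(length(genes))
  gs <- ge <- rep(NA_integer_, length(genes))
  for (i in seq_along(genes)) {
    chr <- as.character(seqnames(genes)[i])
    if (!chr %in% names(genome))
      stop("chromosome '", chr, "' absent from genome for gene ", ids[i])
    chrlen <- nchar(as.character(genome[[chr]]))
    p <- mcols(genes)$cds[[i]]
    if (length(p) == 0L) stop("gene ", ids[i], " has no CDS; ATG anchor unknown")
    str <- as.character(strand(genes)[i])
    if (str == "+") {
      anchor <- min(start(p))          # first CDS base
      e <- anchor - 1L
      s <- anchor - lengthBp
      if (s < 1L) { s <- 1L; trunc[i] <- TRUE }
      if (e < s) { seqs[i] <- ""; trunc[i] <- TRUE; next }
      seqs[i] <- substr(as.character(genome[[chr]]), s, e)
      gs[i] <- s; ge[i] <- e
    } else {
      anchor <- max(end(p))            # first CDS base, genomic end
      s <- anchor + 1L
      e <- anchor + lengthBp
      if (e > chrlen) { e <- chrlen; trunc[i] <- TRUE }
      if (e < s) { seqs[i] <- ""; trunc[i] <- TRUE; next }
      seqs[i] <- as.character(reverseComplement(
        DNAString(substr(as.character(genome[[chr]]), s, e))))
      gs[i] <- s; ge[i] <- e
    }
  }
  out <- DNAStringSet(setNames(seqs, ids))
  mcols(out)$truncated <- trunc
  mcols(out)$genomic_start <- gs
  mcols(out)$genomic_end <- ge
  out
}

.iupac_regex <- function(consensus) {
  chars <- strsplit(consensus, "")[[1L]]
  paste(vapply(chars, function(ch) {
    ex <- IUPAC_DNA[[ch]]
    if (is.null(ex)) stop("invalid IUPAC code: ", ch)
    if (length(ex) == 1L) ex else paste0("[", paste(ex, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

#' Scan promoters for cis-elements
#'
#' Exact IUPAC consensus matching; overlapping matches are all reported. With
#' `strandPolicy = "both"` each motif is additionally matched against the
#' reverse complement of the promoter and mapped back to promoter
#' coordinates. The default is `"given_only"`, because palindromic partner
#' motifs (e.g. CGTCA/TGACG) are distinct table entries and both-strand
#' scanning would double-count them.
#'
#' @param promoters `DNAStringSet` from [extractPromoters()] (or any named
#'   DNA set).
#' @param motifs a [MotifTable-class].
#' @param strandPolicy `"given_only"` (default) or `"both"`.
#' @return data.frame of hits: `gene_id`, `element`, `offset` (1-based on the
#'   promoter string), `strand` (`"+"` or `"-"` relative to the promoter).
#' @export
scanCisElements <- function(promoters, motifs,
                            strandPolicy = c("given_only", "both")) {
  strandPolicy <- match.arg(strandPolicy)
  stopifnot(is(motifs, "MotifTable"))
  tb <- motifTable(motifs)
  hits <- list()
  pseqs <- as.character(promoters)
  for (g in seq_along(pseqs)) {
    pseq <- pseqs[g]
    if (nchar(pseq) == 0L) next
    gid <- names(pseqs)[g]
    for (m in seq_len(nrow(tb))) {
      rex <- .iupac_regex(tb$consensus[m])
      w <- nchar(tb$consensus[m])
      starts <- .overlapping_starts(pseq, rex)
      if (length(starts))
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = gid, element = tb$element[m], offset = starts,
          strand = "+", stringsAsFactors = FALSE)
      if (strandPolicy == "both") {
        rc <- as.character(reverseComplement(DNAString(pseq)))
        starts_rc <- .overlapping_starts(rc, rex)
        if (length(starts_rc))
          hits[[length(hits) + 1L]] <- data.frame(
            gene_id = gid, element = tb$element[m],
            offset = nchar(pseq) - (starts_rc + w - 1L) + 1L,
            strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), element = character(),
                      offset = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$gene_id, out$element, out$offset), , drop = FALSE]
}

.overlapping_starts <- function(s, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Census of cis-element hits
#'
#' @param hits data.frame from [scanCisElements()].
#' @param motifs the [MotifTable-class] the hits were produced with.
#' @return A list: `perGene` (genes x elements count matrix), `perElement`
#'   (named totals per element), `perCategory` (named totals per category).
#'   `sum(perCategory) == nrow(hits)` always.
#' @export
censusByCategory <- function(hits, motifs) {
  stopifnot(is(motifs, "MotifTable"))
  tb <- motifTable(motifs)
  unknown <- setdiff(unique(hits$element), tb$element)
  if (length(unknown))
    stop("hits reference unknown element(s): ", paste(unknown, collapse = ", "))
  genes <- sort(unique(hits$gene_id))
  perGene <- matrix(0L, nrow = length(genes), ncol = nrow(tb),
                    dimnames = list(genes, tb$element))
  if (nrow(hits)) {
    tt <- table(hits$gene_id, factor(hits$element, levels = tb$element))
    perGene[rownames(tt), colnames(tt)] <- as.integer(tt)
  }
  perElement <- setNames(colSums(perGene), tb$element)
  perCategory <- vapply(split(tb$element, tb$category),
                        function(el) sum(perElement[el]), numeric(1L))
  list(perGene = perGene, perElement = perElement, perCategory = perCategory)
}
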