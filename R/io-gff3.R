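# Gene models travel as a GRanges (one range per gene, 1-based inclusive,
# GFF3 native) with metadata columns:
#   gene_id   character
#   cds       IRangesList of CDS parts, sorted by start, within the gene
# Parsing delegates tokenization to rtracklayer::readGFF; the grouping and
# the contract checks live here.

#' Construct a set of gene models
#'
#' @param gene_id unique gene identifiers.
#' @param chromosome chromosome/scaffold names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end 1-based inclusive gene coordinates.
#' @param cds an `IRangesList` (or list of `IRanges`) of CDS parts per gene;
#'   parts are sorted by start and must be non-overlapping and inside the gene.
#' @return A `GRanges` with `gene_id` and `cds` metadata columns.
#' @export
geneModels <- function(gene_id, chromosome, strand, start, end, cds) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(end < start))
    stop("gene model error: end < start for ",
         paste(gene_id[end < start], collapse = ", "))
  if (!is(cds, "IRangesList")) cds <- IRangesList(cds)
  for (i in seq_along(gene_id)) {
    p <- cds[[i]]
    if (length(p) == 0L) next
    p <- p[order(start(p))]
    cds[[i]] <- p
    if (min(start(p)) < start[i] || max(end(p)) > end[i])
      stop("gene model error: CDS outside gene bounds for ", gene_id[i])
    if (length(p) > 1L && any(start(p)[-1L] <= end(p)[-length(p)]))
      stop("gene model error: overlapping CDS parts for ", gene_id[i])
  }
  gr <- GRanges(seqnames = chromosome,
                ranges = IRanges(start = start, end = end),
                strand = strand)
  mcols(gr)$gene_id <- as.character(gene_id)
  mcols(gr)$cds <- cds
  mcols(gr)$cds_len <- vapply(cds, function(p) sum(width(p)), integer(1L))
  names(gr) <- gene_id
  gr
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` features and their `CDS` descendants (CDS may point at the
#' gene directly or through an intermediate `mRNA`). Unknown feature types are
#' skipped with a message giving the count. CDS parts are stored sorted by
#' start regardless of strand.
#'
#' @param path path to a GFF3 file (tab-separated, 9 columns, 1-based
#'   inclusive coordinates, `ID`/`Parent` attributes).
#' @return A `GRanges` of gene models as produced by [geneModels()].
#' @export
readGFF3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (nrow(g) == 0L) stop("GFF3 format error: no features in ", path)
  if (any(g$end < g$start))
    stop("GFF3 format error: end < start at line for ID ",
         paste(g$ID[g$end < g$start], collapse = ", "))
  known <- c("gene", "mRNA", "CDS")
  n_other <- sum(!g$type %in% known)
  if (n_other > 0L)
    message("readGFF3: skipped ", n_other, " feature(s) of other types")
  genes <- g[g$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("GFF3 format error: no gene features in ", path)
  # mRNA -> gene indirection
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  mrna_parent <- setNames(vapply(mrna$Parent, function(p) p[1L], character(1L)),
                          mrna$ID)
  cds <- g[g$type == "CDS", , drop = FALSE]
  cds_by_gene <- setNames(vector("list", nrow(genes)), genes$ID)
  if (nrow(cds) > 0L) {
    for (i in seq_len(nrow(cds))) {
      par <- unlist(cds$Parent[i])
      if (length(par) == 0L)
        stop("GFF3 format error: CDS without a Parent attribute")
      par <- par[1L]
      gene <- if (par %in% names(mrna_parent)) mrna_parent[[par]] else par
      if (!gene %in% genes$ID)
        stop("GFF3 format error: CDS Parent '", par,
             "' does not resolve to a gene feature")
      cds_by_gene[[gene]] <- c(cds_by_gene[[gene]],
                               list(c(cds$start[i], cds$end[i])))
    }
  }
  cds_list <- lapply(genes$ID, function(id) {
    parts <- cds_by_gene[[id]]
    if (is.null(parts)) return(IRanges())
    m <- do.call(rbind, parts)
    m <- m[order(m[, 1L]), , drop = FALSE]
    IRanges(start = m[, 1L], end = m[, 2L])
  })
  geneModels(gene_id = as.character(genes$ID),
             chromosome = as.character(genes$seqid),
             strand = as.character(genes$strand),
             start = genes$start, end = genes$end,
             cds = IRangesList(cds_list))
}

#' Write gene models to GFF3
#'
#' Emits one `gene` line per model and one `CDS` line per part, with the CDS
#' `Parent` pointing at the gene.
#'
#' @param genes a `GRanges` from [geneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_along(genes)) {
    id <- mcols(genes)$gene_id[i]
    chr <- as.character(seqnames(genes)[i])
    str <- as.character(strand(genes)[i])
    lines <- c(lines, paste(chr, "famscan", "gene",
                            start(genes)[i], end(genes)[i], ".", str, ".",
                            paste0("ID=", id), sep = "\t"))
    p <- mcols(genes)$cds[[i]]
    for (j in seq_along(p)) {
      lines <- c(lines, paste(chr, "famscan", "CDS",
                              start(p)[j], end(p)[j], ".", str, "0",
                              paste0("ID=", id, ".cds", j, ";Parent=", id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
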