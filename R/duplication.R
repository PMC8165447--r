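# Duplication-event typing: candidate pairs are sister leaves of the family
# tree; pairs above the identity threshold are typed by chromosomal relation
# (tandem: same chromosome within the separation bound; segmental: different
# chromosomes) and each retained pair gets a whole-gene Ka/Ks estimate.

#' Sister-leaf pairs of a tree
#'
#' Pairs of tips sharing an immediate parent node (cherries); at an unrooted
#' trifurcation any two tips attached to the same node pair up.
#'
#' @param phy an ape `phylo` object.
#' @return data.frame with columns `a`, `b` (tip labels), sorted.
#' @export
sisterLeafPairs <- function(phy) {
  tips <- seq_len(length(phy$tip.label))
  tip_edges <- phy$edge[, 2L] %in% tips
  parents <- phy$edge[tip_edges, 1L]
  children <- phy$edge[tip_edges, 2L]
  out <- list()
  for (p in unique(parents)) {
    kids <- sort(children[parents == p])
    if (length(kids) >= 2L) {
      cmb <- utils::combn(kids, 2L)
      for (k in seq_len(ncol(cmb)))
        out[[length(out) + 1L]] <- phy$tip.label[cmb[, k]]
    }
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  df <- data.frame(a = pmin(m[, 1L], m[, 2L]), b = pmax(m[, 1L], m[, 2L]),
                   stringsAsFactors = FALSE)
  df[order(df$a, df$b), , drop = FALSE]
}

#' Classify duplication events among family members
#'
#' Candidate pairs are sister leaves of `tree`. A pair is retained when the
#' global protein alignment identity exceeds `identityThresholdPct`. Retained
#' pairs are typed: same chromosome with start-to-start separation within
#' `tandemMaxSeparationBp` is tandem; different chromosomes is segmental; same
#' chromosome beyond the bound, or either gene on an unplaced scaffold, is
#' unclassified. Each retained pair carries a whole-gene Nei-Gojobori Ka/Ks
#' computed on the codon alignment induced by the protein alignment.
#'
#' @param genes gene models (`GRanges` from [geneModels()]) covering every
#'   tree leaf.
#' @param proteins `AAStringSet` of member proteins (names = gene ids).
#' @param cds `DNAStringSet` of member coding sequences (names = gene ids).
#' @param tree an ape `phylo` whose tip labels are gene ids.
#' @param identityThresholdPct retain pairs with identity strictly above this
#'   (default 80).
#' @param tandemMaxSeparationBp tandem separation bound in bp (default 2e5).
#' @param unplaced character vector of seqnames to treat as unplaced scaffolds.
#' @param substitutionMatrix,gapOpen,gapExtend protein alignment scoring.
#' @return data.frame with one row per retained pair: `gene_a`, `gene_b`,
#'   `identity_pct`, `chromosomal_relation`, `separation_bp`, `dup_type`,
#'   and the Ka/Ks fields `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`, `ratio`, `call`.
#' @export
classifyDuplications <- function(genes, proteins, cds, tree,
                                 identityThresholdPct = 80,
                                 tandemMaxSeparationBp = 200000L,
                                 unplaced = character(),
                                 substitutionMatrix = blosum62(),
                                 gapOpen = 10, gapExtend = 1) {
  ids <- mcols(genes)$gene_id
  missing <- setdiff(tree$tip.label, ids)
  if (length(missing))
    stop("gene(s) in tree absent from models: ", paste(missing, collapse = ", "))
  pairs <- sisterLeafPairs(tree)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    ga <- pairs$a[k]; gb <- pairs$b[k]
    aln <- globalAlign(proteins[[ga]], proteins[[gb]],
                       substitutionMatrix, gapOpen, gapExtend)
    if (aln$identity_pct <= identityThresholdPct) next
    ia <- match(ga, ids); ib <- match(gb, ids)
    chr_a <- as.character(seqnames(genes)[ia])
    chr_b <- as.character(seqnames(genes)[ib])
    if (chr_a %in% unplaced || chr_b %in% unplaced) {
      relation <- "unplaced"; dup_type <- "unclassified"; sep <- NA_integer_
    } else if (chr_a == chr_b) {
      relation <- "same_chromosome"
      sep <- abs(start(genes)[ia] - start(genes)[ib])
      dup_type <- if (sep <= tandemMaxSeparationBp) "tandem" else "unclassified"
    } else {
      relation <- "different_chromosome"; sep <- NA_integer_
      dup_type <- "segmental"
    }
    caln <- mapProteinAlignmentToCodons(aln$a_aln, aln$b_aln,
                                        cds[[ga]], cds[[gb]], ids = c(ga, gb))
    kk <- kaksPair(caln)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, identity_pct = aln$identity_pct,
      chromosomal_relation = relation, separation_bp = sep,
      dup_type = dup_type, S = kk@S, N = kk@N, Sd = kk@Sd, Nd = kk@Nd,
      Ka = kk@Ka, Ks = kk@Ks, ratio = kk@ratio, call = kk@call,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity_pct = numeric(), chromosomal_relation = character(),
                      separation_bp = integer(), dup_type = character(),
                      S = numeric(), N = numeric(), Sd = numeric(),
                      Nd = numeric(), Ka = numeric(), Ks = numeric(),
                      ratio = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
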