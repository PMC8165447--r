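# Synthetic study generator: genomes carrying a planted transcription-factor
# family (domain-bearing members in three subfamilies, tandem and segmental
# duplicate pairs diverged under a known omega), promoters with planted
# cis-elements, and replicated Ct tables with known fold changes. Every
# generator is a pure function of (spec, seed) and emits a machine-readable
# truth table sufficient to score the downstream stages.

#' Reference domain sequences used by the simulator
#'
#' The Class II reference is a 58-aa helix-loop-helix style domain whose
#' first quarter is the basic (K/R-rich) region; the Class I reference is the
#' same sequence with four basic-region residues deleted, matching the
#' diagnostic deletion that defines the PCF subfamily. `rDomain` is the
#' polar-rich 20-mer appended to CYC members.
#'
#' @return A list with character elements `class1`, `class2`, `rDomain`.
#' @export
defaultDomainRefs <- function() {
  class2 <- paste0("GKRDRHSKIYTAKG",          # basic region (quarter 1)
                   "LRDRRVRLSVET",            # helix I
                   "AIQFYDLQ",                # loop
                   "DRLGFDQPSKAVDWLLTQAKPAIE") # helix II
  class1 <- paste0(substr(class2, 1L, 4L), substr(class2, 9L, nchar(class2)))
  list(class1 = class1, class2 = class2,
       rDomain = "KKEKSRDSNKQQSERKSTND")
}

# non-polar-biased residue sampling keeps random flanks from tripping the
# polar R-domain detector
.random_protein <- function(n) {
  w <- ifelse(AA20 %in% POLAR_AA, 1, 3)
  paste(sample(AA20, n, replace = TRUE, prob = w), collapse = "")
}

.synonymous_codons <- function() {
  if (is.null(.pkg_cache$syn_codons)) {
    gc <- geneticCode()
    sense <- names(gc)[gc != "*"]
    .pkg_cache$syn_codons <- split(sense, gc[sense])
  }
  .pkg_cache$syn_codons
}

# reverse-translate a protein (no stop), choosing synonymous codons at random;
# an initial M always becomes ATG
.reverse_translate <- function(protein) {
  syn <- .synonymous_codons()
  chars <- strsplit(protein, "")[[1L]]
  codons <- vapply(seq_along(chars), function(i) {
    opts <- syn[[chars[i]]]
    if (i == 1L && chars[i] == "M") return("ATG")
    opts[sample.int(length(opts), 1L)]
  }, character(1L))
  paste(codons, collapse = "")
}

.translate_cds <- function(cds, id = "cds") {
  gc <- geneticCode()
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not a multiple of 3 for ", id)
  aa <- gc[.split_codons(cds)]
  if (any(is.na(aa))) stop("non-ACGT codon in CDS for ", id)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  st <- which(aa == "*")
  if (length(st)) stop("internal stop codon at codon ", st[1L], " in ", id)
  paste(aa, collapse = "")
}

#' Evolve a duplicated codon pair under a target omega
#'
#' Draws a random stop-free ancestor CDS (or uses `ancestor`) and evolves one
#' copy by `nEvents` proposal rounds. Each round picks a uniform random
#' single-nucleotide change; proposals creating a stop codon are rejected;
#' synonymous proposals are accepted with probability 1 and nonsynonymous
#' with probability `min(omega, 1)` (for `omega > 1` synonymous proposals are
#' instead accepted with probability `1/omega`), so the realized
#' nonsynonymous:synonymous event ratio tracks `omega`. Fully reproducible
#' from `seed`.
#'
#' @param ancestorLengthCodons ancestor length in codons (>= 10).
#' @param omega target Ka/Ks (>= 0).
#' @param nEvents number of proposal rounds (>= 0).
#' @param seed integer seed.
#' @param ancestor optional explicit ancestor CDS (stop-free, length a
#'   multiple of 3); overrides `ancestorLengthCodons`.
#' @return A list: `cdsA` (the ancestor copy), `cdsB` (the evolved copy),
#'   `acceptedSyn`, `acceptedNonsyn`, `proposals`.
#' @export
evolveCodonPair <- function(ancestorLengthCodons, omega, nEvents, seed = 1L,
                            ancestor = NULL) {
  if (omega < 0) stop("parameter error: omega must be >= 0")
  if (nEvents < 0) stop("parameter error: nEvents must be >= 0")
  set.seed(seed)
  gc <- geneticCode()
  sense <- SENSE_CODONS()
  if (is.null(ancestor)) {
    if (ancestorLengthCodons < 10L) stop("ancestor must be >= 10 codons")
    ancestor <- paste(sample(sense, ancestorLengthCodons, replace = TRUE),
                      collapse = "")
  } else {
    ancestor <- toupper(ancestor)
    if (nchar(ancestor) %% 3L != 0L) stop("ancestor length must be a multiple of 3")
    if (any(gc[.split_codons(ancestor)] == "*")) stop("ancestor contains a stop codon")
  }
  L <- nchar(ancestor)
  b <- strsplit(ancestor, "")[[1L]]
  p_nonsyn <- min(omega, 1)
  p_syn <- if (omega > 1) 1 / omega else 1
  acc_syn <- 0L; acc_nonsyn <- 0L
  for (ev in seq_len(nEvents)) {
    pos <- sample.int(L, 1L)
    newbase <- sample(setdiff(BASES, b[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    cod_old <- paste(b[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    cod_new <- cod_old
    substr(cod_new, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- newbase
    if (gc[cod_new] == "*") next                       # stop-creating: reject
    syn <- gc[cod_new] == gc[cod_old]
    p_acc <- if (syn) p_syn else p_nonsyn
    if (runif(1L) <= p_acc) {
      b[pos] <- newbase
      if (syn) acc_syn <- acc_syn + 1L else acc_nonsyn <- acc_nonsyn + 1L
    }
  }
  list(cdsA = ancestor, cdsB = paste(b, collapse = ""),
       acceptedSyn = acc_syn, acceptedNonsyn = acc_nonsyn,
       proposals = as.integer(nEvents))
}

#' Specification for a synthetic family genome
#'
#' @param nPCF,nCIN,nCYC single (unpaired) family members per subfamily.
#' @param nTandemPairs,nSegmentalPairs duplicate pairs planted on the same
#'   chromosome (within the tandem separation bound) / on different
#'   chromosomes, diverged under `pairOmega`.
#' @param nLowIdentityPairs cross-chromosome pairs evolved far enough that
#'   their protein identity falls below the duplication classifier's
#'   threshold; they exercise the exclusion rule.
#' @param nBackground non-family genes with random, domain-free CDS.
#' @param nChromosomes chromosomes to emit.
#' @param tandemSeparationRange start-to-start separation range (bp) for
#'   tandem pairs; the upper end stays within the 200 kb tandem bound.
#' @param pairOmega,pairEvents omega and proposal rounds for duplicate-pair
#'   divergence (defaults 0.3 and 90: roughly 90% protein identity).
#' @param lowIdentityOmega,lowIdentityEvents divergence settings for the
#'   low-identity pairs (defaults 1.0 and 100: roughly 70% identity).
#' @param flankLengthRange protein flank lengths (aa) around the domain.
#' @param backgroundLengthRange background protein lengths (aa).
#' @return A list with class `familySpec`.
#' @export
familySpec <- function(nPCF = 3L, nCIN = 2L, nCYC = 1L,
                       nTandemPairs = 1L, nSegmentalPairs = 1L,
                       nLowIdentityPairs = 0L, nBackground = 10L,
                       nChromosomes = 3L,
                       tandemSeparationRange = c(20000L, 100000L),
                       pairOmega = 0.3, pairEvents = 90L,
                       lowIdentityOmega = 1.0, lowIdentityEvents = 100L,
                       flankLengthRange = c(40L, 80L),
                       backgroundLengthRange = c(80L, 200L)) {
  spec <- list(nPCF = nPCF, nCIN = nCIN, nCYC = nCYC,
               nTandemPairs = nTandemPairs, nSegmentalPairs = nSegmentalPairs,
               nLowIdentityPairs = nLowIdentityPairs,
               nBackground = nBackground, nChromosomes = nChromosomes,
               tandemSeparationRange = tandemSeparationRange,
               pairOmega = pairOmega, pairEvents = pairEvents,
               lowIdentityOmega = lowIdentityOmega,
               lowIdentityEvents = lowIdentityEvents,
               flankLengthRange = flankLengthRange,
               backgroundLengthRange = backgroundLengthRange)
  class(spec) <- "familySpec"
  spec
}

#' Generate a synthetic genome carrying a planted gene family
#'
#' Emits multi-chromosome genome sequence, gene models, proteins and CDS for
#' a family whose members embed the configured domain (Class I members carry
#' the 4-residue basic-region deletion, CYC members a polar R-domain segment
#' C-terminal of the domain), plus background genes without the domain.
#' Duplicate pairs share a common ancestor CDS diverged with
#' [evolveCodonPair()]. All genes are single-exon; every gene keeps at least
#' ~1.7 kb of gene-free sequence upstream of its ATG so full-length promoters
#' are always extractable.
#'
#' @param spec a [familySpec()].
#' @param seed integer seed; identical (spec, seed) gives byte-identical
#'   output.
#' @return A list: `genome` (`DNAStringSet`), `genes` (`GRanges` from
#'   [geneModels()]), `proteins` (`AAStringSet`, no stop), `cds`
#'   (`DNAStringSet`, ATG..stop), `truth` (a [FamilyTruth-class]).
#' @export
generateFamilyGenome <- function(spec = familySpec(), seed = 1L) {
  stopifnot(inherits(spec, "familySpec"))
  if (spec$nChromosomes < 1L) stop("spec error: need >= 1 chromosome")
  if ((spec$nSegmentalPairs > 0L || spec$nLowIdentityPairs > 0L) &&
      spec$nChromosomes < 2L)
    stop("spec error: cross-chromosome pairs need >= 2 chromosomes")
  if (spec$nTandemPairs > 0L &&
      spec$tandemSeparationRange[2L] > 200000L)
    stop("spec error: tandem separation range exceeds the 200 kb bound")
  set.seed(seed)
  refs <- defaultDomainRefs()

  draw <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

  build_member <- function(subfam) {
    nf <- draw(spec$flankLengthRange[1L], spec$flankLengthRange[2L])
    cf <- draw(spec$flankLengthRange[1L], spec$flankLengthRange[2L])
    nflank <- paste0("M", .random_protein(nf - 1L))
    dom <- if (subfam == "PCF") refs$class1 else refs$class2
    # two substitutions outside the basic region keep members from being
    # literal copies of the reference
    dpos <- sample(seq(16L, nchar(dom)), 2L)
    for (p in dpos) substr(dom, p, p) <- sample(setdiff(AA20, substr(dom, p, p)), 1L)
    cflank <- .random_protein(cf)
    if (subfam == "CYC") {
      at <- sample.int(max(nchar(cflank) - 5L, 1L), 1L)
      cflank <- paste0(substr(cflank, 1L, at), refs$rDomain,
                       substr(cflank, at + 1L, nchar(cflank)))
    }
    prot <- paste0(nflank, dom, cflank)
    list(protein = prot, domain_start = nchar(nflank) + 1L,
         domain_end = nchar(nflank) + nchar(dom), subfamily = subfam)
  }

  members <- list()     # descriptors: id, protein, cds (no stop), subfamily,
                        # domain interval, pair info
  add_member <- function(m) members[[length(members) + 1L]] <<- m

  k <- 0L
  for (subfam in c(rep("PCF", spec$nPCF), rep("CIN", spec$nCIN),
                   rep("CYC", spec$nCYC))) {
    k <- k + 1L
    b <- build_member(subfam)
    add_member(list(id = sprintf("FAM%02d", k), protein = b$protein,
                    cds = .reverse_translate(b$protein),
                    subfamily = subfam, domain_start = b$domain_start,
                    domain_end = b$domain_end, pair = NA_character_,
                    pair_role = NA_character_))
  }

  pair_truth <- list()
  make_pair <- function(kind, omega, n_events) {
    b <- build_member("CIN")
    anc_cds <- .reverse_translate(b$protein)
    ev <- evolveCodonPair(omega = omega, nEvents = n_events,
                          seed = sample.int(2^30, 1L), ancestor = anc_cds)
    ida <- sprintf("FAM%02d", k + 1L); idb <- sprintf("FAM%02d", k + 2L)
    k <<- k + 2L
    add_member(list(id = ida, protein = .translate_cds(ev$cdsA),
                    cds = ev$cdsA, subfamily = "CIN",
                    domain_start = b$domain_start, domain_end = b$domain_end,
                    pair = idb, pair_role = kind))
    add_member(list(id = idb, protein = .translate_cds(ev$cdsB),
                    cds = ev$cdsB, subfamily = "CIN",
                    domain_start = b$domain_start, domain_end = b$domain_end,
                    pair = ida, pair_role = kind))
    pair_truth[[length(pair_truth) + 1L]] <<- data.frame(
      gene_a = ida, gene_b = idb, true_type = kind, omega = omega,
      n_events = n_events, accepted_syn = ev$acceptedSyn,
      accepted_nonsyn = ev$acceptedNonsyn, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$nTandemPairs))
    make_pair("tandem", spec$pairOmega, spec$pairEvents)
  for (i in seq_len(spec$nSegmentalPairs))
    make_pair("segmental", spec$pairOmega, spec$pairEvents)
  for (i in seq_len(spec$nLowIdentityPairs))
    make_pair("low_identity", spec$lowIdentityOmega, spec$lowIdentityEvents)

  backgrounds <- lapply(seq_len(spec$nBackground), function(i) {
    n <- draw(spec$backgroundLengthRange[1L], spec$backgroundLengthRange[2L])
    prot <- paste0("M", .random_protein(n - 1L))
    list(id = sprintf("BGD%02d", i), protein = prot,
         cds = .reverse_translate(prot), subfamily = NA_character_,
         domain_start = NA_integer_, domain_end = NA_integer_,
         pair = NA_character_, pair_role = NA_character_)
  })

  # ---- chromosome assignment -------------------------------------------
  chroms <- sprintf("chr%d", seq_len(spec$nChromosomes))
  placements <- setNames(vector("list", spec$nChromosomes), chroms)
  place <- function(chr, gene, tandem_sep = NA_integer_)
    placements[[chr]][[length(placements[[chr]]) + 1L]] <<-
      list(gene = gene, tandem_sep = tandem_sep)
  next_chr <- 0L
  pick_chr <- function() {
    next_chr <<- next_chr %% spec$nChromosomes + 1L
    chroms[next_chr]
  }
  done <- character()
  for (m in members) {
    if (m$id %in% done) next
    if (!is.na(m$pair) && m$pair_role == "tandem") {
      chr <- pick_chr()
      sep <- draw(spec$tandemSeparationRange[1L],
                  spec$tandemSeparationRange[2L])
      mate <- members[[which(vapply(members, `[[`, "", "id") == m$pair)]]
      place(chr, m)
      place(chr, mate, tandem_sep = sep)
      done <- c(done, m$id, m$pair)
    } else if (!is.na(m$pair)) {          # segmental / low_identity
      c1 <- pick_chr(); c2 <- pick_chr()
      if (c1 == c2) c2 <- chroms[c(setdiff(seq_len(spec$nChromosomes),
                                           match(c1, chroms)))[1L]]
      mate <- members[[which(vapply(members, `[[`, "", "id") == m$pair)]]
      place(c1, m); place(c2, mate)
      done <- c(done, m$id, m$pair)
    } else {
      place(pick_chr(), m)
      done <- c(done, m$id)
    }
  }
  for (bg in backgrounds) place(pick_chr(), bg)

  # ---- lay out coordinates and build sequence --------------------------
  MARGIN <- 2500L
  rows <- list(); chrom_seqs <- character(0L)
  for (chr in chroms) {
    cursor <- MARGIN + sample(1000:2000, 1L)
    segs <- list(); prev_end <- 0L
    genes_here <- placements[[chr]]
    starts <- integer(0L)
    for (pl in genes_here) {
      g <- pl$gene
      cds_full <- paste0(g$cds, "TAA")
      len <- nchar(cds_full)
      if (!is.na(pl$tandem_sep)) {
        prev_start <- starts[length(starts)]
        start <- prev_start + max(pl$tandem_sep,
                                  rows[[length(rows)]]$len + 2L * MARGIN)
        if (start < cursor) start <- cursor
      } else {
        start <- cursor
      }
      strand <- sample(c("+", "-"), 1L)
      emb <- if (strand == "+") cds_full
             else as.character(reverseComplement(DNAString(cds_full)))
      rows[[length(rows) + 1L]] <- list(
        id = g$id, chr = chr, strand = strand, start = start,
        end = start + len - 1L, len = len, emb = emb,
        subfamily = g$subfamily, domain_start = g$domain_start,
        domain_end = g$domain_end, protein = g$protein, cds = cds_full)
      starts <- c(starts, start)
      cursor <- start + len + 2L * MARGIN + sample(500:1500, 1L)
    }
    chrom_len <- cursor + MARGIN
    base <- sample(BASES, chrom_len, replace = TRUE)
    for (rw in rows) {
      if (rw$chr != chr) next
      base[rw$start:rw$end] <- strsplit(rw$emb, "")[[1L]]
    }
    chrom_seqs[chr] <- paste(base, collapse = "")
  }

  ids <- vapply(rows, `[[`, "", "id")
  genes <- geneModels(
    gene_id = ids,
    chromosome = vapply(rows, `[[`, "", "chr"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, function(r) r$start, integer(1L)),
    end = vapply(rows, function(r) r$end, integer(1L)),
    cds = IRangesList(lapply(rows, function(r) IRanges(r$start, r$end))))
  proteins <- AAStringSet(setNames(vapply(rows, `[[`, "", "protein"), ids))
  cds_set <- DNAStringSet(setNames(vapply(rows, `[[`, "", "cds"), ids))
  genome <- DNAStringSet(chrom_seqs)

  truth_members <- data.frame(
    gene_id = ids,
    subfamily = vapply(rows, `[[`, "", "subfamily"),
    domain_start = vapply(rows, function(r) r$domain_start, integer(1L)),
    domain_end = vapply(rows, function(r) r$domain_end, integer(1L)),
    chromosome = vapply(rows, `[[`, "", "chr"),
    strand = vapply(rows, `[[`, "", "strand"),
    is_family = grepl("^FAM", ids),
    stringsAsFactors = FALSE)
  truth_dups <- if (length(pair_truth)) do.call(rbind, pair_truth)
                else data.frame(gene_a = character(), gene_b = character(),
                                true_type = character(), omega = numeric(),
                                n_events = integer(), accepted_syn = integer(),
                                accepted_nonsyn = integer(),
                                stringsAsFactors = FALSE)
  truth <- new("FamilyTruth", members = truth_members, duplicates = truth_dups,
               promoterElements = data.frame(), expression = data.frame())
  list(genome = genome, genes = genes, proteins = proteins, cds = cds_set,
       truth = truth)
}

.sample_iupac <- function(consensus) {
  chars <- strsplit(consensus, "")[[1L]]
  paste(vapply(chars, function(ch) {
    ex <- IUPAC_DNA[[ch]]
    if (is.null(ex)) stop("invalid IUPAC code: ", ch)
    if (length(ex) == 1L) ex else sample(ex, 1L)
  }, character(1L)), collapse = "")
}

#' Plant cis-element occurrences into promoters
#'
#' Replaces (never inserts) bases inside each target gene's promoter window
#' with a concrete instance of the element's IUPAC consensus. Offsets are
#' 1-based on the promoter string returned by [extractPromoters()] (5'->3'
#' toward the ATG); `strand = "-"` plants the reverse complement. After
#' planting, the touched promoters are re-scanned and accidental forward
#' matches of any table motif that are not part of the plan are destroyed by
#' single-base edits outside the planted intervals, so plus-strand planted
#' occurrences are recovered exactly by [scanCisElements()].
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param genes gene models covering every planned gene.
#' @param motifs a [MotifTable-class].
#' @param plan data.frame with columns `gene_id`, `element`, `offset`,
#'   `strand`; planted intervals within a gene must not overlap.
#' @param promoterLength promoter window length in bp (default 1500).
#' @param seed integer seed (ambiguity codes are sampled).
#' @param maxIter bound on scrubbing passes (default 50).
#' @return A list: `genome` (modified `DNAStringSet`) and `truth` (the plan).
#' @export
plantPromoterElements <- function(genome, genes, motifs, plan,
                                  promoterLength = 1500L, seed = 1L,
                                  maxIter = 50L) {
  stopifnot(is(motifs, "MotifTable"))
  set.seed(seed)
  tb <- motifTable(motifs)
  if (nrow(plan) == 0L)
    return(list(genome = genome, truth = plan))
  bad <- setdiff(plan$element, tb$element)
  if (length(bad)) stop("plan error: unknown element(s): ",
                        paste(bad, collapse = ", "))
  widths <- setNames(nchar(tb$consensus), tb$element)
  plan$width <- widths[plan$element]
  if (any(plan$offset < 1L | plan$offset + plan$width - 1L > promoterLength))
    stop("plan error: offset outside the promoter window")
  # non-overlap within gene
  for (g in unique(plan$gene_id)) {
    pg <- plan[plan$gene_id == g, , drop = FALSE]
    if (nrow(pg) > 1L) {
      o <- order(pg$offset)
      s <- pg$offset[o]; e <- pg$offset[o] + pg$width[o] - 1L
      if (any(s[-1L] <= e[-length(e)] + 1L))
        stop("plan error: planted intervals overlap or touch in gene ", g)
    }
  }
  prom <- extractPromoters(genome, genes, promoterLength)
  if (any(mcols(prom)$truncated[names(prom) %in% plan$gene_id]))
    stop("plan error: planned gene has a truncated promoter")
  pstr <- setNames(as.character(prom), names(prom))
  for (i in seq_len(nrow(plan))) {
    g <- plan$gene_id[i]
    inst <- .sample_iupac(tb$consensus[match(plan$element[i], tb$element)])
    if (plan$strand[i] == "-")
      inst <- as.character(reverseComplement(DNAString(inst)))
    substr(pstr[g], plan$offset[i], plan$offset[i] + plan$width[i] - 1L) <- inst
  }
  # scrub accidental forward hits in the touched promoters
  touched <- unique(plan$gene_id)
  planted_iv <- split(plan[, c("offset", "width")], plan$gene_id)
  truth_key <- paste(plan$gene_id, plan$element, plan$offset,
                     ifelse(plan$strand == "+", "+", "-"))
  protected_of <- function(g) {
    iv <- planted_iv[[g]]
    if (is.null(iv)) return(integer())
    unlist(lapply(seq_len(nrow(iv)),
                  function(r) iv$offset[r]:(iv$offset[r] + iv$width[r] - 1L)))
  }
  for (iter in seq_len(maxIter)) {
    cur <- DNAStringSet(pstr[touched])
    hits <- scanCisElements(cur, motifs, "given_only")
    key <- paste(hits$gene_id, hits$element, hits$offset, hits$strand)
    acc <- hits[!key %in% truth_key, , drop = FALSE]
    if (nrow(acc) == 0L) break
    edited <- list()   # per gene: positions mutated this pass
    for (r in seq_len(nrow(acc))) {
      h <- acc[r, ]
      w <- widths[[h$element]]
      span <- h$offset:(h$offset + w - 1L)
      if (length(intersect(span, edited[[h$gene_id]])))
        next                       # already disturbed this pass; re-scan next
      cand <- setdiff(span, protected_of(h$gene_id))
      if (!length(cand))
        stop("cannot scrub accidental hit inside planted intervals (gene ",
             h$gene_id, ", element ", h$element, ")")
      pos <- cand[1L]
      old <- substr(pstr[h$gene_id], pos, pos)
      substr(pstr[h$gene_id], pos, pos) <- sample(setdiff(BASES, old), 1L)
      edited[[h$gene_id]] <- c(edited[[h$gene_id]], pos)
    }
    if (iter == maxIter)
      warning("plantPromoterElements: scrubbing pass bound reached")
  }
  # write promoters back into the genome in the right orientation
  gseq <- setNames(as.character(genome), names(genome))
  for (g in touched) {
    gi <- match(g, names(prom))
    gidx <- match(g, mcols(genes)$gene_id)
    chr <- as.character(seqnames(genes)[gidx])
    s <- mcols(prom)$genomic_start[gi]; e <- mcols(prom)$genomic_end[gi]
    piece <- if (as.character(strand(genes)[gidx]) == "+") pstr[g]
             else as.character(reverseComplement(DNAString(pstr[[g]])))
    substr(gseq[chr], s, e) <- piece
  }
  list(genome = DNAStringSet(gseq),
       truth = plan[, c("gene_id", "element", "offset", "strand")])
}

#' Generate a replicated qPCR Ct table with known fold changes
#'
#' Ct(target, replicate) = `baselineCt - log2(true_fold) + N(0, noiseSd)`;
#' the reference gene has fold 1 in every sample and baseline
#' `referenceBaselineCt`. Truth folds are recorded relative to the calibrator
#' sample.
#'
#' @param design data.frame with columns `sample`, `gene`, `true_fold`
#'   (per-sample fold changes; the calibrator's fold is the baseline the rest
#'   are expressed against).
#' @param referenceGene reference gene id (added automatically).
#' @param calibratorSample calibrator sample id (must appear in `design`).
#' @param noiseSd Gaussian Ct noise, cycles (>= 0).
#' @param replicates technical replicates per (sample, gene) (>= 2).
#' @param seed integer seed.
#' @param baselineCt,referenceBaselineCt baseline cycles for targets and the
#'   reference gene.
#' @return A list: `ct` (a [CtTable-class]) and `truth` (design with folds
#'   normalized to the calibrator).
#' @export
generateCtTable <- function(design, referenceGene = "TUBULIN",
                            calibratorSample, noiseSd = 0.2, replicates = 3L,
                            seed = 1L, baselineCt = 26, referenceBaselineCt = 20) {
  if (replicates < 2L) stop("design error: replicates must be >= 2")
  if (noiseSd < 0) stop("design error: noiseSd must be >= 0")
  if (!calibratorSample %in% design$sample)
    stop("design error: calibrator sample '", calibratorSample,
         "' not among samples")
  if (referenceGene %in% design$gene)
    stop("design error: the reference gene cannot appear in the design")
  set.seed(seed)
  samples <- unique(design$sample)
  rows <- list()
  for (s in samples) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = referenceGene, replicate = r,
        ct = referenceBaselineCt + rnorm(1L, 0, noiseSd),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = design$sample[i], gene = design$gene[i], replicate = r,
        ct = baselineCt - log2(design$true_fold[i]) + rnorm(1L, 0, noiseSd),
        stringsAsFactors = FALSE)
    }
  }
  tbl <- CtTable(do.call(rbind, rows), referenceGene, calibratorSample)
  truth <- design
  for (g in unique(design$gene)) {
    calf <- design$true_fold[design$sample == calibratorSample &
                             design$gene == g]
    if (length(calf) != 1L)
      stop("design error: gene '", g, "' needs exactly one calibrator row")
    truth$true_fold[truth$gene == g] <- design$true_fold[design$gene == g] / calf
  }
  list(ct = tbl, truth = truth)
}
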