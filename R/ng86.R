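# Nei-Gojobori (1986) Ka/Ks: fractional synonymous site counts per codon,
# multi-pathway averaging of codon differences, Jukes-Cantor correction.
# Per-codon and per-codon-pair counts are memoized at first use; everything
# downstream is table lookup.

BASES <- c("A", "C", "G", "T")

.codon_neighbors <- function(codon) {
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      x <- codon
      substr(x, pos, pos) <- b
      k <- k + 1L
      out[k] <- x
    }
  }
  out
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' Each of the 9 single-nucleotide neighbors is classified: synonymous when it
#' is a sense codon for the same amino acid, otherwise nonsynonymous
#' (stop-creating changes count as nonsynonymous). The synonymous site count
#' is the sum over the three positions of the synonymous fraction among that
#' position's three changes; `s + n = 3` always.
#'
#' @param codon a sense codon (3-letter DNA string, not a stop).
#' @return Named numeric vector `c(s = , n = )`.
#' @export
#' @examples
#' ng86CountSites("TTT")  # s = 1/3
ng86CountSites <- function(codon) {
  codon <- toupper(codon)
  gc <- geneticCode()
  aa <- gc[codon]
  if (is.na(aa)) stop("invalid codon: ", codon)
  if (aa == "*") stop("stop codon input: ", codon)
  nb <- .codon_neighbors(codon)
  syn <- sum(gc[nb] != "*" & gc[nb] == aa) / 3
  c(s = syn, n = 3 - syn)
}

#' Nei-Gojobori difference counts for a codon pair
#'
#' With k differing positions, all k! substitution orderings are enumerated;
#' pathways passing through a stop codon are discarded and the synonymous /
#' nonsynonymous step counts averaged over the rest. If every pathway hits a
#' stop, all k! pathways are used with stop-passing steps counted as
#' nonsynonymous. `sd + nd = k` always.
#'
#' @param codonA,codonB sense codons.
#' @return Named numeric vector `c(sd = , nd = )`.
#' @export
#' @examples
#' ng86CountDifferences("TTT", "GTA")  # c(0.5, 1.5)
ng86CountDifferences <- function(codonA, codonB) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  gc <- geneticCode()
  for (c_ in c(codonA, codonB)) {
    if (is.na(gc[c_])) stop("invalid codon: ", c_)
    if (gc[c_] == "*") stop("stop codon input: ", c_)
  }
  pos <- which(strsplit(codonA, "")[[1L]] != strsplit(codonB, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- .permutations(pos)
  tally <- function(count_stop_paths) {
    sd_tot <- 0; nd_tot <- 0; n_path <- 0L
    for (p in perms) {
      cur <- codonA
      sd <- 0; nd <- 0; valid <- TRUE
      for (q in p) {
        nxt <- cur
        substr(nxt, q, q) <- substr(codonB, q, q)
        a1 <- gc[cur]; a2 <- gc[nxt]
        if (!count_stop_paths && a2 == "*" && nxt != codonB) { valid <- FALSE; break }
        if (a1 != "*" && a2 != "*" && a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (valid) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_path <- n_path + 1L }
    }
    list(sd = sd_tot, nd = nd_tot, n = n_path)
  }
  t1 <- tally(FALSE)
  if (t1$n == 0L) t1 <- tally(TRUE)
  c(sd = t1$sd / t1$n, nd = t1$nd / t1$n)
}

.permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

# memoized lookup tables over the 61 sense codons
.ng86_tables <- function() {
  if (is.null(.pkg_cache$ng86)) {
    sc <- SENSE_CODONS()
    sites <- t(vapply(sc, ng86CountSites, numeric(2L)))
    nsc <- length(sc)
    sd_tab <- matrix(0, nsc, nsc, dimnames = list(sc, sc))
    nd_tab <- sd_tab
    for (i in seq_len(nsc)) {
      for (j in seq_len(nsc)) {
        if (i == j) next
        d <- ng86CountDifferences(sc[i], sc[j])
        sd_tab[i, j] <- d[["sd"]]
        nd_tab[i, j] <- d[["nd"]]
      }
    }
    .pkg_cache$ng86 <- list(sites = sites, sd = sd_tab, nd = nd_tab)
  }
  .pkg_cache$ng86
}

.split_codons <- function(s) {
  substring(s, seq(1L, nchar(s) - 2L, by = 3L), seq(3L, nchar(s), by = 3L))
}

#' Jukes-Cantor distance
#'
#' `d = -(3/4) ln(1 - 4p/3)`; `NA` when `p >= 3/4`.
#'
#' @param p proportion of differences per site.
#' @return Corrected distance, `NA` when undefined.
#' @export
jukesCantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Whole-alignment Nei-Gojobori Ka/Ks
#'
#' Comparable codons are those gap-free in both rows. Site counts `S` and `N`
#' are the mean of the two per-sequence sums; differences `Sd`, `Nd` sum the
#' pathway-averaged per-codon counts. `pS = Sd/S` and `pN = Nd/N` are
#' Jukes-Cantor corrected into `Ks` and `Ka`. The ratio is `NA` when `Ks` is
#' zero or a correction is undefined (p >= 3/4); the selection call uses the
#' conventional thresholds with a 1e-9 tolerance around 1.
#'
#' @param aln a [CodonAlignment-class].
#' @return A [KaKsResult-class].
#' @export
kaksPair <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  tabs <- .ng86_tables()
  ca <- .split_codons(aln@a)
  cb <- .split_codons(aln@b)
  ok <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  # trailing stop codons are not comparable material
  ok <- ok & ca %in% rownames(tabs$sites) & cb %in% rownames(tabs$sites)
  if (!any(ok)) stop("no comparable codon columns")
  ca <- ca[ok]; cb <- cb[ok]
  sa <- tabs$sites[ca, , drop = FALSE]
  sb <- tabs$sites[cb, , drop = FALSE]
  S <- (sum(sa[, "s"]) + sum(sb[, "s"])) / 2
  N <- (sum(sa[, "n"]) + sum(sb[, "n"])) / 2
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jukesCantor(pS)
  Ka <- jukesCantor(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  call <- if (is.na(ratio)) "undefined"
          else if (ratio > 1 + 1e-9) "positive"
          else if (ratio < 1 - 1e-9) "purifying"
          else "neutral"
  new("KaKsResult", S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      Ka = Ka, Ks = Ks, ratio = ratio, call = call, nCodons = sum(ok))
}

#' Sliding-window Ka/Ks along a codon alignment
#'
#' Windows start at 1, 1+step, 1+2*step, ... while the window fits inside the
#' alignment; [kaksPair()] is applied per window. Windows with `Ks = 0` (or no
#' comparable codons) carry an `NA` ratio, never zero.
#'
#' @param aln a [CodonAlignment-class].
#' @param windowNt window size in alignment columns (default 150; positive
#'   multiple of 3).
#' @param stepNt step in alignment columns (default 9; positive multiple of 3).
#' @return data.frame: `start_nt`, `end_nt` (1-based inclusive), `S`, `N`,
#'   `Sd`, `Nd`, `Ka`, `Ks`, `ratio`, `call`.
#' @export
slidingWindowKaks <- function(aln, windowNt = 150L, stepNt = 9L) {
  stopifnot(is(aln, "CodonAlignment"))
  windowNt <- as.integer(windowNt); stepNt <- as.integer(stepNt)
  if (windowNt <= 0L || stepNt <= 0L || windowNt %% 3L != 0L || stepNt %% 3L != 0L)
    stop("window and step must be positive multiples of 3")
  L <- nchar(aln@a)
  if (windowNt > L) stop("window larger than alignment")
  starts <- seq(1L, L - windowNt + 1L, by = stepNt)
  rows <- lapply(starts, function(s) {
    e <- s + windowNt - 1L
    sub <- CodonAlignment(substr(aln@a, s, e), substr(aln@b, s, e), aln@ids)
    kk <- tryCatch(kaksPair(sub), error = function(err) NULL)
    if (is.null(kk))
      return(data.frame(start_nt = s, end_nt = e, S = NA_real_, N = NA_real_,
                        Sd = NA_real_, Nd = NA_real_, Ka = NA_real_,
                        Ks = NA_real_, ratio = NA_real_, call = "undefined",
                        stringsAsFactors = FALSE))
    data.frame(start_nt = s, end_nt = e, S = kk@S, N = kk@N, Sd = kk@Sd,
               Nd = kk@Nd, Ka = kk@Ka, Ks = kk@Ks, ratio = kk@ratio,
               call = kk@call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each protein gap column becomes an aligned `---` triplet; each residue
#' column becomes its source codon. A trailing stop codon on either CDS is
#' trimmed. The de-gapped proteins must translate exactly from their CDS.
#'
#' @param protAlnA,protAlnB gapped protein rows of equal length.
#' @param cdsA,cdsB the source coding sequences (character or
#'   `DNAString`/`DNAStringSet`).
#' @param ids identifiers for the two rows.
#' @return A [CodonAlignment-class].
#' @export
mapProteinAlignmentToCodons <- function(protAlnA, protAlnB, cdsA, cdsB,
                                        ids = c("a", "b")) {
  a_cds <- .as_seq_string(cdsA); b_cds <- .as_seq_string(cdsB)
  rowA <- .backtranslate_row(protAlnA, a_cds, ids[1L])
  rowB <- .backtranslate_row(protAlnB, b_cds, ids[2L])
  CodonAlignment(rowA, rowB, ids = ids)
}

.backtranslate_row <- function(prot_aln, cds, id) {
  gc <- geneticCode()
  prot <- gsub("-", "", prot_aln, fixed = TRUE)
  codons <- .split_codons(cds)
  if (nchar(cds) %% 3L != 0L)
    stop(sprintf("CDS length for '%s' (%d) is not a multiple of 3", id, nchar(cds)))
  aa <- gc[codons]
  if (any(is.na(aa))) stop("non-ACGT codon in CDS for ", id)
  if (aa[length(aa)] == "*") { codons <- codons[-length(codons)]; aa <- aa[-length(aa)] }
  st <- which(aa == "*")
  if (length(st))
    stop(sprintf("internal stop in CDS for '%s' at codon %d", id, st[1L]))
  if (length(codons) != nchar(prot))
    stop(sprintf("CDS/protein length mismatch for '%s': expected %d codons, observed %d",
                 id, nchar(prot), length(codons)))
  if (paste(aa, collapse = "") != prot)
    stop("protein does not translate from CDS for ", id)
  cols <- strsplit(prot_aln, "")[[1L]]
  out <- character(length(cols))
  k <- 0L
  for (i in seq_along(cols)) {
    if (cols[i] == "-") out[i] <- "---"
    else { k <- k + 1L; out[i] <- codons[k] }
  }
  paste(out, collapse = "")
}
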