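# Family identification: exact local alignment of each proteome entry against
# the conserved-domain reference, Karlin-Altschul E-values, subfamily typing
# from the two diagnostic features (basic-region deletion for Class I / PCF,
# polar R domain for CYC), and ExPASy-style physicochemical profiles.

#' Karlin-Altschul E-value
#'
#' `E = kappa * m * n * exp(-lambda * s)` for a raw local-alignment score `s`,
#' query length `m` and database size `n` (total residues searched). Strictly
#' decreasing in `s`.
#'
#' @param score raw alignment score(s).
#' @param m query length (residues).
#' @param n database size (total residues).
#' @param lambda,kappa Karlin-Altschul parameters.
#' @return E-value(s).
#' @export
karlinAltschulE <- function(score, m, n, lambda, kappa) {
  kappa * m * n * exp(-lambda * score)
}

#' Scan a proteome for a conserved domain
#'
#' Aligns every protein to the domain reference with [smithWaterman()],
#' converts scores to E-values with the database size `n` set to the total
#' residue count of `proteins`, and accepts hits with
#' `E <= eThreshold` whose aligned span on the protein lies within
#' `[0.8 * minDomainLen, 1.2 * maxDomainLen]` (the 20% slack tolerates
#' alignment fraying at the domain edges).
#'
#' @param proteins an `AAStringSet` (may be empty).
#' @param cfg a [ScanConfig-class].
#' @return A data.frame of accepted hits sorted by E-value: `protein_id`,
#'   `raw_score`, `e_value`, `hit_start`, `hit_end` (1-based inclusive on the
#'   protein), `aligned_domain_fraction`.
#' @export
scanForDomain <- function(proteins, cfg) {
  stopifnot(is(cfg, "ScanConfig"))
  empty <- data.frame(protein_id = character(), raw_score = numeric(),
                      e_value = numeric(), hit_start = integer(),
                      hit_end = integer(), aligned_domain_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (length(proteins) == 0L) return(empty)
  dom <- as.character(cfg@domainRef[[1L]])
  m <- nchar(dom)
  n_db <- sum(nchar(as.character(proteins)))
  rows <- lapply(seq_along(proteins), function(i) {
    aln <- smithWaterman(dom, as.character(proteins[[i]]),
                         substitutionMatrix = cfg@substitutionMatrix,
                         gapOpen = cfg@gapOpen, gapExtend = cfg@gapExtend)
    if (is.na(aln$subject_start)) return(NULL)
    e <- karlinAltschulE(aln$score, m, n_db, cfg@lambda, cfg@kappa)
    hit_len <- aln$subject_end - aln$subject_start + 1L
    dom_span <- aln$query_end - aln$query_start + 1L
    if (e > cfg@eThreshold) return(NULL)
    if (hit_len < 0.8 * cfg@minDomainLen || hit_len > 1.2 * cfg@maxDomainLen)
      return(NULL)
    data.frame(protein_id = names(proteins)[i], raw_score = aln$score,
               e_value = e, hit_start = aln$subject_start,
               hit_end = aln$subject_end,
               aligned_domain_fraction = dom_span / m,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$e_value, out$protein_id), , drop = FALSE]
}

# ------------------------------------------------------------ SubfamilyCall

#' Subfamily assignment for one family member
#'
#' @slot proteinId protein identifier.
#' @slot classLabel `"PCF"` (Class I), `"CIN"` or `"CYC"` (Class II).
#' @slot basicRegionGap TRUE when the domain shows the 3-5 residue deletion in
#'   the basic region that defines Class I.
#' @slot rDomainFound TRUE when a polar-rich R-domain window was found
#'   C-terminal of the domain.
#' @slot rDomainInterval 1-based protein positions of the R-domain window, or
#'   `NA` when absent.
#' @name SubfamilyCall-class
#' @aliases SubfamilyCall-class
#' @exportClass SubfamilyCall
setClass("SubfamilyCall",
  representation(proteinId = "character", classLabel = "character",
                 basicRegionGap = "logical", rDomainFound = "logical",
                 rDomainInterval = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@classLabel %in% c("PCF", "CIN", "CYC"))
      msg <- c(msg, "classLabel must be PCF, CIN or CYC")
    if (object@classLabel == "CYC" && !object@rDomainFound)
      msg <- c(msg, "CYC call requires an R domain")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SubfamilyCall", function(object) {
  cat(sprintf("SubfamilyCall %s: %s (basic-region gap: %s, R domain: %s)\n",
              object@proteinId, object@classLabel,
              object@basicRegionGap, object@rDomainFound))
})

#' @describeIn SubfamilyCall-class class-label accessor
#' @param x a `SubfamilyCall`
#' @export
subfamilyLabel <- function(x) x@classLabel

#' Classify a family member into PCF, CIN or CYC
#'
#' The hit region is aligned globally against both class reference domains.
#' Class I (PCF) is called when the alignment to the Class II reference opens
#' a deletion of 3-5 residues inside the first (basic) quarter of the
#' reference, or when the Class I reference scores strictly higher. Within
#' Class II, the protein C-terminal of the domain is scanned with a sliding
#' window; CYC is called when some window reaches the polar-residue fraction
#' threshold (residues S,T,N,Q,K,R,H,D,E), otherwise CIN.
#'
#' @param hit one row of the [scanForDomain()] result (list or 1-row
#'   data.frame with `protein_id`, `hit_start`, `hit_end`).
#' @param protein the protein sequence (`AAString`/character).
#' @param class1Ref,class2Ref reference domain sequences for Class I and
#'   Class II.
#' @param windowLen R-domain scan window length (default 20 aa).
#' @param polarFractionThreshold minimum polar fraction in a window to call an
#'   R domain (default 0.6).
#' @param substitutionMatrix,gapOpen,gapExtend scoring system for the
#'   reference alignments.
#' @return A [SubfamilyCall-class] object.
#' @export
classifySubfamily <- function(hit, protein, class1Ref, class2Ref,
                              windowLen = 20L, polarFractionThreshold = 0.6,
                              substitutionMatrix = blosum62(),
                              gapOpen = 10, gapExtend = 1) {
  p <- .as_seq_string(protein)
  hs <- as.integer(hit$hit_start); he <- as.integer(hit$hit_end)
  region <- substr(p, hs, he)
  if (nchar(region) < 20L)
    stop("classification error: domain region shorter than 20 aa for ",
         hit$protein_id)
  ref1 <- .as_seq_string(class1Ref); ref2 <- .as_seq_string(class2Ref)
  a1 <- globalAlign(region, ref1, substitutionMatrix, gapOpen, gapExtend)
  a2 <- globalAlign(region, ref2, substitutionMatrix, gapOpen, gapExtend)
  gap_evidence <- .basic_region_gap(a2$a_aln, a2$b_aln)
  is_class1 <- gap_evidence || a1$score > a2$score
  if (is_class1) {
    return(new("SubfamilyCall", proteinId = as.character(hit$protein_id),
               classLabel = "PCF", basicRegionGap = gap_evidence,
               rDomainFound = FALSE, rDomainInterval = NA_integer_))
  }
  tail_seq <- if (he < nchar(p)) substr(p, he + 1L, nchar(p)) else ""
  r <- .find_r_domain(tail_seq, windowLen, polarFractionThreshold)
  if (r$found) {
    new("SubfamilyCall", proteinId = as.character(hit$protein_id),
        classLabel = "CYC", basicRegionGap = FALSE, rDomainFound = TRUE,
        rDomainInterval = c(he + r$start, he + r$end))
  } else {
    new("SubfamilyCall", proteinId = as.character(hit$protein_id),
        classLabel = "CIN", basicRegionGap = FALSE, rDomainFound = FALSE,
        rDomainInterval = NA_integer_)
  }
}

# A Class I domain aligned to the Class II reference shows a deletion (gap in
# the query row) of 3-5 columns starting within the first quarter of the
# reference.
.basic_region_gap <- function(query_row, ref_row) {
  q <- strsplit(query_row, "")[[1L]]
  r <- strsplit(ref_row, "")[[1L]]
  ref_pos <- cumsum(r != "-")
  ref_len <- max(ref_pos)
  runs <- rle(q == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    len <- runs$lengths[k]
    # only deletions relative to the reference (ref residues present there)
    if (all(r[starts[k]:ends[k]] != "-") && len >= 3L && len <= 5L &&
        ref_pos[starts[k]] <= ceiling(ref_len / 4))
      return(TRUE)
  }
  FALSE
}

.find_r_domain <- function(tail_seq, windowLen, threshold) {
  L <- nchar(tail_seq)
  if (L < windowLen) return(list(found = FALSE))
  chars <- strsplit(tail_seq, "")[[1L]]
  polar <- as.integer(chars %in% POLAR_AA)
  cs <- c(0L, cumsum(polar))
  for (s in seq_len(L - windowLen + 1L)) {
    frac <- (cs[s + windowLen] - cs[s]) / windowLen
    if (frac >= threshold)
      return(list(found = TRUE, start = s, end = s + windowLen - 1L))
  }
  list(found = FALSE)
}

# -------------------------------------------------------- physicochemistry

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge: basic groups (N-terminus, K, R, H)
#' contribute `1/(1+10^(pH-pKa))`, acidic groups (C-terminus, D, E, C, Y)
#' contribute `-1/(1+10^(pKa-pH))`. Strictly decreasing in pH.
#'
#' @param protein protein sequence (standard residues only).
#' @param pH pH value(s).
#' @param pKa named pKa vector as in [defaultPKa()].
#' @return Net charge at each pH.
#' @export
netCharge <- function(protein, pH, pKa = defaultPKa()) {
  s <- .as_seq_string(protein)
  chars <- strsplit(s, "")[[1L]]
  counts <- table(factor(chars, levels = AA20))
  basic_pka <- c(pKa[["Nterm"]],
                 rep(pKa[["K"]], counts[["K"]]),
                 rep(pKa[["R"]], counts[["R"]]),
                 rep(pKa[["H"]], counts[["H"]]))
  acidic_pka <- c(pKa[["Cterm"]],
                  rep(pKa[["D"]], counts[["D"]]),
                  rep(pKa[["E"]], counts[["E"]]),
                  rep(pKa[["C"]], counts[["C"]]),
                  rep(pKa[["Y"]], counts[["Y"]]))
  vapply(pH, function(ph) {
    sum(1 / (1 + 10^(ph - basic_pka))) - sum(1 / (1 + 10^(acidic_pka - ph)))
  }, numeric(1L))
}

#' Physicochemical profile of a protein
#'
#' Length, average molecular weight (kDa), isoelectric point (bisection on
#' the net-charge curve to |Q| < 1e-4 within pH 0-14) and GRAVY (mean
#' Kyte-Doolittle hydropathy).
#'
#' @param protein protein sequence over the 20 standard residues (X is not
#'   allowed here).
#' @param pKa pKa table, see [defaultPKa()].
#' @param hydropathy hydropathy table, see [kyteDoolittle()].
#' @param masses residue mass table, see [averageResidueMasses()].
#' @return A list: `length_aa`, `mw_kDa`, `pI`, `gravy`.
#' @export
#' @examples
#' physicochemicalProfile("AAA")$gravy  # 1.8
physicochemicalProfile <- function(protein, pKa = defaultPKa(),
                                   hydropathy = kyteDoolittle(),
                                   masses = averageResidueMasses()) {
  s <- .as_seq_string(protein)
  if (nchar(s) == 0L) stop("profile error: empty sequence")
  chars <- strsplit(s, "")[[1L]]
  bad <- which(!chars %in% AA20)
  if (length(bad))
    stop(sprintf("profile error: nonstandard residue '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  mw <- (sum(masses[chars]) + 18.01524) / 1000
  gravy <- mean(hydropathy[chars])
  # bisection: netCharge is strictly decreasing in pH; iterate until the
  # bracketing interval collapses so flat charge curves still localize the
  # root (|Q| < 1e-4 is then guaranteed a fortiori)
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- netCharge(s, mid, pKa)
    if ((hi - lo) < 1e-6) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(length_aa = nchar(s), mw_kDa = mw, pI = mid, gravy = gravy)
}
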