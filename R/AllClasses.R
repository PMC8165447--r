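#' @include constants.R
NULL

# ---------------------------------------------------------------- ScanConfig

#' Configuration for conserved-domain scanning
#'
#' Bundles the domain reference sequence, the scoring system and the
#' Karlin-Altschul E-value statistics used by [scanForDomain()].
#'
#' @slot domainRef `AAStringSet` of length 1: the conserved-domain reference.
#' @slot substitutionMatrix numeric matrix with residue dimnames.
#' @slot gapOpen,gapExtend positive gap penalties; the first gap residue costs
#'   `gapOpen + gapExtend`.
#' @slot lambda,kappa Karlin-Altschul parameters for
#'   `E = kappa * m * n * exp(-lambda * s)`.
#' @slot eThreshold E-value acceptance threshold.
#' @slot minDomainLen,maxDomainLen expected domain length range (aa); hits are
#'   accepted when the aligned region falls within `[0.8 * min, 1.2 * max]`.
#' @name ScanConfig-class
#' @aliases ScanConfig-class
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(domainRef = "AAStringSet", substitutionMatrix = "matrix",
                 gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", kappa = "numeric",
                 eThreshold = "numeric",
                 minDomainLen = "integer", maxDomainLen = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@domainRef) != 1L || nchar(as.character(object@domainRef[[1L]])) == 0L)
      msg <- c(msg, "domainRef must be a single non-empty sequence")
    if (object@eThreshold <= 0) msg <- c(msg, "eThreshold must be > 0")
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
      msg <- c(msg, "gap penalties must be positive")
    if (object@lambda <= 0 || object@kappa <= 0)
      msg <- c(msg, "lambda and kappa must be positive")
    if (object@minDomainLen > object@maxDomainLen)
      msg <- c(msg, "minDomainLen must be <= maxDomainLen")
    if (length(msg)) msg else TRUE
  })

#' Build a domain-scan configuration
#'
#' @param domainRef the conserved-domain reference: an `AAStringSet` of length
#'   one, an `AAString`, or a single character string (optionally named).
#' @param substitutionMatrix residue scoring matrix (default BLOSUM62).
#' @param gapOpen,gapExtend affine gap penalties (default 10 and 1; the first
#'   gap residue costs 11).
#' @param lambda,kappa Karlin-Altschul statistics for the scoring system
#'   (defaults 0.267 and 0.041, the BLOSUM62 gapped values).
#' @param eThreshold E-value threshold for family membership (default 0.001).
#' @param minDomainLen,maxDomainLen expected domain length range in residues
#'   (defaults 55 and 60).
#' @return A `ScanConfig` object.
#' @export
#' @examples
#' cfg <- ScanConfig("GKDRHSKV" )
ScanConfig <- function(domainRef, substitutionMatrix = blosum62(),
                       gapOpen = 10, gapExtend = 1,
                       lambda = 0.267, kappa = 0.041,
                       eThreshold = 0.001,
                       minDomainLen = 55L, maxDomainLen = 60L) {
  if (is.character(domainRef)) {
    nm <- if (is.null(names(domainRef))) "domain" else names(domainRef)
    domainRef <- AAStringSet(setNames(domainRef, nm))
  } else if (is(domainRef, "AAString")) {
    domainRef <- AAStringSet(setNames(as.character(domainRef), "domain"))
  }
  new("ScanConfig", domainRef = domainRef,
      substitutionMatrix = substitutionMatrix,
      gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
      lambda = as.numeric(lambda), kappa = as.numeric(kappa),
      eThreshold = as.numeric(eThreshold),
      minDomainLen = as.integer(minDomainLen),
      maxDomainLen = as.integer(maxDomainLen))
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig: domain reference", names(object@domainRef)[1L],
      sprintf("(%d aa)", nchar(as.character(object@domainRef[[1L]]))), "\n")
  cat(sprintf("  gapOpen=%g gapExtend=%g lambda=%g kappa=%g E<=%g len=[%d,%d]\n",
              object@gapOpen, object@gapExtend, object@lambda, object@kappa,
              object@eThreshold, object@minDomainLen, object@maxDomainLen))
})

# --------------------------------------------------------------- KaKsResult

#' Nei-Gojobori Ka/Ks estimate for one codon-aligned pair
#'
#' Undefined quantities (e.g. Ka/Ks when Ks = 0, or a Jukes-Cantor correction
#' with p >= 3/4) are `NA`, never 0 or Inf.
#'
#' @slot S,N synonymous / nonsynonymous sites (averaged over the two rows).
#' @slot Sd,Nd synonymous / nonsynonymous differences (pathway-averaged).
#' @slot pS,pN proportions `Sd/S` and `Nd/N`.
#' @slot Ka,Ks Jukes-Cantor corrected distances.
#' @slot ratio Ka/Ks, `NA` when undefined.
#' @slot call one of `"positive"`, `"purifying"`, `"neutral"`, `"undefined"`.
#' @slot nCodons number of comparable (gap-free in both rows) codons.
#' @name KaKsResult-class
#' @aliases KaKsResult-class
#' @exportClass KaKsResult
setClass("KaKsResult",
  representation(S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
                 pS = "numeric", pN = "numeric", Ka = "numeric", Ks = "numeric",
                 ratio = "numeric", call = "character", nCodons = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@call %in% c("positive", "purifying", "neutral", "undefined"))
      msg <- c(msg, "invalid selection call")
    if (isTRUE(abs(object@S + object@N - 3 * object@nCodons) > 1e-6))
      msg <- c(msg, "S + N must equal 3 * nCodons")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "KaKsResult", function(object) {
  cat(sprintf("KaKsResult (%d codons): S=%.3f N=%.3f Sd=%.3f Nd=%.3f\n",
              object@nCodons, object@S, object@N, object@Sd, object@Nd))
  cat(sprintf("  Ka=%s Ks=%s Ka/Ks=%s [%s]\n",
              format(object@Ka, digits = 5), format(object@Ks, digits = 5),
              format(object@ratio, digits = 5), object@call))
})

#' @describeIn KaKsResult-class synonymous-site count accessor
#' @param x a `KaKsResult`
#' @export
synSites <- function(x) x@S
#' @describeIn KaKsResult-class nonsynonymous-site count accessor
#' @export
nonsynSites <- function(x) x@N
#' @describeIn KaKsResult-class synonymous-difference accessor
#' @export
synDiffs <- function(x) x@Sd
#' @describeIn KaKsResult-class nonsynonymous-difference accessor
#' @export
nonsynDiffs <- function(x) x@Nd
#' @describeIn KaKsResult-class Ka accessor
#' @export
ka <- function(x) x@Ka
#' @describeIn KaKsResult-class Ks accessor
#' @export
ks <- function(x) x@Ks
#' @describeIn KaKsResult-class Ka/Ks ratio accessor (`NA` when undefined)
#' @export
kaksRatio <- function(x) x@ratio
#' @describeIn KaKsResult-class selection-call accessor
#' @export
selectionCall <- function(x) x@call

# ----------------------------------------------------------- CodonAlignment

#' Codon-aware pairwise CDS alignment
#'
#' Two gapped coding sequences whose columns group into codon triplets: gaps
#' occur only as whole aligned codons, and neither de-gapped frame contains an
#' internal stop codon.
#'
#' @slot a,b gapped uppercase CDS strings of equal length divisible by 3.
#' @slot ids character vector of the two sequence identifiers.
#' @name CodonAlignment-class
#' @aliases CodonAlignment-class
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(a = "character", b = "character", ids = "character"),
  validity = function(object) .validate_codon_alignment(object))

.validate_codon_alignment <- function(object) {
  msg <- character()
  a <- object@a; b <- object@b
  if (nchar(a) != nchar(b)) return("rows differ in length")
  if (nchar(a) %% 3L != 0L) return("alignment length not a multiple of 3")
  gc <- geneticCode()
  for (row in list(a = a, b = b)) {
    cod <- substring(row, seq(1L, nchar(row) - 2L, by = 3L),
                     seq(3L, nchar(row), by = 3L))
    has_gap <- grepl("-", cod, fixed = TRUE)
    if (any(has_gap & cod != "---"))
      msg <- c(msg, "gaps must occupy whole codon triplets")
    deg <- cod[!has_gap]
    aa <- gc[deg]
    if (any(is.na(aa))) msg <- c(msg, "non-ACGT codon in alignment")
    else if (length(aa) > 1L && any(aa[-length(aa)] == "*"))
      msg <- c(msg, "internal stop codon")
  }
  if (length(msg)) msg else TRUE
}

#' Construct a codon alignment
#'
#' @param a,b gapped CDS strings (equal length, multiple of 3, whole-codon
#'   gaps, no internal stops).
#' @param ids identifiers for the two rows.
#' @return A [CodonAlignment-class] object.
#' @export
CodonAlignment <- function(a, b, ids = c("a", "b")) {
  new("CodonAlignment", a = toupper(a), b = toupper(b),
      ids = as.character(ids))
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment %s/%s: %d columns (%d codons)\n",
              object@ids[1L], object@ids[2L], nchar(object@a),
              nchar(object@a) %/% 3L))
})

#' @describeIn CodonAlignment-class number of alignment columns
#' @param x a `CodonAlignment`
#' @export
alignmentLength <- function(x) nchar(x@a)

# --------------------------------------------------------------- MotifTable

#' Table of cis-regulatory elements
#'
#' Element names with IUPAC consensus strings and one of three functional
#' categories: growth and development, stress response, or hormone response.
#'
#' @slot table data.frame with columns `element`, `consensus`, `category`.
#' @name MotifTable-class
#' @aliases MotifTable-class
#' @exportClass MotifTable
setClass("MotifTable", representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    msg <- character()
    need <- c("element", "consensus", "category")
    if (!all(need %in% names(tb))) return("missing columns")
    if (anyDuplicated(tb$element)) msg <- c(msg, "duplicate element names")
    if (any(nchar(tb$consensus) == 0L)) msg <- c(msg, "empty consensus")
    bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", tb$consensus)
    if (any(bad))
      msg <- c(msg, paste0("invalid IUPAC code in consensus for: ",
                           paste(tb$element[bad], collapse = ", ")))
    ok_cat <- c("growth_development", "stress", "hormone")
    if (!all(tb$category %in% ok_cat))
      msg <- c(msg, "category must be growth_development, stress or hormone")
    if (length(msg)) msg else TRUE
  })

#' Construct a motif table
#'
#' @param element character vector of unique element names.
#' @param consensus IUPAC DNA consensus strings (A,C,G,T plus ambiguity codes).
#' @param category one of `"growth_development"`, `"stress"`, `"hormone"` per
#'   element.
#' @return A [MotifTable-class] object.
#' @export
MotifTable <- function(element, consensus, category) {
  new("MotifTable", table = data.frame(
    element = as.character(element),
    consensus = toupper(as.character(consensus)),
    category = as.character(category), stringsAsFactors = FALSE))
}

setMethod("show", "MotifTable", function(object) {
  cat(sprintf("MotifTable: %d elements (%s)\n", nrow(object@table),
      paste(sprintf("%s=%d", names(table(object@table$category)),
                    as.integer(table(object@table$category))), collapse = ", ")))
})

#' @describeIn MotifTable-class underlying data.frame accessor
#' @param x a `MotifTable`
#' @export
motifTable <- function(x) x@table

# ------------------------------------------------------------------ CtTable

#' Replicated qPCR Ct table
#'
#' Long-format threshold-cycle measurements with a designated reference gene
#' (internal control) and calibrator sample for the Livak 2^-ddCt method.
#'
#' @slot data data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @slot referenceGene the internal reference (housekeeping) gene id.
#' @slot calibratorSample the sample all fold changes are expressed against.
#' @name CtTable-class
#' @aliases CtTable-class
#' @exportClass CtTable
setClass("CtTable",
  representation(data = "data.frame", referenceGene = "character",
                 calibratorSample = "character"),
  validity = function(object) {
    d <- object@data
    msg <- character()
    need <- c("sample", "gene", "replicate", "ct")
    if (!all(need %in% names(d))) return("missing columns")
    if (!object@calibratorSample %in% d$sample)
      return(sprintf("calibrator sample '%s' absent from table",
                     object@calibratorSample))
    reps <- table(d$sample, d$gene)
    if (any(reps > 0 & reps < 2))
      msg <- c(msg, "every (sample, gene) needs >= 2 replicates")
    samples <- unique(d$sample)
    has_ref <- vapply(samples, function(s)
      object@referenceGene %in% d$gene[d$sample == s], logical(1L))
    if (!all(has_ref))
      msg <- c(msg, sprintf("reference gene '%s' missing in sample(s): %s",
                            object@referenceGene,
                            paste(samples[!has_ref], collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a Ct table
#'
#' @param data data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param referenceGene internal reference gene id (present in every sample).
#' @param calibratorSample the calibrator sample id.
#' @return A [CtTable-class] object.
#' @export
CtTable <- function(data, referenceGene, calibratorSample) {
  new("CtTable", data = as.data.frame(data),
      referenceGene = as.character(referenceGene),
      calibratorSample = as.character(calibratorSample))
}

setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat(sprintf("CtTable: %d measurements, %d samples x %d genes; ref=%s, calibrator=%s\n",
              nrow(d), length(unique(d$sample)), length(unique(d$gene)),
              object@referenceGene, object@calibratorSample))
})

#' @describeIn CtTable-class long-format measurement accessor
#' @param x a `CtTable`
#' @export
ctData <- function(x) x@data
#' @describeIn CtTable-class reference-gene accessor
#' @export
referenceGene <- function(x) x@referenceGene
#' @describeIn CtTable-class calibrator-sample accessor
#' @export
calibratorSample <- function(x) x@calibratorSample

# -------------------------------------------------------------- FamilyTruth

#' Ground truth emitted by the synthetic-genome simulator
#'
#' Records everything the simulator planted, sufficient to score every
#' downstream analysis stage without re-deriving anything.
#'
#' @slot members data.frame: gene_id, subfamily, domain_start, domain_end
#'   (1-based on the protein), chromosome, is_family.
#' @slot duplicates data.frame: gene_a, gene_b, true_type, omega, n_events.
#' @slot promoterElements data.frame: gene_id, element, offset, strand.
#' @slot expression data.frame: sample, gene, true_fold.
#' @name FamilyTruth-class
#' @aliases FamilyTruth-class
#' @exportClass FamilyTruth
setClass("FamilyTruth",
  representation(members = "data.frame", duplicates = "data.frame",
                 promoterElements = "data.frame", expression = "data.frame"))

setMethod("show", "FamilyTruth", function(object) {
  cat(sprintf("FamilyTruth: %d genes (%d family), %d duplicate pairs, %d planted elements\n",
              nrow(object@members), sum(object@members$is_family),
              nrow(object@duplicates), nrow(object@promoterElements)))
})

#' @describeIn FamilyTruth-class planted family-member truth
#' @param x a `FamilyTruth`
#' @export
truthMembers <- function(x) x@members
#' @describeIn FamilyTruth-class planted duplicate-pair truth
#' @export
truthDuplicates <- function(x) x@duplicates
#' @describeIn FamilyTruth-class planted promoter-element truth
#' @export
truthPromoterElements <- function(x) x@promoterElements
#' @describeIn FamilyTruth-class planted expression truth
#' @export
truthExpression <- function(x) x@expression
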