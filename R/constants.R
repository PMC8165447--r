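# Physicochemical reference tables. These ship as defaults and every consumer
# takes them as arguments, so alternative parameterizations can be supplied
# without touching package code.

#' Kyte-Doolittle hydropathy values
#'
#' Per-residue hydropathy indices used for GRAVY (grand average of hydropathy).
#' Positive values are hydrophobic, negative hydrophilic.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
#' @examples
#' kyteDoolittle()[["A"]]
kyteDoolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Average residue masses
#'
#' Average (not monoisotopic) masses of amino-acid residues in Daltons, i.e.
#' the free amino acid minus one water. Protein mass = sum of residues plus
#' one water (18.01524 Da).
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
averageResidueMasses <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
}

#' Ionizable-group pKa values
#'
#' EMBOSS-style pKa set used for isoelectric-point calculation: side chains of
#' C, D, E, H, K, R, Y plus the free termini. Basic groups (positive when
#' protonated) are the N-terminus, K, R and H; the rest are acidic.
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `C`, `D`, `E`,
#'   `H`, `K`, `R`, `Y`.
#' @export
defaultPKa <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

# amino-acid alphabet (20 standard residues)
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# polar residues used for R-domain detection
POLAR_AA <- c("S", "T", "N", "Q", "K", "R", "H", "D", "E")

# IUPAC nucleotide code expansion
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# BLOSUM62, loaded once from Biostrings
.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' @return The BLOSUM62 scoring matrix (integer matrix with residue dimnames).
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

# standard genetic code on DNA codons; names are codons, values one-letter AA,
# "*" for stop
geneticCode <- function() Biostrings::GENETIC_CODE

SENSE_CODONS <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
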