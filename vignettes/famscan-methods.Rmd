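---
title: "famscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

famscan implements the comparative workflow used in genome-wide surveys of
plant transcription-factor families — domain-based identification, subfamily
classification, distance phylogeny, duplication typing, Ka/Ks selection
analysis, promoter element census and qPCR quantification — together with a
simulator that generates study-shaped inputs with known truth. This vignette
explains each model, the parameters that matter, and the choices made where
the design was genuinely open.

## Family identification

Each proteome entry is aligned to a conserved-domain reference by exact
Smith–Waterman with affine gaps. The first residue of a gap costs
`gapOpen + gapExtend` (defaults 10 + 1), each further residue `gapExtend`.
Traceback is deterministic: at score ties, diagonal beats up beats left, and
gap openings beat extensions, so identical inputs always yield the identical
alignment. Significance uses the Karlin–Altschul formula
`E = kappa * m * n * exp(-lambda * score)` with `m` the domain length and
`n` the total residue count of the proteome scanned. `lambda = 0.267` and
`kappa = 0.041` are the familiar BLOSUM62 gapped-search constants; they are
configuration, not estimates, because the E-value here only ranks and gates
hits within a small, fully scanned database. A hit is accepted when
`E <= 0.001` and the aligned span on the protein lies within
`[0.8 * 55, 1.2 * 60]` residues; the 20% slack tolerates fraying at the
domain edges, where local alignment may shed a few weakly scoring columns.

An exact aligner replaces a heuristic search deliberately: with databases of
tens of proteins, exactness costs nothing and gives a testable contract (the
suite compares scores against an independent quadratic-space reference
implementation).

### Subfamily typing

Two diagnostic features define the classes in this family architecture:
Class I (PCF) domains lack four residues in the basic region; CYC members of
Class II additionally carry a hydrophilic, polar-rich α-helical R domain.
The classifier aligns the hit region globally against both class reference
domains. Class I is called when the alignment to the Class II reference
opens a deletion of 3–5 residues beginning in the first quarter of the
reference, or when the Class I reference simply outscores the Class II one.
The "first quarter" boundary for the basic region is a stated convention of
this package — the literature defines the basic region structurally, not by
coordinate — and is the natural reading for a domain whose N-terminal
quarter is the basic segment. Within Class II, the sequence C-terminal of
the domain is scanned with a 20-residue window; CYC is called when any
window reaches a polar fraction (S,T,N,Q,K,R,H,D,E) of at least 0.6. Both
the window length and the threshold are exposed as parameters.

### Physicochemical profiles

Molecular weight sums average residue masses plus one water (18.01524 Da)
and is reported in kDa. The isoelectric point solves `Q(pH) = 0` where
basic groups (N-terminus, K, R, H) contribute `1/(1 + 10^(pH - pKa))` and
acidic groups (C-terminus, D, E, C, Y) `-1/(1 + 10^(pKa - pH))`. Because
every term is strictly decreasing in pH the root is unique; bisection runs
until the bracketing interval is below 1e-6 pH units, which localizes the
root even where the charge curve is nearly flat (a two-group dipeptide, for
instance, where the midpoint of the termini pKa values is the closed form).
GRAVY is the mean Kyte–Doolittle hydropathy. The pKa (EMBOSS-style), mass
and hydropathy tables ship as editable defaults, since published studies
delegate these constants to web services without stating them.

## Alignment and phylogeny

The progressive aligner builds a UPGMA guide tree from Euclidean distances
between 3-mer count vectors, then merges profiles leaf-upward with
profile–profile Needleman–Wunsch under sum-of-pairs scoring (column score
`f_A' M f_B` over residue frequencies; gap symbols carry zero mass). Ties
resolve by input order. This is a deliberately compact stand-in for a
full aligner: for families that share a long, well-conserved domain —
the regime the pipeline targets — the guide tree and the profile merges are
dominated by the domain anchor, and the suite verifies the contracts that
matter downstream (rows de-gap to their inputs, two sequences reproduce the
optimal pairwise alignment, column count bounds).

Distances use pairwise deletion: for each pair, `p` is the mismatch fraction
over columns where both rows are residues. The default model is the
p-distance itself, with `-ln(1 - p)` (Poisson correction) as an option; the
default follows the common default of distance-matrix tools for amino-acid
NJ trees, and is configuration, not a claim about any particular published
figure. A pair with no comparable columns is an error naming the pair.

Neighbor joining is the Saitou–Nei agglomeration on
`Q_ij = (r - 2) d_ij - R_i - R_j`, with branch lengths
`l_i = d_ij/2 + (R_i - R_j) / (2(r - 2))`, negative lengths clamped to zero,
ties broken on the smallest (i, j) index pair, and the final three nodes
joined at an unrooted trifurcation. On additive matrices NJ provably
recovers the generating topology with exact path lengths; the suite checks
this on random 8-leaf trees (edge lengths uniform in [0.1, 2]) and against
`ape::nj` as an independent implementation. Serialized trees write branch
lengths with six decimals, terminated by `;`, and re-parse to an isomorphic
tree.

## Duplication events and selection

Candidate duplicate pairs are sister leaves (cherries) of the family tree —
the strictest reading of "located in the same branch". A pair is retained
when global protein alignment identity exceeds 80% (identity, not
similarity-with-substitution-classes; the looser reading is a one-line
change in the identity function and was not taken because identity is the
checkable convention). Retained pairs are typed: same chromosome with
start-to-start separation at most 200 kb → tandem; different chromosomes →
segmental; same chromosome beyond the bound → unclassified (segmental is
defined across chromosomes only, so distant same-chromosome pairs are not
forced into it); either gene on an unplaced scaffold → unclassified with the
relation flagged. The 200 kb bound is the conventional proximity reading of
the tandem criterion.

Ka/Ks follows Nei–Gojobori (1986). Per codon, each of the nine
single-nucleotide neighbors is synonymous or nonsynonymous (stop-creating
changes count as nonsynonymous, the standard convention); the synonymous
site count is the per-position synonymous fraction summed over the three
positions, so `s + n = 3` exactly. For a codon pair differing at `k`
positions, all `k!` substitution orderings are enumerated; pathways passing
through a stop are discarded and the step counts averaged over the rest —
unless every pathway hits a stop, in which case all orderings are used with
stop-passing steps counted as nonsynonymous. `sd + nd = k` always, so
window sums tile consistently. Proportions `pS = Sd/S`, `pN = Nd/N` are
Jukes–Cantor corrected, `d = -(3/4) ln(1 - 4p/3)`; `p >= 3/4` leaves the
distance undefined. The ratio is undefined whenever `Ks = 0` or a
correction is undefined, and undefined is a first-class value (`NA`),
never zero or infinity — sliding-window plots then show gaps rather than
spurious zeros. Selection calls use the conventional thresholds with a
numerical tolerance of 1e-9 around 1. All per-codon and per-codon-pair
counts are precomputed over the 61 sense codons once per session, making
whole-gene and windowed estimates table lookups.

Sliding windows default to 150 nt stepping 9 nt (both must be positive
multiples of 3), starting at column 1 and advancing while the window fits:
a 300-column alignment yields exactly 17 windows, [1,150] through [145,294].

## The simulator

The generator's role is to produce inputs with exactly the structure each
stage assumes, plus truth tables sufficient to score every stage without
re-deriving anything. Its defaults define the package's study conditions:

- **Family genomes.** 3 chromosomes; 6 single members (3 PCF, 2 CIN,
  1 CYC); one tandem pair (start-to-start separation drawn uniformly in
  20–100 kb, within the 200 kb bound) and one segmental pair; 10 background
  genes with random, domain-free CDS so scan specificity is measurable.
  Members embed the Class II reference domain (Class I members the
  4-residue-deleted variant, CYC members an appended polar 20-mer), with two
  random substitutions outside the basic region so members are not literal
  reference copies. All genes are single-exon with an ATG..stop CDS, placed
  with at least ~1.7 kb of gene-free margin upstream of every ATG so
  full-length promoters always exist; flank residues are sampled with a 3:1
  bias toward non-polar residues so random flanks do not trip the R-domain
  detector at its 0.6 threshold — real proteomes are not composition-biased
  this way, which is one reason synthetic specificity is an upper bound on
  real-data specificity.
- **Codon-pair evolution** is an acceptance–rejection scheme rather than a
  continuous-time codon model: per proposal round, a uniform random
  single-nucleotide change is accepted with probability 1 if synonymous and
  `min(omega, 1)` if nonsynonymous (for `omega > 1` the synonymous
  probability becomes `1/omega` instead); stop-creating proposals are always
  rejected, matching the estimator's assumption that stops do not occur.
  This makes the realized nonsynonymous:synonymous event ratio directly
  controllable, which is the property the estimator is validated against.
  Duplicate pairs default to `omega = 0.3` with 90 proposal rounds (about
  90% protein identity, safely above the 80% retention threshold); the
  optional low-identity decoy pairs use `omega = 1` with 100 rounds (about
  65–72% identity, safely below), exercising the exclusion rule.
- **Promoter planting** replaces (never inserts) bases with a concrete
  instance of the element's IUPAC consensus at a stated offset. After
  planting, touched promoters are re-scanned and accidental forward-strand
  matches of any table motif are destroyed by single-base edits outside the
  planted intervals, iterating to a fixed pass bound; together with a
  default motif table whose consensus strings are pairwise substring-free,
  this makes "every planted occurrence, and nothing else" a well-defined
  target on random background. Minus-strand planting of one of a
  palindromic partner pair (e.g. CGTCA/TGACG) necessarily creates the
  partner's forward match, so exact-census claims apply to plus-strand
  plans.
- **Ct tables** are `baseline - log2(fold) + N(0, noiseSd)` per replicate,
  with the reference gene at fold 1 everywhere. With `noiseSd = 0` the
  Livak estimator inverts the design exactly (to machine precision), which
  the suite asserts with `expect_identical`.

Every generator is a pure function of (spec, seed); reruns are
byte-identical.

## Expression analysis choices

Replicate ΔCt pairs target and reference by replicate index — the
within-run pairing a plate layout implies; an unpaired mean-vs-mean variant
is available (`pairing = "mean"`). Dispersion is summarized as the ΔCt
standard deviation and exponentiated afterwards (`2^-(ddCt ± sd)`), the
Livak convention, rather than propagated through the fold nonlinearly.
"Responds to treatment" is operationalized as a two-sided Welch test on
replicate ΔCt against the 0-hour calibrator with p < 0.05 *and* a two-fold
change in either direction; published descriptions of such time courses
state no test, so the rule is a documented package choice, and the fold gate
means statistically crisp but small shifts are deliberately not called.
Degenerate inputs (identical replicate values, where the t statistic is
undefined) are treated as non-significant rather than errors.

## Pipeline, problem sizes and limitations

`runPipeline()` composes the stages in dependency order over either a
simulated study or FASTA/GFF3/TSV inputs on disk, writing one TSV per stage
plus a manifest with the seed, a config hash and per-stage row counts; rerun
outputs are byte-identical apart from the manifest timestamp. Configuration
is validated — file existence, parameter ranges — before any stage runs.

The test and validation runs use deliberately compact sizes chosen so the
full suite exercises every stage many times over: 8-leaf trees for NJ
consistency (100 replicates), 500-codon pairs with 300 proposal rounds for
ω recovery (50 replicates per ω), 20 simulated genomes for duplication
typing, a 34-gene genome for the 75-occurrence census fixture, and 200
replicates for the noisy ΔΔCt average. These sizes are the package's own
validation conditions; nothing in the methods depends on them.

Known limitations: the aligner is a compact progressive implementation, not
a drop-in for a full MSA tool on families without a shared anchor domain;
no bootstrap support values; no maximum-likelihood dN/dS (counting methods
underestimate under strong rate heterogeneity); no synteny-based
collinearity evidence for segmental calls (chromosomal relation only); no
amplification-efficiency correction in the qPCR model; and the simulator
evolves substitutions only — no indels, so alignment inference is never
stressed by the synthetic data.
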