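test_that("NG86 site counts match enumeration of the standard code", {
  expect_equal(ng86CountSites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86CountSites("ATG"), c(s = 0, n = 3))
  expect_error(ng86CountSites("TAA"), "stop codon")

  # s + n = 3 and agreement with the independent enumerator on all 61 codons
  gc <- Biostrings::GENETIC_CODE
  for (codon in names(gc)[gc != "*"]) {
    got <- ng86CountSites(codon)
    expect_equal(unname(sum(got)), 3)
    expect_equal(got, oracle_sites(codon), tolerance = 1e-12)
  }
})

test_that("NG86 difference counts average over stop-free pathways", {
  expect_equal(ng86CountDifferences("GGA", "GGG"), c(sd = 1, nd = 0))
  expect_equal(ng86CountDifferences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_equal(ng86CountDifferences("AAA", "AAA"), c(sd = 0, nd = 0))
})

test_that("pathway averaging conserves the Hamming distance", {
  set.seed(17)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in 1:200) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    d <- ng86CountDifferences(a, b)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(d)), k)
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukesCantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(round(jukesCantor(0.1), 6), 0.107326)
  expect_true(is.na(jukesCantor(0.75)))
  expect_true(is.na(jukesCantor(0.9)))
})

test_that("kaksPair handles identical rows, symmetry and codon-pair fixtures", {
  cds <- "ATGAAACCCGGGTTT"
  kk <- kaksPair(CodonAlignment(cds, cds))
  expect_equal(synDiffs(kk), 0)
  expect_equal(nonsynDiffs(kk), 0)
  expect_equal(ka(kk), 0)
  expect_equal(ks(kk), 0)
  expect_true(is.na(kaksRatio(kk)))
  expect_equal(selectionCall(kk), "undefined")
  expect_equal(synSites(kk) + nonsynSites(kk), 3 * 5)

  set.seed(23)
  a <- random_sense_cds(40); b <- random_sense_cds(40)
  k1 <- kaksPair(CodonAlignment(a, b))
  k2 <- kaksPair(CodonAlignment(b, a))
  expect_equal(synSites(k1), synSites(k2))
  expect_equal(synDiffs(k1), synDiffs(k2))
  expect_equal(ka(k1), ka(k2))
})

test_that("codon alignment invariants are enforced", {
  expect_error(CodonAlignment("ATGAAA", "ATGA"), "length")
  expect_error(CodonAlignment("ATGA-A", "ATGAAA"), "whole codon")
  expect_error(CodonAlignment("ATGTAAAAA", "ATGAAAAAA"), "internal stop")
  # trailing stop is allowed
  expect_s4_class(CodonAlignment("ATGAAATAA", "ATGAAATAA"), "CodonAlignment")
})

test_that("aggregate NG86 counts match the brute-force oracle", {
  set.seed(31)
  for (i in 1:25) {
    a <- random_sense_cds(50); b <- random_sense_cds(50)
    kk <- kaksPair(CodonAlignment(a, b))
    ref <- oracle_pair_counts(a, b)
    expect_equal(synSites(kk), ref[["S"]], tolerance = 1e-9)
    expect_equal(nonsynSites(kk), ref[["N"]], tolerance = 1e-9)
    expect_equal(synDiffs(kk), ref[["Sd"]], tolerance = 1e-9)
    expect_equal(nonsynDiffs(kk), ref[["Nd"]], tolerance = 1e-9)
  }
})

test_that("sliding windows tile the alignment per the stated bookkeeping", {
  set.seed(37)
  a <- random_sense_cds(100); b <- random_sense_cds(100)
  aln <- CodonAlignment(a, b)
  w <- slidingWindowKaks(aln, 150L, 9L)
  expect_equal(nrow(w), 17L)
  expect_equal(w$start_nt[1], 1L)
  expect_equal(w$end_nt[1], 150L)
  expect_equal(w$start_nt[17], 145L)
  expect_equal(w$end_nt[17], 294L)

  # disjoint tiling sums to the whole-gene differences
  tiles <- slidingWindowKaks(aln, 30L, 30L)
  whole <- kaksPair(aln)
  expect_equal(sum(tiles$Sd), synDiffs(whole))
  expect_equal(sum(tiles$Nd), nonsynDiffs(whole))

  # identical alignment: every window undefined
  w0 <- slidingWindowKaks(CodonAlignment(a, a), 150L, 9L)
  expect_true(all(w0$call == "undefined"))
  expect_true(all(is.na(w0$ratio)))

  expect_error(slidingWindowKaks(aln, 3000L, 9L), "larger than alignment")
  expect_error(slidingWindowKaks(aln, 100L, 9L), "multiples of 3")
})

test_that("window ratios rise across a junction between selection regimes", {
  lowA <- evolveCodonPair(120, 0.05, 150, seed = 401)
  hiA <- evolveCodonPair(120, 1.0, 150, seed = 402)
  a <- paste0(lowA$cdsA, hiA$cdsA)
  b <- paste0(lowA$cdsB, hiA$cdsB)
  w <- slidingWindowKaks(CodonAlignment(a, b), 150L, 9L)
  half <- nrow(w) %/% 2
  first <- mean(w$ratio[seq_len(half)], na.rm = TRUE)
  last <- mean(w$ratio[seq(nrow(w) - half + 1, nrow(w))], na.rm = TRUE)
  expect_gt(last, first)
})

test_that("protein alignments back-translate to codon alignments", {
  # gapless round trip
  cds <- "ATGAAACCCGGGTTT"
  ca <- mapProteinAlignmentToCodons("MKPGF", "MKPGF", cds, cds)
  expect_equal(ca@a, cds)
  expect_equal(alignmentLength(ca), 15L)

  # protein gap becomes an aligned triplet at columns 7-9
  cds_a <- "ATGGCAGTT"          # M A V
  cds_b <- "ATGGCACATGTC"       # M A H V
  ca <- mapProteinAlignmentToCodons("MA-V", "MAHV", cds_a, cds_b)
  expect_equal(substr(ca@a, 7, 9), "---")
  expect_equal(substr(ca@b, 7, 9), "CAT")

  # trailing stop accepted and trimmed
  ca <- mapProteinAlignmentToCodons("MAV", "MAV", "ATGGCAGTTTAA", "ATGGCAGTT")
  expect_equal(alignmentLength(ca), 9L)

  expect_error(mapProteinAlignmentToCodons("MAV", "MAV", "ATGGCA", "ATGGCAGTT"),
               "expected 3 codons, observed 2")
  expect_error(mapProteinAlignmentToCodons("MAV", "MAV",
                                           "ATGTAAGCAGTT", "ATGGCAGTT"),
               "internal stop")
})

test_that("duplication typing follows the chromosomal rules", {
  base <- paste0("M", strrep("AVLIKE", 30))
  p1 <- base
  p2 <- paste0(substr(base, 1, 170), "WWWWWWWWFFF")  # ~94% identical to p1
  p3 <- paste0("M", strrep("AVLIKE", 10), strrep("WFYC", 30))  # diverged
  prots <- Biostrings::AAStringSet(c(g1 = p1, g2 = p2, g3 = p3, g4 = p1))
  set.seed(77)
  cds <- Biostrings::DNAStringSet(vapply(
    as.character(prots), famscan:::.reverse_translate, ""))
  names(cds) <- names(prots)

  w <- Biostrings::width(cds)
  starts <- c(10000L, 60000L, 10000L, 10000L)
  genes <- geneModels(
    gene_id = c("g1", "g2", "g3", "g4"),
    chromosome = c("chr1", "chr1", "chr2", "chr3"),
    strand = c("+", "+", "+", "+"),
    start = starts, end = starts + w - 1L,
    cds = IRanges::IRangesList(
      IRanges::IRanges(starts[1], starts[1] + w[1] - 1L),
      IRanges::IRanges(starts[2], starts[2] + w[2] - 1L),
      IRanges::IRanges(starts[3], starts[3] + w[3] - 1L),
      IRanges::IRanges(starts[4], starts[4] + w[4] - 1L)))

  # tandem: g1/g2 sisters, same chromosome, 50 kb apart
  tree <- ape::read.tree(text = "((g1:0.02,g2:0.02):0.3,(g3:0.2,g4:0.2):0.3);")
  ev <- classifyDuplications(genes, prots, cds, tree)
  expect_equal(nrow(ev), 1L)   # g3/g4 sisters but identity too low
  expect_equal(ev$dup_type, "tandem")
  expect_equal(ev$separation_bp, 50000L)

  # segmental: g1/g4 sisters on different chromosomes, high identity
  tree <- ape::read.tree(text = "((g1:0.02,g4:0.02):0.3,(g2:0.2,g3:0.2):0.3);")
  ev <- classifyDuplications(genes, prots, cds, tree)
  expect_equal(ev$dup_type, "segmental")
  expect_true(is.na(ev$separation_bp))
  expect_equal(ev$chromosomal_relation, "different_chromosome")

  # same chromosome beyond the bound -> unclassified
  ev <- classifyDuplications(genes, prots, cds,
                             ape::read.tree(text = "((g1:0.1,g2:0.1):0.3,(g3:0.2,g4:0.2):0.3);"),
                             tandemMaxSeparationBp = 10000L)
  expect_equal(ev$dup_type, "unclassified")

  # unplaced scaffolds are flagged, not typed
  ev <- classifyDuplications(genes, prots, cds,
                             ape::read.tree(text = "((g1:0.1,g4:0.1):0.3,(g2:0.2,g3:0.2):0.3);"),
                             unplaced = "chr3")
  expect_equal(ev$chromosomal_relation, "unplaced")
  expect_equal(ev$dup_type, "unclassified")

  # tree leaf missing from the models
  expect_error(classifyDuplications(genes, prots, cds,
                                    ape::read.tree(text = "((g1:1,gX:1):1,(g3:1,g4:1):1);")),
               "gX")
})

test_that("planted duplicate pairs are recovered with their true type", {
  refs <- defaultDomainRefs()
  cfg <- ScanConfig(refs$class2)
  for (seed in 1:5) {
    sim <- generateFamilyGenome(familySpec(nLowIdentityPairs = 1L,
                                           nBackground = 0L), seed = seed)
    tm <- truthMembers(sim$truth)
    fam <- tm$gene_id[tm$is_family]
    aln <- progressiveMSA(sim$proteins[fam])
    tree <- buildNJTree(proteinDistanceMatrix(aln))
    ev <- classifyDuplications(sim$genes, sim$proteins, sim$cds, tree)
    td <- truthDuplicates(sim$truth)
    for (k in seq_len(nrow(td))) {
      key <- paste(sort(c(td$gene_a[k], td$gene_b[k])), collapse = "|")
      got <- ev[paste(ev$gene_a, ev$gene_b, sep = "|") == key, ]
      if (td$true_type[k] == "low_identity") {
        expect_equal(nrow(got), 0L, info = paste("seed", seed))
      } else {
        expect_equal(nrow(got), 1L, info = paste("seed", seed))
        expect_equal(got$dup_type, td$true_type[k], info = paste("seed", seed))
        expect_equal(got$call, "purifying", info = paste("seed", seed))
      }
    }
  }
})
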