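test_that("codon-pair evolution respects its acceptance rules", {
  # zero events: identical copies
  ev <- evolveCodonPair(20, 0.5, 0, seed = 1)
  expect_equal(ev$cdsA, ev$cdsB)
  expect_equal(ev$acceptedSyn + ev$acceptedNonsyn, 0L)

  # omega = 0: nonsynonymous proposals never accepted
  ev <- evolveCodonPair(50, 0, 50, seed = 2)
  expect_equal(ev$acceptedNonsyn, 0L)
  expect_equal(famscan:::.translate_cds(ev$cdsA),
               famscan:::.translate_cds(ev$cdsB))

  # no stop codons ever created
  for (s in 1:5) {
    ev <- evolveCodonPair(50, 2, 100, seed = s)
    expect_no_error(famscan:::.translate_cds(ev$cdsB))
  }

  expect_error(evolveCodonPair(50, -0.1, 10), "omega")
  expect_error(evolveCodonPair(5, 0.5, 10), ">= 10 codons")
})

test_that("evolution is reproducible from its seed", {
  e1 <- evolveCodonPair(60, 0.4, 80, seed = 99)
  e2 <- evolveCodonPair(60, 0.4, 80, seed = 99)
  expect_identical(e1, e2)
})

test_that("member counts and labels match the family specification", {
  sim <- generateFamilyGenome(familySpec(nPCF = 3L, nCIN = 2L, nCYC = 1L,
                                         nTandemPairs = 0L,
                                         nSegmentalPairs = 0L,
                                         nBackground = 4L), seed = 3)
  tm <- truthMembers(sim$truth)
  expect_equal(sum(tm$is_family), 6L)
  expect_equal(unname(table(tm$subfamily)[c("CIN", "CYC", "PCF")]),
               c(2L, 1L, 3L), ignore_attr = TRUE)
  expect_equal(length(sim$proteins), 10L)
  expect_equal(length(sim$genome), 3L)
  # domain truly embedded at the recorded interval
  fam <- tm[tm$is_family, ]
  for (i in seq_len(nrow(fam))) {
    dom <- substr(as.character(sim$proteins[[fam$gene_id[i]]]),
                  fam$domain_start[i], fam$domain_end[i])
    ref <- if (fam$subfamily[i] == "PCF") defaultDomainRefs()$class1
           else defaultDomainRefs()$class2
    expect_equal(nchar(dom), nchar(ref))
  }
})

test_that("tandem pairs land on one chromosome within the drawn separation", {
  spec <- familySpec(nTandemPairs = 1L, nSegmentalPairs = 1L,
                     tandemSeparationRange = c(50000L, 50000L))
  sim <- generateFamilyGenome(spec, seed = 8)
  td <- truthDuplicates(sim$truth)
  g <- sim$genes
  ids <- S4Vectors::mcols(g)$gene_id
  tp <- td[td$true_type == "tandem", ]
  ia <- match(tp$gene_a, ids); ib <- match(tp$gene_b, ids)
  expect_equal(as.character(GenomicRanges::seqnames(g)[ia]),
               as.character(GenomicRanges::seqnames(g)[ib]))
  expect_equal(abs(GenomicRanges::start(g)[ib] - GenomicRanges::start(g)[ia]),
               50000L)
  sp <- td[td$true_type == "segmental", ]
  ia <- match(sp$gene_a, ids); ib <- match(sp$gene_b, ids)
  expect_false(as.character(GenomicRanges::seqnames(g)[ia]) ==
                 as.character(GenomicRanges::seqnames(g)[ib]))
})

test_that("the generator is a pure function of (spec, seed)", {
  s1 <- generateFamilyGenome(familySpec(), seed = 5)
  s2 <- generateFamilyGenome(familySpec(), seed = 5)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(as.character(s1$proteins), as.character(s2$proteins))
  expect_identical(truthMembers(s1$truth), truthMembers(s2$truth))
  s3 <- generateFamilyGenome(familySpec(), seed = 6)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("emitted annotation is internally consistent", {
  sim <- generateFamilyGenome(familySpec(), seed = 9)
  g <- sim$genes
  ids <- S4Vectors::mcols(g)$gene_id
  for (i in seq_along(g)) {
    chr <- as.character(GenomicRanges::seqnames(g)[i])
    piece <- substr(as.character(sim$genome[[chr]]),
                    GenomicRanges::start(g)[i], GenomicRanges::end(g)[i])
    if (as.character(GenomicRanges::strand(g)[i]) == "-")
      piece <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(piece)))
    expect_equal(piece, as.character(sim$cds[[ids[i]]]))
    expect_equal(famscan:::.translate_cds(piece),
                 as.character(sim$proteins[[ids[i]]]))
    expect_equal(S4Vectors::mcols(g)$cds_len[i] %% 3L, 0L)
  }
})

test_that("genome round-trips through FASTA and GFF3 on disk", {
  sim <- generateFamilyGenome(familySpec(nBackground = 2L), seed = 10)
  fa <- tempfile(fileext = ".fna"); gff <- tempfile(fileext = ".gff3")
  writeFasta(sim$genome, fa)
  writeGFF3(sim$genes, gff)
  genome2 <- readFasta(fa, "dna")
  expect_equal(as.character(genome2), as.character(sim$genome))
  suppressMessages(genes2 <- readGFF3(gff))
  expect_equal(S4Vectors::mcols(genes2)$gene_id,
               S4Vectors::mcols(sim$genes)$gene_id)
  expect_equal(GenomicRanges::start(genes2), GenomicRanges::start(sim$genes))
  expect_equal(as.character(GenomicRanges::strand(genes2)),
               as.character(GenomicRanges::strand(sim$genes)))
})

test_that("inconsistent specs error before any work", {
  expect_error(generateFamilyGenome(familySpec(nChromosomes = 1L,
                                               nSegmentalPairs = 1L)),
               "cross-chromosome")
  expect_error(generateFamilyGenome(
    familySpec(tandemSeparationRange = c(10000L, 250000L))), "200 kb")
})

test_that("an empty planting plan leaves the genome untouched", {
  sim <- generateFamilyGenome(familySpec(), seed = 11)
  out <- plantPromoterElements(sim$genome, sim$genes, defaultMotifTable(),
                               data.frame(gene_id = character(),
                                          element = character(),
                                          offset = integer(),
                                          strand = character()))
  expect_identical(as.character(out$genome), as.character(sim$genome))
  expect_equal(nrow(out$truth), 0L)
})
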