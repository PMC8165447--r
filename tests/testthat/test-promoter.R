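.mini_genome <- function() {
  set.seed(101)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  Biostrings::DNAStringSet(c(chr1 = chr1))
}

test_that("promoter extraction is strand-aware with 1-based coordinates", {
  genome <- .mini_genome()
  genes <- geneModels(
    gene_id = c("plus", "minus"),
    chromosome = c("chr1", "chr1"),
    strand = c("+", "-"),
    start = c(5000L, 9100L), end = c(5899L, 10000L),
    cds = IRanges::IRangesList(IRanges::IRanges(5000L, 5899L),
                               IRanges::IRanges(9100L, 10000L)))
  prom <- extractPromoters(genome, genes, 1500L)
  chr <- as.character(genome[["chr1"]])

  # plus strand: genomic [3500, 4999]
  expect_equal(as.character(prom[["plus"]]), substr(chr, 3500, 4999))
  expect_equal(S4Vectors::mcols(prom)$genomic_start[1], 3500L)
  expect_equal(S4Vectors::mcols(prom)$genomic_end[1], 4999L)

  # minus strand: genomic [10001, 11500], reverse-complemented
  expect_equal(as.character(prom[["minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 10001, 11500)))))
  expect_false(any(S4Vectors::mcols(prom)$truncated))
})

test_that("promoters truncate at chromosome edges with a flag", {
  genome <- .mini_genome()
  genes <- geneModels("edge", "chr1", "+", 800L, 1099L,
                      IRanges::IRangesList(IRanges::IRanges(800L, 1099L)))
  prom <- extractPromoters(genome, genes, 1500L)
  expect_equal(nchar(as.character(prom[["edge"]])), 799L)
  expect_true(S4Vectors::mcols(prom)$truncated[1])

  expect_error(extractPromoters(genome,
                                geneModels("x", "chrZ", "+", 5000L, 5899L,
                                           IRanges::IRangesList(IRanges::IRanges(5000L, 5899L))),
                                1500L),
               "chrZ")
})

test_that("IUPAC scanning reports all overlapping matches on the given strand", {
  motifs <- MotifTable(c("Gbox", "CG5", "AA2"),
                       c("CACGTG", "CGTCA", "AA"),
                       c("growth_development", "hormone", "stress"))
  prom <- Biostrings::DNAStringSet(c(
    g1 = paste0(strrep("T", 99), "CACGTG", strrep("T", 95)),
    g2 = paste0(strrep("C", 50), "TGACG", strrep("C", 45))))
  hits <- scanCisElements(prom, motifs, "given_only")
  expect_equal(hits$element, "Gbox")
  expect_equal(hits$offset, 100L)
  # CGTCA is only present as its reverse complement: no given-strand hit
  expect_false(any(hits$gene_id == "g2"))

  both <- scanCisElements(prom, motifs, "both")
  g2 <- both[both$gene_id == "g2" & both$element == "CG5", ]
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$strand, "-")
  expect_equal(g2$offset, 51L)

  # homopolymer: AA matches at every offset 1..L-1
  polyA <- Biostrings::DNAStringSet(c(pa = strrep("A", 30)))
  hits <- scanCisElements(polyA, motifs, "given_only")
  expect_equal(hits$offset[hits$element == "AA2"], 1:29)
})

test_that("ambiguity codes expand and invalid codes error at load", {
  motifs <- MotifTable("WBox", "TTGACY", "stress")
  prom <- Biostrings::DNAStringSet(c(p = "GGTTGACTGGTTGACCGG"))
  hits <- scanCisElements(prom, motifs)
  expect_equal(hits$offset, c(3L, 11L))
  expect_error(MotifTable("bad", "ACGU", "stress"), "IUPAC")
})

test_that("census totals are conserved and categorized", {
  motifs <- defaultMotifTable()
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    element = c("ABRE", "G-box", "ABRE", "MBS", "ABRE"),
    offset = c(10L, 40L, 11L, 70L, 200L),
    strand = "+", stringsAsFactors = FALSE)
  cs <- censusByCategory(hits, motifs)
  expect_equal(unname(cs$perElement[["ABRE"]]), 3)
  expect_equal(unname(cs$perCategory[["hormone"]]), 3)
  expect_equal(unname(cs$perCategory[["stress"]]), 1)
  expect_equal(sum(cs$perCategory), nrow(hits))
  expect_equal(sum(cs$perGene), nrow(hits))
  expect_error(censusByCategory(transform(hits, element = "mystery"), motifs),
               "unknown element")
  empty <- censusByCategory(hits[0, ], motifs)
  expect_equal(sum(empty$perCategory), 0)
})

test_that("reverse-complementing a promoter preserves both-strand totals", {
  motifs <- defaultMotifTable()
  set.seed(59)
  p <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  fw <- Biostrings::DNAStringSet(c(x = p))
  rc <- Biostrings::DNAStringSet(c(x = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(p)))))
  expect_equal(nrow(scanCisElements(fw, motifs, "both")),
               nrow(scanCisElements(rc, motifs, "both")))
})

test_that("planted elements are recovered exactly at their offsets", {
  motifs <- defaultMotifTable()
  for (seed in 1:3) {
    sim <- generateFamilyGenome(familySpec(nBackground = 2L), seed = seed)
    ids <- S4Vectors::mcols(sim$genes)$gene_id[1:4]
    plan <- data.frame(gene_id = rep(ids, each = 2),
                       element = rep(c("ABRE", "G-box"), 4),
                       offset = rep(c(100L, 400L), 4),
                       strand = "+", stringsAsFactors = FALSE)
    planted <- plantPromoterElements(sim$genome, sim$genes, motifs, plan,
                                     seed = seed + 1000L)
    prom <- extractPromoters(planted$genome, sim$genes[ids], 1500L)
    hits <- scanCisElements(prom, motifs, "given_only")
    expect_equal(nrow(hits), nrow(plan), info = paste("seed", seed))
    key_h <- sort(paste(hits$gene_id, hits$element, hits$offset))
    key_p <- sort(paste(plan$gene_id, plan$element, plan$offset))
    expect_equal(key_h, key_p, info = paste("seed", seed))
    cs <- censusByCategory(hits, motifs)
    expect_equal(sum(cs$perCategory), nrow(hits))
  }
})

test_that("planting validates offsets and overlap", {
  sim <- generateFamilyGenome(familySpec(nBackground = 0L), seed = 4)
  motifs <- defaultMotifTable()
  id <- S4Vectors::mcols(sim$genes)$gene_id[1]
  bad <- data.frame(gene_id = id, element = "ABRE", offset = 1496L,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(plantPromoterElements(sim$genome, sim$genes, motifs, bad),
               "outside the promoter window")
  overlap <- data.frame(gene_id = id, element = c("ABRE", "G-box"),
                        offset = c(100L, 104L), strand = "+",
                        stringsAsFactors = FALSE)
  expect_error(plantPromoterElements(sim$genome, sim$genes, motifs, overlap),
               "overlap")
  expect_error(plantPromoterElements(sim$genome, sim$genes, motifs,
                                     transform(bad, element = "nope",
                                               offset = 10L)),
               "unknown element")
})
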