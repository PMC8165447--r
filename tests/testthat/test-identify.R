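test_that("Smith-Waterman matches self-alignment and floors at zero", {
  m <- blosum62()
  s <- "MKVLAWHEDE"
  aln <- smithWaterman(s, s)
  expect_equal(aln$score, sum(diag(m[strsplit(s, "")[[1]],
                                     strsplit(s, "")[[1]]])))
  expect_equal(aln$query_start, 1L)
  expect_equal(aln$query_end, nchar(s))

  neg <- matrix(-1, 2, 2, dimnames = list(c("A", "T"), c("A", "T")))
  aln <- smithWaterman("AAA", "TTTT", substitutionMatrix = neg)
  expect_equal(aln$score, 0)
  expect_equal(aln$query_aln, "")
  expect_true(is.na(aln$query_start))
})

test_that("Smith-Waterman agrees with a quadratic-space reference on random pairs", {
  m <- blosum62()
  set.seed(11)
  for (i in 1:100) {
    a <- random_aa(30); b <- random_aa(30)
    expect_equal(smithWaterman(a, b)$score, oracle_sw_score(a, b, m, 10, 1),
                 info = paste("pair", i))
  }
})

test_that("local alignment score is symmetric for symmetric matrices", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_aa(25); b <- random_aa(40)
    expect_equal(smithWaterman(a, b)$score, smithWaterman(b, a)$score)
  }
})

test_that("unknown residues are reported with position", {
  expect_error(smithWaterman("MKB2", "MKV"), "unknown residue '2' at position 4")
})

test_that("E-value is strictly decreasing in score and the exact domain is accepted", {
  e1 <- karlinAltschulE(100, 58, 1e4, 0.267, 0.041)
  e2 <- karlinAltschulE(101, 58, 1e4, 0.267, 0.041)
  expect_lt(e2, e1)

  dom <- defaultDomainRefs()$class2
  cfg <- ScanConfig(dom)
  set.seed(5)
  prots <- Biostrings::AAStringSet(c(
    hit = paste0(random_aa(50), dom, random_aa(60)),
    miss = random_aa(170)))
  res <- scanForDomain(prots, cfg)
  expect_equal(res$protein_id, "hit")
  expect_lt(res$e_value, 1e-10)
  expect_equal(res$hit_start, 51L)
  expect_equal(res$hit_end, 50L + nchar(dom))
})

test_that("domain scan rejects random background proteins", {
  cfg <- ScanConfig(defaultDomainRefs()$class2)
  set.seed(21)
  prots <- Biostrings::AAStringSet(setNames(
    vapply(1:100, function(i) random_aa(sample(80:250, 1)), ""),
    sprintf("r%03d", 1:100)))
  res <- scanForDomain(prots, cfg)
  expect_lte(nrow(res), 1)   # >= 99/100 rejected
})

test_that("empty protein set scans to an empty result", {
  res <- scanForDomain(Biostrings::AAStringSet(), ScanConfig("GKDRH"))
  expect_equal(nrow(res), 0)
})

test_that("planted subfamily labels are recovered", {
  refs <- defaultDomainRefs()
  cfg <- ScanConfig(refs$class2)
  agree <- 0L; total <- 0L
  for (seed in 1:10) {
    sim <- generateFamilyGenome(familySpec(nBackground = 2L), seed = seed)
    tm <- truthMembers(sim$truth)
    hits <- scanForDomain(sim$proteins, cfg)
    for (i in seq_len(nrow(hits))) {
      id <- hits$protein_id[i]
      truth <- tm$subfamily[tm$gene_id == id]
      if (is.na(truth)) next
      cl <- classifySubfamily(hits[i, ], sim$proteins[[id]],
                              refs$class1, refs$class2)
      total <- total + 1L
      if (subfamilyLabel(cl) == truth) agree <- agree + 1L
    }
  }
  expect_gte(total, 90L)
  expect_gte(agree / total, 0.95)
})

test_that("subfamily calls carry the diagnostic evidence", {
  refs <- defaultDomainRefs()
  cfg <- ScanConfig(refs$class2)
  sim <- generateFamilyGenome(familySpec(nBackground = 0L), seed = 42)
  tm <- truthMembers(sim$truth)
  hits <- scanForDomain(sim$proteins, cfg)
  for (i in seq_len(nrow(hits))) {
    id <- hits$protein_id[i]
    cl <- classifySubfamily(hits[i, ], sim$proteins[[id]],
                            refs$class1, refs$class2)
    truth <- tm$subfamily[tm$gene_id == id]
    if (truth == "PCF") expect_true(cl@basicRegionGap)
    if (truth == "CYC") expect_true(cl@rDomainFound)
  }
})

test_that("classification refuses domains shorter than 20 aa", {
  refs <- defaultDomainRefs()
  hit <- data.frame(protein_id = "p", hit_start = 1L, hit_end = 10L)
  expect_error(classifySubfamily(hit, "MKVLAWHEDEAA", refs$class1, refs$class2),
               "shorter than 20")
})

test_that("GRAVY, molecular weight and pI follow the configured tables", {
  p <- physicochemicalProfile("AAA")
  expect_equal(p$gravy, 1.8)
  expect_equal(p$length_aa, 3L)
  expect_equal(p$mw_kDa, (3 * 71.0788 + 18.01524) / 1000)

  # dipeptide with no ionizable side chains: pI = mean of the two termini pKa
  pka <- defaultPKa()
  pka[["Nterm"]] <- 9.6; pka[["Cterm"]] <- 2.34
  p <- physicochemicalProfile("GG", pKa = pka)
  expect_equal(p$pI, (9.6 + 2.34) / 2, tolerance = 0.01)
})

test_that("GRAVY is reversal-invariant and MW additive over concatenation", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_aa(30)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(physicochemicalProfile(s)$gravy,
                 physicochemicalProfile(r)$gravy)
    t2 <- random_aa(20)
    expect_equal(physicochemicalProfile(paste0(s, t2))$mw_kDa,
                 physicochemicalProfile(s)$mw_kDa +
                   physicochemicalProfile(t2)$mw_kDa - 18.01524 / 1000)
  }
})

test_that("net charge is strictly decreasing in pH", {
  set.seed(13)
  grid <- seq(0.5, 13.5, by = 0.5)
  for (i in 1:25) {
    q <- netCharge(random_aa(sample(10:60, 1)), grid)
    expect_true(all(diff(q) < 0))
  }
})

test_that("profiles reject nonstandard or empty input", {
  expect_error(physicochemicalProfile("AXA"), "nonstandard residue 'X'")
  expect_error(physicochemicalProfile(""), "empty")
})
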