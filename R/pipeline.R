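# End-to-end orchestration: identify -> classify -> align/tree ->
# duplications/KaKs/windows -> promoters -> expression, with a run manifest.
# The R functions are the interface; runPipeline() composes them over either
# a simulated study or files on disk.

#' Build a pipeline run configuration
#'
#' Either `simulate` (a [familySpec()]) or the four input paths must be
#' given. All stage parameters carry the package defaults.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer seed for every stochastic step.
#' @param simulate a [familySpec()] to generate the study inputs, or `NULL`
#'   to read them from disk.
#' @param genomeFasta,gff3,proteinsFasta,cdsFasta input paths (ignored when
#'   `simulate` is given).
#' @param ctTsv optional Ct table TSV (columns sample, gene, replicate, ct);
#'   when `simulate` is given and `ctTsv` is NULL, a default four-sample Ct
#'   design over the first three family genes is simulated.
#' @param referenceGene,calibratorSample Ct analysis anchors.
#' @param motifs a [MotifTable-class] (default [defaultMotifTable()]).
#' @param domainRef domain reference for the scan (default the simulator's
#'   Class II reference).
#' @param eThreshold,promoterLength,windowNt,stepNt,identityThresholdPct,tandemMaxSeparationBp
#'   stage parameters, see the stage functions.
#' @return A validated list of class `runConfig`.
#' @export
runConfig <- function(outdir, seed = 1L, simulate = familySpec(),
                      genomeFasta = NULL, gff3 = NULL, proteinsFasta = NULL,
                      cdsFasta = NULL, ctTsv = NULL,
                      referenceGene = "TUBULIN", calibratorSample = "S1",
                      motifs = defaultMotifTable(),
                      domainRef = defaultDomainRefs()$class2,
                      eThreshold = 0.001, promoterLength = 1500L,
                      windowNt = 150L, stepNt = 9L,
                      identityThresholdPct = 80,
                      tandemMaxSeparationBp = 200000L) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              genomeFasta = genomeFasta, gff3 = gff3,
              proteinsFasta = proteinsFasta, cdsFasta = cdsFasta,
              ctTsv = ctTsv, referenceGene = referenceGene,
              calibratorSample = calibratorSample, motifs = motifs,
              domainRef = domainRef, eThreshold = eThreshold,
              promoterLength = as.integer(promoterLength),
              windowNt = as.integer(windowNt), stepNt = as.integer(stepNt),
              identityThresholdPct = identityThresholdPct,
              tandemMaxSeparationBp = as.integer(tandemMaxSeparationBp))
  class(cfg) <- "runConfig"
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration before any stage runs
#'
#' @param cfg a `runConfig` list.
#' @return `cfg` invisibly; errors on missing files or out-of-range
#'   parameters.
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$simulate)) {
    paths <- c(genome = cfg$genomeFasta, gff3 = cfg$gff3,
               proteins = cfg$proteinsFasta, cds = cfg$cdsFasta)
    if (any(vapply(paths, is.null, logical(1L))))
      stop("validation error: without 'simulate', all four input paths are required")
    miss <- paths[!file.exists(unlist(paths))]
    if (length(miss))
      stop("validation error: missing input file(s): ",
           paste(unlist(miss), collapse = ", "))
  }
  if (!is.null(cfg$ctTsv) && !file.exists(cfg$ctTsv))
    stop("validation error: missing Ct table: ", cfg$ctTsv)
  if (cfg$eThreshold <= 0) stop("validation error: eThreshold must be > 0")
  if (cfg$promoterLength < 1L) stop("validation error: promoterLength must be >= 1")
  if (cfg$windowNt %% 3L != 0L || cfg$stepNt %% 3L != 0L ||
      cfg$windowNt <= 0L || cfg$stepNt <= 0L)
    stop("validation error: window and step must be positive multiples of 3")
  if (cfg$identityThresholdPct < 0 || cfg$identityThresholdPct > 100)
    stop("validation error: identityThresholdPct must be in [0, 100]")
  invisible(cfg)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; any stage error aborts with the stage
#' name. Reruns with an identical configuration are byte-identical except for
#' the manifest timestamp.
#'
#' @param cfg a [runConfig()].
#' @return Invisibly, a list with the outputs of every stage plus the
#'   manifest. Files written to `cfg$outdir`: members.tsv, classes.tsv,
#'   tree.nwk, events.tsv, kaks.tsv, windows.tsv, hits.tsv, census.tsv,
#'   folds.tsv, manifest.json (plus truth tables for simulated runs).
#' @export
runPipeline <- function(cfg) {
  validateRunConfig(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", generateFamilyGenome(cfg$simulate, cfg$seed))
    genome <- sim$genome; genes <- sim$genes
    proteins <- sim$proteins; cds <- sim$cds
    .write_tsv(truthMembers(sim$truth), file.path(cfg$outdir, "truth_members.tsv"))
    .write_tsv(truthDuplicates(sim$truth), file.path(cfg$outdir, "truth_duplicates.tsv"))
  } else {
    genome <- stage("load", readFasta(cfg$genomeFasta, "dna"))
    genes <- stage("load", readGFF3(cfg$gff3))
    proteins <- stage("load", readFasta(cfg$proteinsFasta, "protein"))
    cds <- stage("load", readFasta(cfg$cdsFasta, "dna"))
  }

  # ---- identify --------------------------------------------------------
  scfg <- ScanConfig(cfg$domainRef, eThreshold = cfg$eThreshold)
  hits <- stage("identify", scanForDomain(proteins, scfg))
  refs <- defaultDomainRefs()
  members <- hits
  if (nrow(hits)) {
    cls <- lapply(seq_len(nrow(hits)), function(i)
      stage("classify", classifySubfamily(hits[i, ],
                                          proteins[[hits$protein_id[i]]],
                                          refs$class1, refs$class2)))
    prof <- lapply(hits$protein_id, function(id)
      stage("physchem", physicochemicalProfile(proteins[[id]])))
    members$class <- vapply(cls, subfamilyLabel, character(1L))
    members$MW_kDa <- vapply(prof, `[[`, numeric(1L), "mw_kDa")
    members$pI <- vapply(prof, `[[`, numeric(1L), "pI")
    members$GRAVY <- vapply(prof, `[[`, numeric(1L), "gravy")
    classes <- data.frame(
      protein_id = hits$protein_id,
      class = members$class,
      basic_region_gap = vapply(cls, function(x) x@basicRegionGap, logical(1L)),
      r_domain_found = vapply(cls, function(x) x@rDomainFound, logical(1L)),
      stringsAsFactors = FALSE)
  } else {
    classes <- data.frame(protein_id = character(), class = character(),
                          basic_region_gap = logical(),
                          r_domain_found = logical(), stringsAsFactors = FALSE)
  }
  counts$members <- .write_tsv(members, file.path(cfg$outdir, "members.tsv"))
  counts$classes <- .write_tsv(classes, file.path(cfg$outdir, "classes.tsv"))
  member_ids <- hits$protein_id
  if (length(member_ids) < 2L)
    stop("pipeline stage 'phylo' failed: fewer than 2 family members found")

  # ---- phylo -----------------------------------------------------------
  member_prot <- proteins[member_ids]
  aln <- stage("phylo", progressiveMSA(member_prot))
  dm <- stage("phylo", proteinDistanceMatrix(aln, "p_distance"))
  tree <- stage("phylo", buildNJTree(dm))
  writeNewick(tree, file.path(cfg$outdir, "tree.nwk"))
  counts$tree_leaves <- length(tree$tip.label)

  # ---- selection -------------------------------------------------------
  events <- stage("selection", classifyDuplications(
    genes, proteins, cds, tree,
    identityThresholdPct = cfg$identityThresholdPct,
    tandemMaxSeparationBp = cfg$tandemMaxSeparationBp))
  counts$events <- .write_tsv(events, file.path(cfg$outdir, "events.tsv"))
  kaks_cols <- c("gene_a", "gene_b", "S", "N", "Sd", "Nd", "Ka", "Ks",
                 "ratio", "call", "dup_type")
  .write_tsv(events[, kaks_cols], file.path(cfg$outdir, "kaks.tsv"))
  windows <- list()
  for (k in seq_len(nrow(events))) {
    ga <- events$gene_a[k]; gb <- events$gene_b[k]
    pa <- globalAlign(proteins[[ga]], proteins[[gb]])
    caln <- mapProteinAlignmentToCodons(pa$a_aln, pa$b_aln,
                                        cds[[ga]], cds[[gb]], c(ga, gb))
    if (alignmentLength(caln) < cfg$windowNt) next
    w <- stage("selection", slidingWindowKaks(caln, cfg$windowNt, cfg$stepNt))
    w <- cbind(gene_a = ga, gene_b = gb, w)
    windows[[length(windows) + 1L]] <- w
  }
  wdf <- if (length(windows)) do.call(rbind, windows) else
    data.frame(gene_a = character(), gene_b = character(), start_nt = integer(),
               end_nt = integer(), S = numeric(), N = numeric(), Sd = numeric(),
               Nd = numeric(), Ka = numeric(), Ks = numeric(), ratio = numeric(),
               call = character(), stringsAsFactors = FALSE)
  counts$windows <- .write_tsv(wdf, file.path(cfg$outdir, "windows.tsv"))

  # ---- promoter --------------------------------------------------------
  fam_genes <- genes[mcols(genes)$gene_id %in% member_ids]
  prom <- stage("promoter", extractPromoters(genome, fam_genes,
                                             cfg$promoterLength))
  chits <- stage("promoter", scanCisElements(prom, cfg$motifs, "given_only"))
  census <- stage("promoter", censusByCategory(chits, cfg$motifs))
  counts$cis_hits <- .write_tsv(chits, file.path(cfg$outdir, "hits.tsv"))
  tb <- motifTable(cfg$motifs)
  census_df <- data.frame(element = tb$element, category = tb$category,
                          total = as.integer(census$perElement[tb$element]),
                          stringsAsFactors = FALSE)
  counts$census <- .write_tsv(census_df, file.path(cfg$outdir, "census.tsv"))

  # ---- expression ------------------------------------------------------
  folds <- NULL
  if (!is.null(cfg$ctTsv)) {
    ctd <- stage("expression", read.delim(cfg$ctTsv))
    tblct <- stage("expression",
                   CtTable(ctd, cfg$referenceGene, cfg$calibratorSample))
    folds <- stage("expression", relativeExpressionDDCt(tblct))
  } else if (!is.null(cfg$simulate) && length(member_ids) >= 1L) {
    tgt <- utils::head(member_ids, 3L)
    design <- expand.grid(sample = c("S1", "S2", "S3", "S4"), gene = tgt,
                          stringsAsFactors = FALSE)
    set.seed(cfg$seed)
    design$true_fold <- ifelse(design$sample == "S1", 1,
                               2^sample(-2:3, nrow(design), replace = TRUE))
    g <- generateCtTable(design, cfg$referenceGene, "S1",
                         noiseSd = 0.2, replicates = 3L, seed = cfg$seed)
    .write_tsv(g$truth, file.path(cfg$outdir, "truth_expression.tsv"))
    folds <- stage("expression", relativeExpressionDDCt(g$ct))
  }
  if (!is.null(folds))
    counts$folds <- .write_tsv(folds, file.path(cfg$outdir, "folds.tsv"))

  # ---- manifest --------------------------------------------------------
  cfg_norm <- cfg
  cfg_norm$motifs <- motifTable(cfg$motifs)
  cfg_norm$outdir <- NULL
  cfg_json <- file.path(cfg$outdir, "config.json")
  jsonlite::write_json(cfg_norm, cfg_json, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(packageVersion("famscan")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(members = members, classes = classes, tree = tree,
                 events = events, windows = wdf, cis_hits = chits,
                 census = census_df, folds = folds, manifest = manifest))
}
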