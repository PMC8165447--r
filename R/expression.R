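# Livak 2^-ddCt relative expression, gibberellin time-course response
# classification, and the log2 heatmap transform.

#' Relative expression by the Livak 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference), replicates paired by
#' index (set `pairing = "mean"` for the unpaired mean-vs-mean variant). Per
#' sample the mean and sd of dCt are taken; ddCt = mean dCt(sample) - mean
#' dCt(calibrator); fold = 2^-ddCt. Dispersion is propagated on the dCt
#' scale and then exponentiated: fold_range = 2^-(ddCt +/- sd).
#'
#' @param tbl a [CtTable-class].
#' @param pairing `"by_index"` (default) or `"mean"`.
#' @return data.frame: `sample`, `gene`, `fold`, `delta_ct_mean`,
#'   `delta_ct_sd`, `fold_low`, `fold_high` for every non-reference gene in
#'   every sample (the reference gene itself, when requested via
#'   `includeReference`, gives fold 1 everywhere).
#' @param includeReference also report the reference gene as a target
#'   (default FALSE).
#' @export
relativeExpressionDDCt <- function(tbl, pairing = c("by_index", "mean"),
                                   includeReference = FALSE) {
  stopifnot(is(tbl, "CtTable"))
  pairing <- match.arg(pairing)
  d <- ctData(tbl)
  ref <- referenceGene(tbl)
  cal <- calibratorSample(tbl)
  genes <- setdiff(unique(d$gene), ref)
  if (includeReference) genes <- c(genes, ref)
  samples <- unique(d$sample)
  dct <- .delta_ct_replicates(d, ref, pairing)
  out <- list()
  for (g in genes) {
    key_cal <- paste(cal, g, sep = "\r")
    if (is.null(dct[[key_cal]]))
      stop("gene '", g, "' missing in calibrator sample '", cal, "'")
    cal_mean <- mean(dct[[key_cal]])
    for (s in samples) {
      v <- dct[[paste(s, g, sep = "\r")]]
      if (is.null(v)) next
      m <- mean(v); sdv <- sd(v)
      ddct <- m - cal_mean
      out[[length(out) + 1L]] <- data.frame(
        sample = s, gene = g, fold = 2^(-ddct), delta_ct_mean = m,
        delta_ct_sd = sdv, fold_low = 2^(-(ddct + sdv)),
        fold_high = 2^(-(ddct - sdv)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# replicate-level dCt values keyed by "sample\rgene"
.delta_ct_replicates <- function(d, ref, pairing) {
  out <- new.env(parent = emptyenv())
  res <- list()
  for (s in unique(d$sample)) {
    ds <- d[d$sample == s, , drop = FALSE]
    refrows <- ds[ds$gene == ref, , drop = FALSE]
    if (nrow(refrows) == 0L)
      stop("missing reference gene Ct in sample '", s, "'")
    refct <- setNames(refrows$ct, refrows$replicate)
    for (g in unique(ds$gene)) {
      rows <- ds[ds$gene == g, , drop = FALSE]
      if (nrow(rows) < 2L)
        stop("fewer than 2 replicates for gene '", g, "' in sample '", s, "'")
      if (pairing == "by_index") {
        idx <- as.character(rows$replicate)
        if (!all(idx %in% names(refct)))
          stop("replicate indices of gene '", g,
               "' unmatched in reference for sample '", s, "'")
        v <- rows$ct - refct[idx]
      } else {
        v <- rows$ct - mean(refrows$ct)
      }
      res[[paste(s, g, sep = "\r")]] <- as.numeric(v)
    }
  }
  res
}

#' Classify a gibberellin time-course response
#'
#' A gene is responsive when at some post-treatment time point the two-sided
#' Welch t-test on replicate dCt values against the 0-hour calibrator gives
#' p < `alpha` and the fold change passes `foldCut` (>= foldCut or
#' <= 1/foldCut). The first such time point is reported.
#'
#' @param tbl a [CtTable-class] whose samples are time points of one
#'   treatment course; the calibrator sample must map to time 0.
#' @param gene the target gene to classify.
#' @param times named numeric vector mapping sample ids to hours
#'   post-treatment.
#' @param alpha significance level (default 0.05).
#' @param foldCut fold-change cutoff (default 2).
#' @return A list: `status` (`"responsive"` / `"non_responsive"`),
#'   `first_time` (hours, `NA` when non-responsive), and a per-time-point
#'   data.frame `detail` with fold and p-value.
#' @export
gaResponseClassify <- function(tbl, gene, times, alpha = 0.05, foldCut = 2) {
  stopifnot(is(tbl, "CtTable"))
  d <- ctData(tbl)
  if (!all(unique(d$sample) %in% names(times)))
    stop("every sample needs an entry in 'times'")
  t0 <- names(times)[times == 0]
  if (length(t0) != 1L) stop("exactly one sample must map to time 0")
  if (t0 != calibratorSample(tbl))
    stop("the calibrator sample must be the 0-hour time point")
  dct <- .delta_ct_replicates(d, referenceGene(tbl), "by_index")
  v0 <- dct[[paste(t0, gene, sep = "\r")]]
  if (is.null(v0)) stop("gene '", gene, "' missing at the 0-hour time point")
  later <- names(times)[order(times)]
  later <- later[times[later] > 0]
  detail <- list()
  first_time <- NA_real_
  for (s in later) {
    v <- dct[[paste(s, gene, sep = "\r")]]
    if (is.null(v)) next
    fold <- 2^(-(mean(v) - mean(v0)))
    p <- tryCatch(t.test(v, v0)$p.value, error = function(e) NA_real_)
    hit <- !is.na(p) && p < alpha && (fold >= foldCut || fold <= 1 / foldCut)
    detail[[length(detail) + 1L]] <- data.frame(
      time = times[[s]], sample = s, fold = fold, p_value = p,
      responsive = hit, stringsAsFactors = FALSE)
    if (hit && is.na(first_time)) first_time <- times[[s]]
  }
  list(status = if (!is.na(first_time)) "responsive" else "non_responsive",
       first_time = first_time,
       detail = do.call(rbind, detail))
}

#' Log2 heatmap matrix
#'
#' Elementwise `log2(value + pseudocount)`; zero maps to 0 under the default
#' pseudocount of 1, and cell ordering is preserved (the transform is
#' monotone).
#'
#' @param expr non-negative numeric matrix (genes x tissues).
#' @param pseudocount added before the log (default 1).
#' @return Transformed matrix, dimnames and order preserved.
#' @export
tissueHeatmapMatrix <- function(expr, pseudocount = 1) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("negative expression value")
  log2(expr + pseudocount)
}
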