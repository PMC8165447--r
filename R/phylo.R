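# Progressive multiple alignment (UPGMA guide tree on 3-mer count distances,
# profile-profile Needleman-Wunsch merges) and Saitou-Nei neighbor joining.

#' Progressive multiple sequence alignment
#'
#' Guide tree by UPGMA on Euclidean distances between 3-mer count vectors;
#' profiles merged leaf-upward by profile-profile global alignment under
#' sum-of-pairs scoring (column score = f_A' M f_B over residue frequencies,
#' gaps contributing zero). Deterministic: ties resolve by input order.
#'
#' @param seqs an `AAStringSet` (>= 1 sequence).
#' @param substitutionMatrix residue score matrix (default BLOSUM62).
#' @param gapOpen,gapExtend affine gap penalties.
#' @return An `AAStringSet` of equal-length gapped rows, input order and names
#'   preserved; de-gapping row i recovers input i.
#' @export
progressiveMSA <- function(seqs, substitutionMatrix = blosum62(),
                           gapOpen = 10, gapExtend = 1) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences")
  chars <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1L]])
  if (n == 1L) return(AAStringSet(setNames(as.character(seqs), names(seqs))))
  # guide tree
  km <- .kmer_counts(as.character(seqs), k = 3L)
  hc <- hclust(as.dist(as.matrix(stats::dist(km))), method = "average")
  # alignments as character matrices (rows = sequences), with row ids
  res_letters <- rownames(substitutionMatrix)
  alns <- lapply(seq_len(n), function(i)
    matrix(chars[[i]], nrow = 1L, dimnames = list(names(seqs)[i], NULL)))
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(idx) if (idx < 0L) alns[[-idx]] else merged[[idx]]
    A <- pick(hc$merge[step, 1L])
    B <- pick(hc$merge[step, 2L])
    merged[[step]] <- .merge_profiles(A, B, substitutionMatrix,
                                      gapOpen, gapExtend, res_letters)
  }
  final <- merged[[n - 1L]]
  final <- final[match(names(seqs), rownames(final)), , drop = FALSE]
  AAStringSet(setNames(apply(final, 1L, paste, collapse = ""), names(seqs)))
}

.kmer_counts <- function(seqs, k = 3L) {
  kmers <- unique(unlist(lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
  })))
  t(vapply(seqs, function(s) {
    if (nchar(s) < k) return(setNames(numeric(length(kmers)), kmers))
    km <- substring(s, seq_len(nchar(s) - k + 1L),
                    seq_len(nchar(s) - k + 1L) + k - 1L)
    tab <- table(factor(km, levels = kmers))
    as.numeric(tab)
  }, numeric(length(kmers))))
}

.profile_freq <- function(A, letters) {
  # residue frequency per column; gaps contribute zero mass
  P <- matrix(0, nrow = length(letters), ncol = ncol(A),
              dimnames = list(letters, NULL))
  for (i in seq_len(nrow(A))) {
    idx <- match(A[i, ], letters)
    ok <- !is.na(idx)
    P[cbind(idx[ok], which(ok))] <- P[cbind(idx[ok], which(ok))] + 1
  }
  P / nrow(A)
}

.merge_profiles <- function(A, B, mat, gapOpen, gapExtend, letters) {
  PA <- .profile_freq(A, letters)
  PB <- .profile_freq(B, letters)
  S <- t(PA) %*% mat[letters, letters] %*% PB
  res <- .dp_align_cpp(S, gapOpen, gapExtend, FALSE)
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = length(res$a),
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  acols <- which(res$a > 0L); bcols <- which(res$b > 0L)
  out[seq_len(nrow(A)), acols] <- A[, res$a[acols], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), bcols] <- B[, res$b[bcols], drop = FALSE]
  out
}

#' Pairwise distance matrix from a protein alignment
#'
#' Pairwise deletion: for each pair, p = mismatches / columns where both rows
#' are non-gap. `p_distance` returns p itself; `poisson` returns
#' `-ln(1 - p)`.
#'
#' @param aln an `AAStringSet` of equal-length gapped rows (>= 2).
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal and sequence names
#'   as dimnames.
#' @export
proteinDistanceMatrix <- function(aln, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  n <- length(aln)
  if (n < 2L) stop("need >= 2 rows")
  rows <- strsplit(as.character(aln), "")
  if (length(unique(lengths(rows))) != 1L) stop("rows differ in length")
  ids <- names(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- rows[[i]] != "-" & rows[[j]] != "-"
      nc <- sum(ok)
      if (nc == 0L)
        stop(sprintf("no comparable columns for pair (%s, %s)", ids[i], ids[j]))
      p <- sum(rows[[i]][ok] != rows[[j]][ok]) / nc
      if (model == "poisson") {
        if (p >= 1) stop(sprintf("poisson distance undefined (p = 1) for pair (%s, %s)",
                                 ids[i], ids[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimizing
#' `Q_ij = (r - 2) d_ij - R_i - R_j`, with the standard rate-corrected branch
#' lengths; negative computed lengths are clamped to 0; Q ties break on the
#' smallest (i, j) index pair; the final three nodes join at an unrooted
#' trifurcation. Consistent: additive input distances are reproduced exactly
#' as leaf-to-leaf path lengths.
#'
#' @param dm symmetric non-negative distance matrix with zero diagonal and
#'   unique dimnames (>= 2 taxa).
#' @return An ape `phylo` object.
#' @export
buildNJTree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need >= 2 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must have taxon names")
  if (any(dm < 0)) stop("validation error: negative distances")
  if (max(abs(dm - t(dm))) > 1e-9) stop("validation error: asymmetric matrix")
  if (any(abs(diag(dm)) > 1e-12)) stop("validation error: nonzero diagonal")
  labels <- rownames(dm)
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", labels[1L], fmt(dm[1L, 2L] / 2),
                   labels[2L], fmt(dm[1L, 2L] / 2))
    return(ape::read.tree(text = txt))
  }
  nodes <- labels      # newick fragment per active node
  D <- dm
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    nw <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], nw)
    D <- D2
  }
  la <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  lb <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  lc <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1L], fmt(la),
                 nodes[2L], fmt(lb), nodes[3L], fmt(lc))
  ape::read.tree(text = txt)
}
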