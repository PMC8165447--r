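# Independent oracles, deliberately sharing no code with the package
# internals beyond the standard genetic code table.

.gc <- Biostrings::GENETIC_CODE
.bases <- c("A", "C", "G", "T")
.sense <- names(.gc)[.gc != "*"]

# --- Nei-Gojobori brute force -------------------------------------------

oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (b in .bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (.gc[alt] != "*" && .gc[alt] == .gc[codon]) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

.oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .oracle_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

oracle_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  walk <- function(skip_stops) {
    tot_s <- 0; tot_n <- 0; used <- 0L
    for (ord in .oracle_perms(pos)) {
      cur <- a; s <- 0; n <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (skip_stops && .gc[nxt] == "*" && nxt != b) { ok <- FALSE; break }
        if (.gc[cur] != "*" && .gc[nxt] != "*" && .gc[cur] == .gc[nxt])
          s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; used <- used + 1L }
    }
    list(s = tot_s, n = tot_n, used = used)
  }
  w <- walk(TRUE)
  if (w$used == 0L) w <- walk(FALSE)
  c(sd = w$s / w$used, nd = w$n / w$used)
}

# whole-pair aggregate counts over gapless codon sequences
oracle_pair_counts <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a) - 2, 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b) - 2, 3), seq(3, nchar(seq_b), 3))
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i]); sb <- oracle_sites(cb[i])
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    d <- oracle_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  c(S = S, N = N, Sd = Sd, Nd = Nd)
}

random_sense_cds <- function(n_codons) {
  paste(sample(.sense, n_codons, replace = TRUE), collapse = "")
}

# --- simple quadratic-space affine Smith-Waterman score (no traceback) ---

oracle_sw_score <- function(a, b, mat, go, ge) {
  ac <- strsplit(a, "")[[1L]]; bc <- strsplit(b, "")[[1L]]
  n <- length(ac); m <- length(bc); g1 <- go + ge
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - g1, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - g1, Y[i, j - 1] - ge)
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        mat[ac[i - 1], bc[j - 1]]
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- random additive trees ----------------------------------------------

random_additive_case <- function(n_leaves, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_leaves, rooted = FALSE)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.1, 2)
  list(tree = phy, dist = ape::cophenetic.phylo(phy))
}

random_aa <- function(n) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
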