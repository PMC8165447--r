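# Trees travel as ape "phylo" objects; serialization fixes branch lengths at
# 6 decimals so runs are byte-reproducible.

#' Serialize a phylogenetic tree to a Newick string
#'
#' @param phy an ape `phylo` object; every tip must be labeled and branch
#'   lengths, when present, are written with 6 decimals.
#' @return A single Newick string terminated by `;`.
#' @export
#' @examples
#' phy <- ape::read.tree(text = "(a:1,b:1);")
#' newickString(phy)
newickString <- function(phy) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object")
  if (is.null(phy$tip.label) || any(is.na(phy$tip.label)) ||
      any(phy$tip.label == ""))
    stop("unlabeled leaf in tree")
  n_tip <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  rec <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(phy$tip.label[node])
    parts <- vapply(e, function(k) {
      s <- rec(phy$edge[k, 2L])
      if (!is.null(phy$edge.length))
        s <- paste0(s, ":", sprintf("%.6f", phy$edge.length[k]))
      s
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(n_tip + 1L), ";")
}

#' Write a tree to a Newick file
#'
#' @param phy an ape `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(phy, path) {
  writeLines(newickString(phy), path)
  invisible(path)
}

#' Read a Newick file
#'
#' @param path path to a Newick file.
#' @return An ape `phylo` object.
#' @export
readNewick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("Newick format error in ", path)
  phy
}
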