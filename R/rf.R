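# Robinson-Foulds distances via canonical bipartition sets. Each
# non-trivial split (internal edge) is stored as the sorted leaf
# subset on the side NOT containing the alphabetically first leaf, so
# splits compare across trees and rootings. Multifurcating trees
# simply contribute fewer splits.

#' Non-trivial bipartitions of a tree
#'
#' @param tree A \code{phylo} with >= 4 leaves.
#' @return Character vector of canonical splits, each the
#'   comma-separated sorted leaf set on the side away from the
#'   reference (first alphabetical) leaf. A fully resolved unrooted
#'   tree over n leaves has n - 3 splits.
#' @export
bipartitions <- function(tree) {
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) stop("bipartitions require at least 4 leaves")
  if (ntip >= 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- stats::reorder(tree, "postorder")
  labs <- tree$tip.label
  ref <- labs[order(labs)][1L]
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  root <- ntip + 1L
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    c <- tree$edge[e, 2L]
    if (c <= ntip || c == root) next        # trivial or root-side edge
    side <- below[[c]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (ref %in% side) side <- setdiff(labs, side)
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets. Trees must share the same leaf set; either may be
#' multifurcating.
#'
#' @param t1,t2 \code{phylo} objects over identical leaf sets.
#' @return Non-negative integer.
#' @examples
#' a <- read_newick("((A,B),(C,D),E);")
#' b <- read_newick("((A,C),(B,D),E);")
#' rf_distance(a, b)
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop(sprintf("trees have different leaf sets; differing labels: %s",
                 paste(d, collapse = ", ")))
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Pairwise Robinson-Foulds matrix
#'
#' @param trees Named list of \code{phylo} objects over the same leaf
#'   set.
#' @return Symmetric integer matrix of pairwise RF distances with a
#'   zero diagonal.
#' @export
rf_matrix <- function(trees) {
  n <- length(trees)
  if (is.null(names(trees))) names(trees) <- paste0("T", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(names(trees), names(trees)))
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- rf_distance(trees[[i]], trees[[j]])
  m
}

#' Format an RF matrix as a lower-triangle table
#'
#' @param m Matrix from \code{\link{rf_matrix}}.
#' @return Character vector of tab-separated lines (printed table
#'   style: "=" on the diagonal, blank above).
#' @export
format_rf_table <- function(m) {
  n <- nrow(m)
  lines <- paste(c("Tree", rownames(m)), collapse = "\t")
  for (i in seq_len(n)) {
    cells <- character(n)
    for (j in seq_len(n))
      cells[j] <- if (j < i) as.character(m[i, j]) else if (j == i) "=" else ""
    lines <- c(lines, paste(c(rownames(m)[i], cells), collapse = "\t"))
  }
  lines
}
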