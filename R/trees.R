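# Tree input/output. Trees are ape "phylo" objects, handled unrooted;
# a rooted input has its basal bifurcation collapsed so that any rooting
# of the same topology yields the same bipartition set.

#' Read a newick tree
#'
#' Parses a newick string or file into an unrooted \code{phylo} object.
#' Rooted inputs are unrooted (the basal bifurcation is collapsed).
#' Edges lacking a branch length receive \code{default_length} with a
#' warning, so cladogram inputs can be used directly as candidate
#' topologies (their branch lengths are re-optimized downstream anyway).
#'
#' @param x Newick string (must end in \code{";"}) or path to a file
#'   containing one tree.
#' @param name Optional tree label (e.g. \code{"T1"}), stored as the
#'   \code{"name"} attribute.
#' @param default_length Branch length substituted for missing lengths.
#' @return An unrooted \code{phylo}.
#' @export
read_newick <- function(x, name = NULL, default_length = 0.1) {
  txt <- if (length(x) == 1L && !grepl(";", x, fixed = TRUE) && file.exists(x))
    paste(readLines(x), collapse = "") else x
  if (!grepl(";", txt, fixed = TRUE)) stop("newick string must end with ';'")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop(sprintf("newick parse error: %s",
                                                  conditionMessage(e))))
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("duplicate leaf label: '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1L]))
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label")
  if (ape::Ntip(tr) >= 3L && ape::is.rooted(tr)) tr <- ape::unroot(tr)
  if (is.null(tr$edge.length)) {
    warning(sprintf("tree has no branch lengths; using %g for every edge",
                    default_length))
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning(sprintf("missing branch lengths set to %g", default_length))
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  if (!is.null(name)) attr(tr, "name") <- name
  tr
}

#' Write a tree as newick
#'
#' @param tree A \code{phylo}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read several candidate topologies
#'
#' @param paths Character vector of newick files (or strings).
#' @param names Labels for the trees; defaults to \code{T1, T2, ...}.
#' @return Named list of unrooted \code{phylo} objects with identical
#'   leaf sets.
#' @export
read_candidate_trees <- function(paths, names = NULL) {
  if (is.null(names)) names <- paste0("T", seq_along(paths))
  trees <- Map(read_newick, paths, names)
  names(trees) <- names
  check_same_leaves(trees)
  trees
}

check_same_leaves <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)[-1L]) {
    cur <- sort(trees[[i]]$tip.label)
    if (!identical(ref, cur)) {
      d <- c(setdiff(ref, cur), setdiff(cur, ref))
      stop(sprintf("candidate trees have different leaf sets; differing labels: %s",
                   paste(d, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Read a RAxML-style partition file
#'
#' Lines of the form \code{"MODEL, name = start-end[, start-end]*"}
#' with 1-based inclusive site ranges. A gene may span several ranges;
#' ranges of different genes must not overlap.
#'
#' @param path Partition file path.
#' @return A \code{data.frame} of class \code{"partition_map"} with
#'   columns \code{gene}, \code{start}, \code{end} (one row per range).
#' @export
read_partitions <- function(path) {
  if (!file.exists(path)) stop(sprintf("partition file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i],
                    regexec("^[^,]+,\\s*([^=]+?)\\s*=\\s*(.+)$", lines[i]))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed partition line %d: '%s'", i, lines[i]))
    gene <- m[2L]
    for (rng in strsplit(m[3L], ",")[[1L]]) {
      rng <- trimws(rng)
      se <- regmatches(rng, regexec("^(\\d+)\\s*-\\s*(\\d+)$", rng))[[1L]]
      if (length(se) != 3L)
        stop(sprintf("malformed range '%s' in partition line %d", rng, i))
      start <- as.integer(se[2L]); end <- as.integer(se[3L])
      if (start > end)
        stop(sprintf("partition range start > end (%d-%d) for gene '%s'",
                     start, end, gene))
      rows[[length(rows) + 1L]] <- data.frame(gene = gene, start = start,
                                              end = end)
    }
  }
  if (length(rows) == 0L) stop("empty partition file")
  pm <- do.call(rbind, rows)
  partition_map(pm)
}

#' Construct a partition map
#'
#' @param df Data frame with columns \code{gene}, \code{start},
#'   \code{end} (1-based inclusive ranges).
#' @return The validated \code{"partition_map"}.
#' @export
partition_map <- function(df) {
  stopifnot(all(c("gene", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1L)) stop("partition ranges must start at >= 1")
  if (any(df$start > df$end)) stop("partition range start > end")
  o <- order(df$start)
  so <- df[o, , drop = FALSE]
  bad <- which(so$start[-1L] <= so$end[-nrow(so)])
  if (length(bad))
    stop(sprintf("overlapping partition ranges: genes '%s' and '%s'",
                 so$gene[bad[1L]], so$gene[bad[1L] + 1L]))
  class(df) <- c("partition_map", "data.frame")
  df
}

# gene label per site; NA_character_ where no range covers the site
site_genes <- function(partitions, nsites) {
  g <- rep(NA_character_, nsites)
  for (i in seq_len(nrow(partitions))) {
    to <- min(partitions$end[i], nsites)
    if (partitions$start[i] <= to)
      g[partitions$start[i]:to] <- partitions$gene[i]
  }
  g
}
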