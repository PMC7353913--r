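# Supermatrix diagnostics: occupancy by gene and by site, kept
# fraction relative to reference protein lengths, pairwise taxon
# divergence, and gene-set overlaps across studies.

#' Occupancy of a partitioned supermatrix
#'
#' Coverage by gene is the fraction of taxon-by-gene cells where the
#' taxon has at least one non-missing residue in the gene; coverage by
#' site is the mean fraction of non-missing cells per column,
#' equivalently total non-missing cells over taxa x sites.
#'
#' @param aln An \code{aa_alignment}.
#' @param partitions A \code{"partition_map"} covering the columns to
#'   report.
#' @return List with \code{per_taxon_gene_presence} (logical matrix,
#'   taxa x genes), \code{coverage_by_gene}, \code{coverage_by_site}.
#' @export
coverage_stats <- function(aln, partitions) {
  stopifnot(inherits(aln, "aa_alignment"))
  pres <- present_mask(aln)
  genes <- unique(partitions$gene)
  pg <- matrix(FALSE, length(aln$taxa), length(genes),
               dimnames = list(aln$taxa, genes))
  for (g in genes) {
    cols <- unlist(lapply(which(partitions$gene == g), function(i) {
      if (partitions$end[i] > aln$n_sites)
        stop(sprintf("partition '%s' extends past the alignment (%d > %d)",
                     g, partitions$end[i], aln$n_sites))
      partitions$start[i]:partitions$end[i]
    }))
    if (length(cols) == 0L) stop(sprintf("empty partition '%s'", g))
    pg[, g] <- rowSums(pres[, cols, drop = FALSE]) > 0L
  }
  list(per_taxon_gene_presence = pg,
       coverage_by_gene = mean(pg),
       coverage_by_site = mean(pres))
}

#' Kept fraction relative to reference proteins
#'
#' For each gene, the number of alignment columns where the reference
#' taxon carries a residue, divided by the full length of the
#' reference protein: how much of each protein survived trimming. The
#' total is summed kept columns over summed reference lengths.
#'
#' @param aln An \code{aa_alignment}.
#' @param partitions A \code{"partition_map"}.
#' @param ref_taxon Reference taxon label (e.g. the human sequence).
#' @param ref_lengths Named numeric vector or two-column data frame
#'   (gene, length) of full reference protein lengths.
#' @return List with \code{per_gene} (data frame: gene, kept_columns,
#'   ref_length, kept_fraction, absent flag), \code{total_kept_percent}
#'   and \code{warnings} (genes whose fraction exceeds 1).
#' @export
kept_fraction <- function(aln, partitions, ref_taxon, ref_lengths) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!ref_taxon %in% aln$taxa)
    stop(sprintf("reference taxon '%s' not in alignment", ref_taxon))
  if (is.data.frame(ref_lengths)) {
    rl <- ref_lengths[[2L]]; names(rl) <- ref_lengths[[1L]]
    ref_lengths <- rl
  }
  genes <- unique(partitions$gene)
  miss <- setdiff(genes, names(ref_lengths))
  if (length(miss))
    stop(sprintf("no reference length for gene(s): %s",
                 paste(miss, collapse = ", ")))
  pres <- present_mask(aln)[ref_taxon, ]
  kept <- vapply(genes, function(g) {
    cols <- unlist(lapply(which(partitions$gene == g),
                          function(i) partitions$start[i]:partitions$end[i]))
    sum(pres[cols])
  }, 0L)
  frac <- kept / ref_lengths[genes]
  over <- genes[frac > 1]
  if (length(over))
    warning(sprintf("kept fraction exceeds 1 for gene(s) %s; reference lengths inconsistent with alignment",
                    paste(over, collapse = ", ")))
  list(per_gene = data.frame(gene = genes, kept_columns = kept,
                             ref_length = unname(ref_lengths[genes]),
                             kept_fraction = unname(frac),
                             absent = kept == 0L, row.names = NULL),
       total_kept_percent = 100 * sum(kept) / sum(ref_lengths[genes]),
       warnings = over)
}

#' Percent difference between two taxa
#'
#' @param aln An \code{aa_alignment}.
#' @param a,b Taxon labels.
#' @param mode \code{"all-columns"} counts mismatches over every
#'   column, with residue-vs-missing counted as a difference and
#'   missing-vs-missing as a match; \code{"both-present"} restricts to
#'   columns where both taxa carry residues.
#' @return Percent difference (0-100). Identical labels return 0 with
#'   a message.
#' @export
pairwise_difference <- function(aln, a, b,
                                mode = c("all-columns", "both-present")) {
  mode <- match.arg(mode)
  for (t in c(a, b)) if (!t %in% aln$taxa)
    stop(sprintf("taxon '%s' not in alignment", t))
  if (a == b) {
    message("comparing a taxon with itself; difference is 0")
    return(0)
  }
  ra <- aln$mat[a, ]; rb <- aln$mat[b, ]
  pa <- !is.na(match(ra, aa_states())); pb <- !is.na(match(rb, aa_states()))
  if (mode == "both-present") {
    use <- pa & pb
    if (!any(use)) return(NA_real_)
    return(100 * mean(ra[use] != rb[use]))
  }
  diff <- (pa & pb & ra != rb) | xor(pa, pb)
  100 * mean(diff)
}

#' Overlap regions of named gene sets
#'
#' Counts every exclusive membership region of k named sets (the Venn
#' regions) plus the union.
#'
#' @param sets Named list (>= 2 elements) of vectors of gene
#'   identifiers.
#' @return List with \code{regions} (named counts; region names are
#'   set names joined by \code{"&"}), \code{union} and
#'   \code{common_all} (size of the intersection of all sets).
#' @export
gene_overlap <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  k <- length(sets)
  regions <- integer(0)
  for (mask in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    cnt <- sum(apply(member, 1L, function(r) all(r == inset)))
    regions[paste(names(sets)[inset], collapse = "&")] <- cnt
  }
  list(regions = as.list(regions),
       union = length(all_ids),
       common_all = sum(apply(member, 1L, all)))
}
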