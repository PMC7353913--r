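# Topology-targeted site removal: delete strong sites whose best tree
# lies in a chosen set of topologies, keep strong sites favoring the
# others, and re-evaluate the candidate topologies on the filtered
# ("weak") matrix.

#' Select sites to remove
#'
#' Indices of strong sites whose best tree is in \code{favored_set}.
#' Strong sites favoring other topologies are untouched.
#'
#' @param records A \code{"site_strength_df"}.
#' @param favored_set Character vector of tree labels targeted for
#'   removal.
#' @param threshold Strong-site threshold, inclusive (default: the one
#'   recorded in \code{records}, else 0.5).
#' @return Sorted integer vector of 1-based site indices.
#' @export
select_removals <- function(records, favored_set, threshold = NULL) {
  if (length(favored_set) == 0L) stop("favored_set must be non-empty")
  tn <- attr(records, "tree_names") %||% unique(records$best_tree)
  unknown <- setdiff(favored_set, tn)
  if (length(unknown))
    stop(sprintf("unknown tree label in favored_set: %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(threshold)) threshold <- attr(records, "threshold") %||% 0.5
  strong <- records$dlnl >= threshold & !records$tie
  sort(records$site[strong & records$best_tree %in% favored_set])
}

#' Remove sites from an alignment
#'
#' @param aln An \code{aa_alignment}.
#' @param removed Integer vector of unique, in-range 1-based site
#'   indices (may be empty).
#' @param records Optional \code{"site_strength_df"} used to attribute
#'   removals to their best tree in the report.
#' @param partitions Optional \code{"partition_map"} for per-gene
#'   attribution.
#' @return List with \code{alignment} (the filtered matrix) and
#'   \code{report} (class \code{"filter_report"}).
#' @export
apply_filter <- function(aln, removed, records = NULL, partitions = NULL) {
  stopifnot(inherits(aln, "aa_alignment"))
  removed <- sort(unique(as.integer(removed)))
  if (length(removed) && (min(removed) < 1L || max(removed) > aln$n_sites))
    stop("removed site index out of range")
  if (length(removed) == aln$n_sites)
    stop("refusing to remove every site (empty alignment)")
  kept <- setdiff(seq_len(aln$n_sites), removed)
  out <- if (length(removed)) subset_sites(aln, kept) else aln
  report <- list(n_total = aln$n_sites,
                 n_removed = length(removed),
                 n_kept = length(kept),
                 removed_fraction = length(removed) / aln$n_sites,
                 removed_indices = removed,
                 removed_by_tree = NULL,
                 per_gene_removed = NULL)
  if (!is.null(records) && length(removed)) {
    bt <- records$best_tree[match(removed, records$site)]
    report$removed_by_tree <- as.list(table(bt))
  }
  if (!is.null(partitions))
    report$per_gene_removed <- attribute_to_genes(removed, partitions,
                                                  aln$n_sites)
  class(report) <- "filter_report"
  list(alignment = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: removed %d of %d sites (%.2f%%), kept %d\n",
              x$n_removed, x$n_total, 100 * x$removed_fraction, x$n_kept))
  if (!is.null(x$removed_by_tree))
    cat("  removed by favored tree:",
        paste(sprintf("%s=%d", names(x$removed_by_tree),
                      unlist(x$removed_by_tree)), collapse = ", "), "\n")
  invisible(x)
}

#' Attribute removed sites to genes
#'
#' @param removed Integer vector of 1-based removed site indices.
#' @param partitions A \code{"partition_map"}.
#' @param n_sites Total site count (used to validate ranges); optional.
#' @return Named list of counts per gene; sites outside every range
#'   are counted under \code{"unpartitioned"}.
#' @export
attribute_to_genes <- function(removed, partitions, n_sites = NULL) {
  if (is.null(n_sites)) n_sites <- max(c(removed, partitions$end))
  g <- site_genes(partitions, n_sites)[removed]
  g[is.na(g)] <- "unpartitioned"
  as.list(table(g))
}

#' Save a filter report
#'
#' Writes the report both as human-readable text and as JSON.
#'
#' @param report A \code{"filter_report"}.
#' @param path Output path; the JSON twin gets extension
#'   \code{".json"}.
#' @return Invisibly, \code{path}.
#' @export
write_filter_report <- function(report, path) {
  txt <- c(sprintf("n_total\t%d", report$n_total),
           sprintf("n_removed\t%d", report$n_removed),
           sprintf("n_kept\t%d", report$n_kept),
           sprintf("removed_fraction\t%.6f", report$removed_fraction),
           sprintf("removed_indices\t%s",
                   paste(report$removed_indices, collapse = ",")))
  if (!is.null(report$removed_by_tree))
    txt <- c(txt, sprintf("removed_by_tree\t%s",
                          paste(sprintf("%s:%d", names(report$removed_by_tree),
                                        unlist(report$removed_by_tree)),
                                collapse = ",")))
  writeLines(txt, path)
  jsonlite::write_json(unclass(report),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare candidate topologies before and after filtering
#'
#' Evaluates the total log-likelihood of every candidate tree on both
#' matrices and reports the winning topology on each, the package's
#' fixed-candidate analog of re-running tree inference on the filtered
#' data.
#'
#' @param aln_before,aln_after \code{aa_alignment}s (after is usually
#'   the filtered matrix).
#' @param trees Named list of candidate \code{phylo} topologies.
#' @param model Optional \code{aa_model}; defaults to LG+F with
#'   frequencies from \code{aln_before}.
#' @param reoptimize If \code{TRUE} (default) branch lengths and shape
#'   are re-optimized on each matrix, mirroring re-inference; if
#'   \code{FALSE} the trees are evaluated with their given branch
#'   lengths and the model's shape on both matrices (fixed-parameter
#'   mode, exactly idempotent under repeated filtering).
#' @param init Optional list of previously optimized trees (and
#'   \code{alphas}) used as warm starts, e.g. a \code{sitewise_table}.
#' @return Object of class \code{"flip_report"}: per-matrix totals,
#'   winners, whether the winner flipped, and pairwise lnL margins.
#' @export
evaluate_flip <- function(aln_before, aln_after, trees, model = NULL,
                          reoptimize = TRUE, init = NULL) {
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("T", seq_along(trees))
  check_same_leaves(trees)
  if (is.null(model)) model <- build_model("empirical", aln_before, alpha = 1)

  eval_on <- function(aln, start_trees, start_alphas) {
    totals <- numeric(length(trees)); names(totals) <- names(trees)
    fits <- vector("list", length(trees)); names(fits) <- names(trees)
    alphas <- numeric(length(trees))
    for (i in seq_along(trees)) {
      if (reoptimize) {
        mod_i <- model
        if (!is.null(start_alphas) && is.finite(start_alphas[i]))
          mod_i$alpha <- start_alphas[i]
        fit <- optimize_tree(start_trees[[i]], mod_i, aln)
        totals[i] <- fit$logLik; fits[[i]] <- fit$tree; alphas[i] <- fit$alpha
      } else {
        totals[i] <- tree_loglik(trees[[i]], model, aln)
        fits[[i]] <- trees[[i]]; alphas[i] <- model$alpha
      }
    }
    list(totals = totals, trees = fits, alphas = alphas)
  }

  start_trees <- trees; start_alphas <- NULL
  if (!is.null(init) && !is.null(init$trees)) {
    start_trees <- init$trees[names(trees)]
    start_alphas <- init$alphas
  }
  before <- eval_on(aln_before, start_trees, start_alphas)
  after <- eval_on(aln_after, before$trees, before$alphas)

  winner <- function(tot) names(tot)[which.max(tot)]
  res <- list(tree_names = names(trees),
              totals_before = before$totals,
              totals_after = after$totals,
              winner_before = winner(before$totals),
              winner_after = winner(after$totals),
              flipped = winner(before$totals) != winner(after$totals),
              margins_before = max(before$totals) - before$totals,
              margins_after = max(after$totals) - after$totals,
              alphas_before = before$alphas,
              alphas_after = after$alphas,
              trees_before = before$trees,
              trees_after = after$trees)
  class(res) <- "flip_report"
  res
}

#' @export
print.flip_report <- function(x, ...) {
  cat("Candidate-topology comparison\n")
  cat(sprintf("  %-8s %18s %18s\n", "tree", "lnL before", "lnL after"))
  for (i in seq_along(x$tree_names))
    cat(sprintf("  %-8s %18.4f %18.4f\n", x$tree_names[i],
                x$totals_before[i], x$totals_after[i]))
  cat(sprintf("  winner before: %s   winner after: %s%s\n", x$winner_before,
              x$winner_after, if (x$flipped) "   (FLIPPED)" else ""))
  invisible(x)
}
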