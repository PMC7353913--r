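# End-to-end orchestration: score -> classify -> filter ->
# re-evaluate -> report, with plain-text intermediates so external
# per-site likelihood files can replace the internal engine and the
# filtering stages can run on their own.

#' Pipeline run configuration
#'
#' Collects and validates all inputs of a scoring/filtering run.
#' Validation problems are reported all at once.
#'
#' @param alignment Path to the alignment file.
#' @param alignment_format \code{"fasta"} or \code{"phylip"}.
#' @param trees Character vector of newick paths (or strings).
#' @param tree_names Labels for the candidate trees.
#' @param threshold Strong-site threshold (inclusive, default 0.5).
#' @param favored_set Tree labels whose strong sites are removed.
#' @param freq_mode \code{"empirical"} (+F) or \code{"lg"}.
#' @param alpha Initial Gamma shape.
#' @param k Gamma categories.
#' @param persite Optional path to an existing per-site likelihood
#'   file; when given, scoring bypasses the internal engine.
#' @param partitions Optional partition file path.
#' @param out_dir Output directory.
#' @param seed RNG seed recorded in provenance.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(alignment, trees, tree_names = NULL,
                       alignment_format = c("fasta", "phylip"),
                       threshold = 0.5, favored_set = NULL,
                       freq_mode = c("empirical", "lg"), alpha = 1, k = 4L,
                       persite = NULL, partitions = NULL,
                       out_dir = ".", seed = 1L) {
  alignment_format <- match.arg(alignment_format)
  freq_mode <- match.arg(freq_mode)
  if (is.null(tree_names)) tree_names <- paste0("T", seq_along(trees))
  problems <- character(0)
  if (!file.exists(alignment))
    problems <- c(problems, sprintf("alignment file not found: %s", alignment))
  for (t in trees)
    if (!grepl(";", t, fixed = TRUE) && !file.exists(t))
      problems <- c(problems, sprintf("tree file not found: %s", t))
  if (length(trees) != length(tree_names))
    problems <- c(problems, "tree_names length differs from trees")
  if (threshold < 0) problems <- c(problems, "threshold must be >= 0")
  if (!is.null(favored_set) && !all(favored_set %in% tree_names))
    problems <- c(problems, sprintf("favored_set labels not among tree names: %s",
                                    paste(setdiff(favored_set, tree_names),
                                          collapse = ", ")))
  if (!is.null(persite) && !file.exists(persite))
    problems <- c(problems, sprintf("per-site likelihood file not found: %s", persite))
  if (!is.null(partitions) && !file.exists(partitions))
    problems <- c(problems, sprintf("partition file not found: %s", partitions))
  if (length(problems))
    stop(paste(c("invalid configuration:", paste(" -", problems)),
               collapse = "\n"))
  structure(list(alignment = alignment, alignment_format = alignment_format,
                 trees = trees, tree_names = tree_names,
                 threshold = threshold, favored_set = favored_set,
                 freq_mode = freq_mode, alpha = alpha, k = as.integer(k),
                 persite = persite, partitions = partitions,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

provenance_header <- function(config, stage) {
  c(sprintf("# topofilter %s | stage: %s",
            as.character(utils::packageVersion("topofilter")), stage),
    sprintf("# alignment: %s (%s)", config$alignment, config$alignment_format),
    sprintf("# trees: %s", paste(config$tree_names, collapse = ", ")),
    sprintf("# threshold: %g | favored_set: %s", config$threshold,
            paste(config$favored_set %||% "(none)", collapse = ",")),
    sprintf("# model: LG+%s+Gamma(k=%d, alpha0=%g) | seed: %d",
            if (config$freq_mode == "empirical") "F" else "lg",
            config$k, config$alpha, config$seed))
}

load_inputs <- function(config) {
  aln <- read_alignment(config$alignment, config$alignment_format)
  trees <- read_candidate_trees(config$trees, config$tree_names)
  parts <- if (!is.null(config$partitions)) read_partitions(config$partitions)
  list(aln = aln, trees = trees, partitions = parts)
}

#' Score stage: per-site likelihoods and strength records
#'
#' Computes (or ingests) the per-site log-likelihood table and writes
#' it together with the site-strength classification to
#' \code{out_dir}.
#'
#' @param config A \code{"run_config"}.
#' @param quiet Suppress progress messages.
#' @return List with \code{table} (\code{sitewise_table}),
#'   \code{records} (\code{site_strength_df}) and the written paths.
#' @export
cmd_score <- function(config, quiet = FALSE) {
  inp <- load_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (!is.null(config$persite)) {
    if (!quiet) message("using precomputed per-site likelihoods: ", config$persite)
    tab <- read_persite(config$persite, config$tree_names)
    if (tab$n_sites != inp$aln$n_sites)
      stop(sprintf("per-site file has %d sites but alignment has %d",
                   tab$n_sites, inp$aln$n_sites))
  } else {
    if (!quiet) message(sprintf("scoring %d sites under %d topologies",
                                inp$aln$n_sites, length(inp$trees)))
    model <- if (config$freq_mode == "empirical")
      build_model("empirical", inp$aln, alpha = config$alpha, k = config$k)
    else build_model("lg", alpha = config$alpha, k = config$k)
    tab <- per_site_table(inp$aln, inp$trees, model)
  }
  records <- classify_sites(tab, config$threshold)
  persite_path <- file.path(config$out_dir, "persite_lnl.txt")
  strength_path <- file.path(config$out_dir, "site_strength.tsv")
  write_persite(tab, persite_path)
  writeLines(c(provenance_header(config, "score"),
               utils::capture.output(utils::write.table(
                 records, sep = "\t", quote = FALSE, row.names = FALSE))),
             strength_path)
  list(table = tab, records = records,
       persite_path = persite_path, strength_path = strength_path)
}

#' Filter stage: remove targeted strong sites
#'
#' @param config A \code{"run_config"} with non-empty
#'   \code{favored_set}.
#' @param score Optional result of \code{\link{cmd_score}}; computed
#'   if absent.
#' @param quiet Suppress progress messages.
#' @return List with \code{alignment} (filtered), \code{report},
#'   \code{removed}, and the written paths.
#' @export
cmd_filter <- function(config, score = NULL, quiet = FALSE) {
  if (is.null(config$favored_set)) stop("favored_set is required for filtering")
  if (is.null(score)) score <- cmd_score(config, quiet = quiet)
  inp <- load_inputs(config)
  removed <- select_removals(score$records, config$favored_set,
                             config$threshold)
  res <- apply_filter(inp$aln, removed, score$records, inp$partitions)
  aln_path <- file.path(config$out_dir, "weak_alignment.fasta")
  rep_path <- file.path(config$out_dir, "filter_report.txt")
  write_alignment(res$alignment, aln_path, "fasta")
  write_filter_report(res$report, rep_path)
  if (!quiet)
    message(sprintf("removed %d of %d sites (%.2f%%)", res$report$n_removed,
                    res$report$n_total, 100 * res$report$removed_fraction))
  list(alignment = res$alignment, report = res$report, removed = removed,
       alignment_path = aln_path, report_path = rep_path, score = score)
}

#' Compare stage: winner flip and RF table
#'
#' Re-evaluates every candidate topology on the original and filtered
#' matrices and writes the flip report plus the pairwise
#' Robinson-Foulds table of the candidates.
#'
#' @param config A \code{"run_config"}.
#' @param filter Optional result of \code{\link{cmd_filter}}; computed
#'   if absent.
#' @param quiet Suppress progress messages.
#' @return List with \code{flip} (\code{flip_report}), \code{rf}
#'   (matrix) and written paths.
#' @export
cmd_compare <- function(config, filter = NULL, quiet = FALSE) {
  if (is.null(filter)) filter <- cmd_filter(config, quiet = quiet)
  inp <- load_inputs(config)
  model <- if (config$freq_mode == "empirical")
    build_model("empirical", inp$aln, alpha = config$alpha, k = config$k)
  else build_model("lg", alpha = config$alpha, k = config$k)
  flip <- evaluate_flip(inp$aln, filter$alignment, inp$trees, model,
                        init = filter$score$table)
  rf <- rf_matrix(inp$trees)
  flip_path <- file.path(config$out_dir, "flip_report.txt")
  rf_path <- file.path(config$out_dir, "rf_table.tsv")
  writeLines(c(provenance_header(config, "compare"),
               utils::capture.output(print(flip))), flip_path)
  writeLines(c(provenance_header(config, "compare"), format_rf_table(rf)),
             rf_path)
  if (!quiet)
    message(sprintf("winner before: %s, after: %s", flip$winner_before,
                    flip$winner_after))
  list(flip = flip, rf = rf, flip_path = flip_path, rf_path = rf_path)
}
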