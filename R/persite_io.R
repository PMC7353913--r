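# Reader/writer for the per-site log-likelihood text dialect produced
# by sitewise likelihood runs: a header "<n_trees> <n_sites>" followed
# by one line per tree, "<tree_id> <lnL_1> ... <lnL_n>".

#' Parse a per-site log-likelihood file
#'
#' @param path File in the perSiteLLs dialect (header with tree and
#'   site counts, then one whitespace-separated row per tree starting
#'   with a tree identifier).
#' @param tree_names Optional labels overriding the identifiers in the
#'   file.
#' @return A \code{"sitewise_table"}.
#' @export
read_persite <- function(path, tree_names = NULL) {
  if (!file.exists(path)) stop(sprintf("per-site likelihood file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed header: expected '<n_trees> <n_sites>'")
  ntree <- as.integer(hdr[1L]); nsit <- as.integer(hdr[2L])
  body <- lines[-1L]
  if (length(body) != ntree)
    stop(sprintf("header declares %d trees but file has %d rows", ntree,
                 length(body)))
  lnl <- matrix(NA_real_, ntree, nsit)
  ids <- character(ntree)
  for (i in seq_len(ntree)) {
    parts <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    ids[i] <- parts[1L]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (length(vals) != nsit)
      stop(sprintf("row %d ('%s') has %d values, header declares %d sites",
                   i, ids[i], length(vals), nsit))
    if (anyNA(vals))
      stop(sprintf("non-numeric log-likelihood in row %d ('%s') at position %d",
                   i, ids[i], which(is.na(vals))[1L]))
    lnl[i, ] <- vals
  }
  if (is.null(tree_names)) tree_names <- ids
  if (length(tree_names) != ntree) stop("tree_names length mismatch")
  sitewise_table(lnl, tree_names)
}

#' Write a per-site log-likelihood file
#'
#' @param table A \code{"sitewise_table"}.
#' @param path Output path.
#' @param digits Significant digits for the values.
#' @return Invisibly, \code{path}.
#' @export
write_persite <- function(table, path, digits = 10L) {
  stopifnot(inherits(table, "sitewise_table"))
  rows <- vapply(seq_along(table$tree_names), function(i)
    paste(table$tree_names[i],
          paste(formatC(table$lnl[i, ], format = "g", digits = digits),
                collapse = " ")), "")
  writeLines(c(sprintf("%d %d", length(table$tree_names), table$n_sites), rows),
             path)
  invisible(path)
}
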