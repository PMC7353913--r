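# Amino-acid alignment container and readers/writers.
#
# Residues are stored as an upper-case character matrix (taxa x sites).
# The 20 standard amino acids are data states; gaps ('-') and the
# ambiguity codes X, B, Z, J, ?, * are collapsed into a single missing
# class for likelihood purposes.

#' Canonical amino-acid residue order
#'
#' The 20 standard amino acids in the order used by the LG rate matrix
#' (PAML order: A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @return Character vector of length 20.
#' @export
aa_states <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.missing_chars <- c("-", "X", "B", "Z", "J", "?", "*", ".")

#' Construct an amino-acid alignment
#'
#' @param x Character matrix (taxa in rows, sites in columns) with row
#'   names giving taxon labels, or a named list/character vector of
#'   equal-length sequences.
#' @return An object of class \code{"aa_alignment"}: a list with
#'   elements \code{mat} (character matrix), \code{taxa} and
#'   \code{n_sites}.
#' @examples
#' aln <- aa_alignment(c(t1 = "ACDE", t2 = "AC-E"))
#' n_sites(aln)
#' @export
aa_alignment <- function(x) {
  if (is.list(x) || (is.character(x) && !is.matrix(x))) {
    seqs <- vapply(x, paste0, "", collapse = "")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named with taxon labels")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop(sprintf("alignment is ragged: taxon '%s' has %d sites, expected %d",
                   names(seqs)[bad], lens[bad], lens[1L]))
    }
    x <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(x) <- names(seqs)
  }
  stopifnot(is.matrix(x), is.character(x))
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("alignment must have at least 1 taxon and 1 site")
  if (is.null(rownames(x)) || any(!nzchar(rownames(x))))
    stop("alignment matrix must have non-empty row names (taxon labels)")
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate taxon label: '%s'",
                 rownames(x)[duplicated(rownames(x))][1L]))
  x[] <- toupper(x)
  ok <- matrix(x %in% c(aa_states(), .missing_chars), nrow(x))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal residue '%s' for taxon '%s' at site %d",
                 x[bad[1L], bad[2L]], rownames(x)[bad[1L]], bad[2L]))
  }
  structure(list(mat = x, taxa = rownames(x), n_sites = ncol(x)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d taxa, %d sites\n",
              length(x$taxa), x$n_sites))
  show <- utils::head(x$taxa, 5L)
  for (t in show)
    cat(sprintf("  %-20s %s%s\n", t,
                paste0(x$mat[t, seq_len(min(40L, x$n_sites))], collapse = ""),
                if (x$n_sites > 40L) "..." else ""))
  if (length(x$taxa) > 5L)
    cat(sprintf("  ... and %d more taxa\n", length(x$taxa) - 5L))
  invisible(x)
}

#' Number of sites in an alignment
#' @param aln An \code{aa_alignment}.
#' @return Integer site count.
#' @export
n_sites <- function(aln) aln$n_sites

#' Extract alignment columns
#'
#' @param aln An \code{aa_alignment}.
#' @param sites Integer vector of 1-based column indices to keep.
#' @return A new \code{aa_alignment} with the selected columns.
#' @export
subset_sites <- function(aln, sites) {
  stopifnot(inherits(aln, "aa_alignment"))
  sites <- as.integer(sites)
  if (any(sites < 1L | sites > aln$n_sites))
    stop("site index out of range")
  if (length(sites) == 0L) stop("cannot create an empty alignment")
  aa_alignment(aln$mat[, sites, drop = FALSE])
}

#' Encode residues as integer states
#'
#' Maps each residue to its index in \code{aa_states()}; missing-class
#' characters (gap and ambiguity codes) become \code{NA}.
#'
#' @param aln An \code{aa_alignment}.
#' @return Integer matrix (taxa x sites) with \code{NA} for missing.
#' @export
encode_alignment <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- match(aln$mat, aa_states())
  dim(m) <- dim(aln$mat)
  dimnames(m) <- dimnames(aln$mat)
  m
}

#' Read a protein alignment
#'
#' Reads FASTA (via \pkg{Biostrings}) or relaxed sequential PHYLIP. Residues
#' are upper-cased; \code{?} and \code{*} are mapped to the missing
#' class.
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed,
#'   sequential). \code{"phylip-relaxed"} is accepted as a synonym.
#' @return An \code{aa_alignment}.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "phylip-relaxed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("alignment file not found: %s", path))
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)   # byte-faithful, no translation
    if (length(x) == 0L) stop("no sequences found in FASTA file")
    seqs <- stats::setNames(as.character(x),
                            sub("\\s.*$", "", names(x)))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop(sprintf("alignment is ragged: taxon '%s' has %d sites, expected %d",
                   names(seqs)[bad], lens[bad], lens[1L]))
    }
    return(aa_alignment(seqs))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("PHYLIP file too short")
  hdr <- scan(text = lines[1L], what = integer(), quiet = TRUE, n = 2L)
  if (length(hdr) != 2L) stop("malformed PHYLIP header (need taxon and site counts)")
  ntax <- hdr[1L]; nsit <- hdr[2L]
  body <- lines[-1L]
  if (length(body) != ntax)
    stop(sprintf("PHYLIP header declares %d taxa but file has %d sequence lines",
                 ntax, length(body)))
  nm <- character(ntax); sq <- character(ntax)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    if (length(parts) < 2L)
      stop(sprintf("malformed PHYLIP sequence line %d", i))
    nm[i] <- parts[1L]
    sq[i] <- paste0(parts[-1L], collapse = "")
    if (nchar(sq[i]) != nsit)
      stop(sprintf("alignment is ragged: taxon '%s' has %d sites, expected %d",
                   nm[i], nchar(sq[i]), nsit))
  }
  names(sq) <- nm
  aa_alignment(sq)
}

#' Write a protein alignment
#'
#' @param aln An \code{aa_alignment}.
#' @param path Output file path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed sequential,
#'   header \code{"<ntaxa> <nsites>"}).
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "phylip-relaxed")) {
  stopifnot(inherits(aln, "aa_alignment"))
  format <- match.arg(format)
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", aln$taxa), seqs))
  } else {
    out <- c(sprintf("%d %d", length(aln$taxa), aln$n_sites),
             sprintf("%s  %s", aln$taxa, seqs))
  }
  writeLines(out, path)
  invisible(path)
}

# TRUE where a cell holds one of the 20 data states
present_mask <- function(aln) !is.na(encode_alignment(aln))
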