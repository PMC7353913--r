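# The per-site topology-strength statistic.
#
# A site's strength dlnL is the log-likelihood of its best candidate
# topology minus that of the second best: a non-negative number that
# is zero when the top two topologies tie. Sites with dlnL >= 0.5
# (threshold inclusive) are "strong"; everything else is effectively
# phylogenetic noise for the contested node. The alternative statistic
# of Shen et al. (mean of the absolute pairwise differences involving
# each topology) is provided for comparison; it overestimates the
# strength of sites where one topology is much weaker than the other
# two.

#' Site strength from per-tree log-likelihoods
#'
#' @param lnls Numeric vector, one log-likelihood per candidate tree
#'   (>= 2 finite values). Names, if present, label the trees.
#' @return List with \code{best} (index or name of the best tree),
#'   \code{dlnl} (max minus second max, >= 0) and \code{tie} (TRUE
#'   when the top two values are equal; the best tree is then the
#'   first in input order).
#' @examples
#' site_strength(c(T1 = -10.0, T2 = -10.6, T3 = -11.0))
#' @export
site_strength <- function(lnls) {
  if (length(lnls) < 2L || any(!is.finite(lnls)))
    stop("need at least 2 finite log-likelihood values")
  o <- order(lnls, decreasing = TRUE)
  d <- lnls[o[1L]] - lnls[o[2L]]
  best_i <- which(lnls == lnls[o[1L]])[1L]  # ties resolve to input order
  list(best = if (is.null(names(lnls))) best_i else names(lnls)[best_i],
       dlnl = unname(d), tie = d == 0)
}

#' Shen-style per-topology strength
#'
#' For each of exactly three candidate topologies, the mean of the
#' absolute log-likelihood differences of the two pairs involving it.
#' For the best topology this is never smaller than the
#' max-minus-second-best statistic, which is why it overestimates the
#' strength of sites where the third topology is far weaker.
#'
#' @param lnls Numeric vector of exactly 3 finite values.
#' @return Numeric vector of 3 non-negative scores.
#' @examples
#' shen_strength(c(-1, -2, -3))  # 1.5 1.0 1.5
#' @export
shen_strength <- function(lnls) {
  if (length(lnls) != 3L)
    stop("the mean-absolute-difference statistic is defined for exactly 3 trees")
  if (any(!is.finite(lnls))) stop("log-likelihoods must be finite")
  out <- vapply(1:3, function(i) mean(abs(lnls[i] - lnls[-i])), 0)
  names(out) <- names(lnls)
  out
}

#' Classify every site of a sitewise table
#'
#' @param table A \code{"sitewise_table"}.
#' @param threshold Strong-site threshold on dlnL, inclusive
#'   (default 0.5).
#' @return Data frame of class \code{"site_strength_df"} with columns
#'   \code{site} (1-based), \code{best_tree}, \code{dlnl}, \code{tie},
#'   \code{is_strong}, and \code{shen} (NA unless exactly 3 trees).
#' @export
classify_sites <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "sitewise_table"))
  if (threshold < 0) stop("threshold must be non-negative")
  lnl <- table$lnl
  nt <- nrow(lnl)
  # columnwise top-two without sorting whole columns
  best_i <- max.col(t(lnl), ties.method = "first")
  best_v <- lnl[cbind(best_i, seq_len(ncol(lnl)))]
  tmp <- lnl
  tmp[cbind(best_i, seq_len(ncol(lnl)))] <- -Inf
  second_v <- apply(tmp, 2L, max)
  d <- best_v - second_v
  shen <- rep(NA_real_, ncol(lnl))
  if (nt == 3L) {
    s12 <- abs(lnl[1L, ] - lnl[2L, ])
    s13 <- abs(lnl[1L, ] - lnl[3L, ])
    s23 <- abs(lnl[2L, ] - lnl[3L, ])
    shen_all <- rbind((s12 + s13) / 2, (s12 + s23) / 2, (s13 + s23) / 2)
    shen <- shen_all[cbind(best_i, seq_len(ncol(lnl)))]
  }
  out <- data.frame(site = seq_len(ncol(lnl)),
                    best_tree = table$tree_names[best_i],
                    dlnl = d,
                    tie = d == 0,
                    is_strong = d >= threshold & d > 0,
                    shen = shen)
  attr(out, "threshold") <- threshold
  attr(out, "tree_names") <- table$tree_names
  class(out) <- c("site_strength_df", "data.frame")
  out
}

#' Summary statistics of site strengths
#'
#' Characterizes the strength distribution: the fraction of sites with
#' near-zero signal and where the strong-site threshold sits in units
#' of standard deviations above the mean.
#'
#' @param records A \code{"site_strength_df"} (or data frame with a
#'   \code{dlnl} column).
#' @param epsilon Sites with \code{dlnl < epsilon} count as "close to
#'   zero" (default 0.1).
#' @param threshold Strong-site threshold (default: the one recorded
#'   in \code{records}, else 0.5).
#' @return List with \code{mean_dlnl}, \code{sd_dlnl},
#'   \code{frac_below}, \code{threshold_in_sd} (NA when the standard
#'   deviation is zero), \code{epsilon}, \code{threshold}, \code{n}.
#' @export
strength_summary <- function(records, epsilon = 0.1, threshold = NULL) {
  d <- records$dlnl
  if (length(d) == 0L) stop("no site records")
  if (is.null(threshold))
    threshold <- attr(records, "threshold") %||% 0.5
  m <- mean(d); s <- stats::sd(d)
  list(mean_dlnl = m, sd_dlnl = s,
       frac_below = mean(d < epsilon),
       threshold_in_sd = if (is.na(s) || s == 0) NA_real_ else (threshold - m) / s,
       epsilon = epsilon, threshold = threshold, n = length(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a site-strength table
#'
#' Tab-separated columns: site, best_tree, dlnL, is_strong, tie, shen.
#'
#' @param records A \code{"site_strength_df"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_strength <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a site-strength table written by \code{\link{write_strength}}
#'
#' @param path Input path.
#' @param threshold Threshold to record on the result (default 0.5).
#' @return A \code{"site_strength_df"}.
#' @export
read_strength <- function(path, threshold = 0.5) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "threshold") <- threshold
  class(df) <- c("site_strength_df", "data.frame")
  df
}
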