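# LG+F+Gamma substitution model.
#
# The instantaneous rate matrix is Q_ij = s_ij * pi_j (i != j) with the
# LG exchangeabilities s, diagonal set so rows sum to 0, and the whole
# matrix scaled so the expected substitution rate -sum_i pi_i Q_ii is 1
# (branch lengths are then expected substitutions per site). Because
# diag(pi) Q is symmetric (time reversibility), exp(Qt) is obtained by
# a symmetric eigendecomposition done once per model.

lg_constants_env <- new.env(parent = emptyenv())

#' Published LG exchangeabilities and frequencies
#'
#' Parses the LG replacement-model constants bundled with the package
#' (Le & Gascuel 2008), in the residue order of \code{aa_states()}.
#'
#' @return List with \code{exch} (symmetric 20x20 matrix, zero
#'   diagonal) and \code{freq} (named length-20 vector summing to 1).
#' @export
lg_constants <- function() {
  if (!is.null(lg_constants_env$lg)) return(lg_constants_env$lg)
  path <- system.file("extdata", "lg.dat", package = "topofilter")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  ex <- matrix(0, 20L, 20L, dimnames = list(aa_states(), aa_states()))
  for (i in 2:20) {
    vals <- scan(text = lines[i - 1L], quiet = TRUE)
    stopifnot(length(vals) == i - 1L)
    ex[i, seq_len(i - 1L)] <- vals
  }
  ex <- ex + t(ex)
  freq <- scan(text = lines[20L], quiet = TRUE)
  stopifnot(length(freq) == 20L)
  names(freq) <- aa_states()
  lg_constants_env$lg <- list(exch = ex, freq = freq / sum(freq))
  lg_constants_env$lg
}

#' Discrete Gamma rate categories
#'
#' Mean rates of \code{k} equal-probability bands of a Gamma
#' distribution with shape \code{alpha} and mean 1 (the usual
#' discretization of among-site rate variation). The category means
#' average to exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of \code{k} increasing positive rates.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive number")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  # band boundaries are quantiles of Gamma(alpha, rate = alpha);
  # band means come from the CDF of Gamma(alpha + 1, rate = alpha)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  rates <- k * diff(p)
  rates / mean(rates) * 1  # guard against roundoff; mean is 1 by construction
}

#' Build an LG+F+Gamma model
#'
#' @param freq_mode \code{"lg"} uses the published LG frequencies;
#'   \code{"empirical"} (the "+F" option) counts residues over all
#'   non-missing cells of \code{aln}, adding \code{pseudocount}
#'   observations per residue class so no frequency is zero.
#' @param aln \code{aa_alignment}; required for empirical frequencies.
#' @param alpha Gamma shape parameter (default 1).
#' @param k Number of discrete Gamma categories (default 4).
#' @param pseudocount Added per residue class in empirical mode.
#' @return Object of class \code{"aa_model"}: exchangeabilities,
#'   frequencies, normalized rate matrix \code{Q}, its symmetric
#'   eigendecomposition, \code{alpha} and \code{k}.
#' @examples
#' mod <- build_model("lg", alpha = 0.8)
#' range(rowSums(transition_matrix(mod, 0.3)))
#' @export
build_model <- function(freq_mode = c("lg", "empirical", "lg-default"),
                        aln = NULL, alpha = 1, k = 4L, pseudocount = 0.5) {
  freq_mode <- match.arg(freq_mode)
  lg <- lg_constants()
  if (freq_mode == "empirical") {
    if (is.null(aln)) stop("empirical frequencies require an alignment")
    enc <- encode_alignment(aln)
    counts <- tabulate(enc[!is.na(enc)], nbins = 20L)
    if (sum(counts) == 0L)
      stop("alignment has no non-missing residues; cannot estimate frequencies")
    freq <- (counts + pseudocount) / sum(counts + pseudocount)
    names(freq) <- aa_states()
  } else {
    freq <- lg$freq
  }
  model <- list(exch = lg$exch, freq = freq, alpha = alpha, k = as.integer(k))
  model <- c(model, build_q(lg$exch, freq))
  class(model) <- "aa_model"
  model
}

# rate matrix, normalization and eigendecomposition shared by models
build_q <- function(exch, freq) {
  Q <- exch * rep(freq, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  # states with zero frequency are unreachable; keep the similarity
  # transform finite so the decomposition still exists
  sq <- sqrt(pmax(freq, 1e-12))
  B <- Q * (sq / rep(sq, each = 20L))  # diag(sq) Q diag(1/sq), symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(Q = Q,
       eig_values = eig$values,
       eig_left = eig$vectors / sq,              # diag(1/sq) U
       eig_right = t(eig$vectors * sq))          # U' diag(sq)
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("LG+F+Gamma model: alpha = %.4g, %d rate categories\n",
              x$alpha, x$k))
  cat("frequencies:", paste(sprintf("%s=%.3f", names(x$freq)[1:5],
                                    x$freq[1:5]), collapse = " "), "...\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' \eqn{P(t) = \exp(Q t r)} for branch length \code{t} and relative
#' rate \code{rate}, via the model's cached eigendecomposition. Rows
#' sum to 1; tiny negative entries from roundoff are clamped to 0.
#'
#' @param model An \code{aa_model}.
#' @param t Branch length (>= 0), expected substitutions per site.
#' @param rate Relative rate multiplier (e.g. a Gamma category rate).
#' @return 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  P <- model$eig_left %*% (exp(model$eig_values * (t * rate)) * model$eig_right)
  P[P < 0] <- 0
  dimnames(P) <- list(aa_states(), aa_states())
  P
}
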