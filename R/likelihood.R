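# Per-site log-likelihoods under fixed topologies: Felsenstein pruning
# with a discrete-Gamma rate mixture, per-node rescaling against
# underflow, site-pattern compression, and coordinate-ascent
# optimization of branch lengths and the Gamma shape.
#
# Internals operate on an "engine" environment holding, per candidate
# tree: the postorder node structure, tip partial-likelihood matrices
# (20 x n_patterns), current branch lengths indexed by child node, and
# per-category conditional likelihoods of every node.

.BL_MIN <- 1e-8
.BL_MAX <- 50

pmat <- function(model, t, rate) {
  P <- model$eig_left %*% (exp(model$eig_values * (t * rate)) * model$eig_right)
  P[P < 0] <- 0
  P
}

# collapse alignment columns to unique site patterns
compress_patterns <- function(enc) {
  key <- apply(enc, 2L, paste, collapse = ",")
  map <- match(key, key)                 # first occurrence index per site
  first <- sort(unique(map))
  idx <- match(map, first)               # site -> pattern
  list(pat = enc[, first, drop = FALSE],
       weights = tabulate(idx, nbins = length(first)),
       site_to_pat = idx)
}

new_engine <- function(tree, model, aln) {
  if (ape::Ntip(tree) >= 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- stats::reorder(tree, "postorder")
  missing_tips <- setdiff(tree$tip.label, aln$taxa)
  if (length(missing_tips))
    stop(sprintf("tree leaf absent from alignment: %s",
                 paste(missing_tips, collapse = ", ")))
  enc <- encode_alignment(aln)[tree$tip.label, , drop = FALSE]
  cp <- compress_patterns(enc)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  npat <- ncol(cp$pat)

  children <- vector("list", nnode)
  lens <- rep(NA_real_, nnode)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(NA_real_, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    children[[p]] <- c(children[[p]], c)
    lens[c] <- el[e]
  }
  # postorder internal nodes (parents in edge postorder, deduplicated)
  internals <- unique(tree$edge[, 1L])

  tipL <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    L <- matrix(0, 20L, npat)
    s <- cp$pat[i, ]
    obs <- which(!is.na(s))
    L[cbind(s[obs], obs)] <- 1
    if (length(obs) < npat) L[, setdiff(seq_len(npat), obs)] <- 1
    tipL[[i]] <- L
  }

  en <- new.env(parent = emptyenv())
  en$tree <- tree; en$ntip <- ntip; en$nnode <- nnode
  en$root <- ntip + 1L
  en$children <- children; en$lens <- lens; en$internals <- internals
  en$tipL <- tipL; en$npat <- npat
  en$w <- cp$weights; en$site_to_pat <- cp$site_to_pat
  en$model <- model; en$K <- model$k
  en$alpha <- model$alpha
  en$rates <- discrete_gamma_rates(model$alpha, model$k)
  en$D <- NULL; en$lsc <- NULL
  en
}

# conditional likelihoods of one internal node from its children
down_node <- function(en, u) {
  kids <- en$children[[u]]
  for (cat in seq_len(en$K)) {
    acc <- NULL; lsc <- 0
    for (v in kids) {
      P <- pmat(en$model, en$lens[v], en$rates[cat])
      Dv <- if (v <= en$ntip) en$tipL[[v]] else en$D[[cat]][[v]]
      PD <- P %*% Dv
      acc <- if (is.null(acc)) PD else acc * PD
      if (v > en$ntip) lsc <- lsc + en$lsc[[cat]][[v]]
    }
    sc <- colSums(acc)
    sc[sc <= 0] <- .Machine$double.xmin
    en$D[[cat]][[u]] <- acc * rep(1 / sc, each = 20L)
    en$lsc[[cat]][[u]] <- lsc + log(sc)
  }
}

full_down <- function(en) {
  en$D <- replicate(en$K, vector("list", en$nnode), simplify = FALSE)
  en$lsc <- replicate(en$K, vector("list", en$nnode), simplify = FALSE)
  for (u in en$internals) down_node(en, u)
}

# per-pattern log-likelihood from root conditionals, mixed over categories
pattern_lnl <- function(en) {
  CL <- matrix(0, en$K, en$npat)
  piv <- en$model$freq
  for (cat in seq_len(en$K)) {
    lik <- colSums(piv * en$D[[cat]][[en$root]])
    lik[lik <= 0] <- .Machine$double.xmin
    CL[cat, ] <- log(lik) + en$lsc[[cat]][[en$root]]
  }
  mix_categories(CL)
}

mix_categories <- function(CL) {
  K <- nrow(CL)
  if (K == 1L) return(CL[1L, ])
  M <- CL[1L, ]
  for (k in 2:K) M <- pmax(M, CL[k, ])
  s <- exp(CL[1L, ] - M)
  for (k in 2:K) s <- s + exp(CL[k, ] - M)
  M + log(s / K)
}

engine_total <- function(en) {
  full_down(en)
  sum(en$w * pattern_lnl(en))
}

#' Log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning under the supplied LG+F+Gamma model, using the
#' tree's branch lengths as given (no optimization).
#'
#' @param tree \code{phylo} with branch lengths; leaves must appear in
#'   the alignment.
#' @param model An \code{aa_model}.
#' @param aln An \code{aa_alignment}.
#' @param per_site If \code{TRUE}, also return the per-site
#'   log-likelihood vector (original column order).
#' @return Total log-likelihood, or (with \code{per_site}) a list with
#'   \code{total} and \code{site_lnl}.
#' @export
tree_loglik <- function(tree, model, aln, per_site = FALSE) {
  en <- new_engine(tree, model, aln)
  if (anyNA(en$lens[-en$root]))
    stop("tree has missing branch lengths; optimize or set them first")
  full_down(en)
  lnl <- pattern_lnl(en)
  total <- sum(en$w * lnl)
  if (!per_site) return(total)
  list(total = total, site_lnl = lnl[en$site_to_pat])
}

#' Log-likelihood of a single alignment site
#'
#' @param tree \code{phylo} with branch lengths.
#' @param model An \code{aa_model}.
#' @param site Named character vector: one residue per taxon; names
#'   must cover the tree's leaves.
#' @return Site log-likelihood (<= 0 for informative input). A site
#'   that is missing in every taxon has likelihood 1 and returns 0
#'   with a warning.
#' @export
site_log_likelihood <- function(tree, model, site) {
  absent <- setdiff(tree$tip.label, names(site))
  if (length(absent))
    stop(sprintf("leaf missing from site data: %s",
                 paste(absent, collapse = ", ")))
  aln <- aa_alignment(as.list(site))
  if (all(is.na(encode_alignment(aln))))
    warning("site is missing in all taxa; log-likelihood is 0")
  tree_loglik(tree, model, aln)
}

## --- branch-length / shape optimization ------------------------------

# log-likelihood profile of one branch given the flanking conditionals
edge_lnl_fun <- function(en, piX, lscX, Dv, lscDv) {
  function(t) {
    CL <- matrix(0, en$K, en$npat)
    for (cat in seq_len(en$K)) {
      P <- pmat(en$model, t, en$rates[cat])
      lik <- colSums(piX[[cat]] * (P %*% Dv[[cat]]))
      lik[lik <= 0] <- .Machine$double.xmin
      CL[cat, ] <- log(lik) + lscX[[cat]] + lscDv[[cat]]
    }
    sum(en$w * mix_categories(CL))
  }
}

# Brent search on the log scale, starting from a window around the
# current value and expanding toward a bound when the optimum lands on
# the window edge (a blind search over the whole range can step across
# narrow optima).
maximize_1d <- function(f, lower, upper, cur, tol = 1e-4, window = 10) {
  lo <- max(lower, cur / window); hi <- min(upper, cur * window)
  repeat {
    opt <- stats::optimize(function(u) f(exp(u)), lower = log(lo),
                           upper = log(hi), maximum = TRUE, tol = tol)
    at_lo <- opt$maximum < log(lo) + 10 * tol && lo > lower
    at_hi <- opt$maximum > log(hi) - 10 * tol && hi < upper
    if (!at_lo && !at_hi) break
    if (at_lo) lo <- max(lower, lo / window^2)
    if (at_hi) hi <- min(upper, hi * window^2)
  }
  cand <- exp(opt$maximum)
  if (opt$objective > f(cur)) cand else cur
}

# depth-first exact coordinate ascent over branches below node u.
# A/lscA: per-category "above" conditionals at u (stationary freqs not
# yet applied); all caches reflect the current branch lengths.
optimize_edges_below <- function(en, u, A, lscA) {
  kids <- en$children[[u]]
  piv <- en$model$freq
  for (v in kids) {
    sibs <- setdiff(kids, v)
    X <- vector("list", en$K); lscX <- vector("list", en$K)
    for (cat in seq_len(en$K)) {
      acc <- A[[cat]]; lsc <- lscA[[cat]]
      for (s in sibs) {
        P <- pmat(en$model, en$lens[s], en$rates[cat])
        Ds <- if (s <= en$ntip) en$tipL[[s]] else en$D[[cat]][[s]]
        acc <- acc * (P %*% Ds)
        if (s > en$ntip) lsc <- lsc + en$lsc[[cat]][[s]]
      }
      sc <- colSums(acc); sc[sc <= 0] <- .Machine$double.xmin
      X[[cat]] <- acc * rep(1 / sc, each = 20L)
      lscX[[cat]] <- lsc + log(sc)
    }
    Dv <- vector("list", en$K); lscDv <- vector("list", en$K)
    for (cat in seq_len(en$K)) {
      if (v <= en$ntip) {
        Dv[[cat]] <- en$tipL[[v]]; lscDv[[cat]] <- 0
      } else {
        Dv[[cat]] <- en$D[[cat]][[v]]; lscDv[[cat]] <- en$lsc[[cat]][[v]]
      }
    }
    piX <- lapply(X, function(m) piv * m)
    f <- edge_lnl_fun(en, piX, lscX, Dv, lscDv)
    en$lens[v] <- maximize_1d(f, .BL_MIN, .BL_MAX, en$lens[v])
    if (v > en$ntip) {
      Av <- vector("list", en$K); lscAv <- vector("list", en$K)
      for (cat in seq_len(en$K)) {
        P <- pmat(en$model, en$lens[v], en$rates[cat])
        Au <- P %*% X[[cat]]
        sc <- colSums(Au); sc[sc <= 0] <- .Machine$double.xmin
        Av[[cat]] <- Au * rep(1 / sc, each = 20L)
        lscAv[[cat]] <- lscX[[cat]] + log(sc)
      }
      optimize_edges_below(en, v, Av, lscAv)
      down_node(en, v)   # refresh with the subtree's new branch lengths
    }
  }
}

#' Optimize branch lengths and Gamma shape on a fixed topology
#'
#' Coordinate ascent: exact one-dimensional (Brent) optimization of
#' each branch length in depth-first order with cached conditional
#' likelihoods, followed by optimization of the Gamma shape, repeated
#' until the total log-likelihood improves by less than \code{tol}.
#' The total never decreases across sweeps. Branch lengths are bounded
#' to [1e-8, 50].
#'
#' @param tree \code{phylo} (branch lengths used as the starting
#'   point; missing lengths start at 0.1).
#' @param model An \code{aa_model}; its \code{alpha} is the starting
#'   shape.
#' @param aln An \code{aa_alignment}.
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_sweeps Maximum number of sweeps.
#' @param optimize_alpha Set \code{FALSE} to hold the shape fixed.
#' @return List with \code{tree} (optimized branch lengths),
#'   \code{alpha}, \code{logLik}, and \code{sweeps} used.
#' @export
optimize_tree <- function(tree, model, aln, tol = 1e-4, max_sweeps = 50L,
                          optimize_alpha = TRUE) {
  en <- new_engine(tree, model, aln)
  if (anyNA(en$lens[-en$root])) {
    en$lens[is.na(en$lens)] <- 0.1
    en$lens[en$root] <- NA_real_
  }
  en$lens <- pmin(pmax(en$lens, .BL_MIN), .BL_MAX)
  en$lens[en$root] <- NA_real_
  total <- engine_total(en)
  ones <- lapply(seq_len(en$K), function(i) matrix(1, 20L, en$npat))
  zeros <- lapply(seq_len(en$K), function(i) rep(0, en$npat))
  sweeps <- 0L; converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    full_down(en)
    optimize_edges_below(en, en$root, ones, zeros)
    if (optimize_alpha) {
      falpha <- function(a) {
        en$rates <- discrete_gamma_rates(a, en$K)
        engine_total(en)
      }
      new_alpha <- maximize_1d(falpha, 0.02, 100, en$alpha, tol = 1e-3)
      en$alpha <- new_alpha
      en$rates <- discrete_gamma_rates(en$alpha, en$K)
    }
    new_total <- engine_total(en)
    improved <- new_total - total
    total <- new_total
    if (improved < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("branch-length optimization did not converge in %d sweeps",
                    max_sweeps))
  out_tree <- en$tree
  out_tree$edge.length <- en$lens[out_tree$edge[, 2L]]
  attr(out_tree, "name") <- attr(tree, "name")
  list(tree = out_tree, alpha = en$alpha, logLik = total, sweeps = sweeps)
}

#' Per-site log-likelihood table for candidate topologies
#'
#' For each candidate tree independently: optimize branch lengths and
#' Gamma shape on the full alignment, then emit the per-site
#' log-likelihood of every column (the table an external sitewise
#' likelihood run would produce). The per-site values of a tree sum to
#' its optimized total.
#'
#' @param aln An \code{aa_alignment}.
#' @param trees Named list of \code{phylo} candidate topologies over
#'   identical leaf sets (>= 2 trees).
#' @param model An \code{aa_model}; defaults to LG with empirical
#'   (+F) frequencies from \code{aln} and alpha 1 as the starting
#'   shape.
#' @param optimize If \code{FALSE}, evaluate each tree with its given
#'   branch lengths and the model's shape (fixed-parameter mode).
#' @param tol,max_sweeps Passed to \code{\link{optimize_tree}}.
#' @return Object of class \code{"sitewise_table"}: list with
#'   \code{tree_names}, \code{lnl} (trees x sites matrix),
#'   \code{totals}, \code{alphas}, \code{trees} (optimized trees) and
#'   \code{n_sites}.
#' @export
per_site_table <- function(aln, trees, model = NULL, optimize = TRUE,
                           tol = 1e-4, max_sweeps = 50L) {
  if (length(trees) < 2L) stop("need at least 2 candidate trees")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("T", seq_along(trees))
  check_same_leaves(trees)
  if (is.null(model)) model <- build_model("empirical", aln, alpha = 1)
  lnl <- matrix(NA_real_, length(trees), aln$n_sites,
                dimnames = list(names(trees), NULL))
  totals <- stats::setNames(numeric(length(trees)), names(trees))
  alphas <- stats::setNames(numeric(length(trees)), names(trees))
  fitted <- vector("list", length(trees)); names(fitted) <- names(trees)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (optimize) {
      fit <- optimize_tree(tr, model, aln, tol = tol, max_sweeps = max_sweeps)
      tr <- fit$tree; alphas[i] <- fit$alpha
      mod_i <- model; mod_i$alpha <- fit$alpha
    } else {
      mod_i <- model; alphas[i] <- model$alpha
    }
    res <- tree_loglik(tr, mod_i, aln, per_site = TRUE)
    lnl[i, ] <- res$site_lnl
    totals[i] <- res$total
    fitted[[i]] <- tr
  }
  structure(list(tree_names = names(trees), lnl = lnl, totals = totals,
                 alphas = alphas, trees = fitted, n_sites = aln$n_sites),
            class = "sitewise_table")
}

#' @export
print.sitewise_table <- function(x, ...) {
  cat(sprintf("Sitewise log-likelihood table: %d trees x %d sites\n",
              length(x$tree_names), x$n_sites))
  for (i in seq_along(x$tree_names))
    cat(sprintf("  %-8s total lnL = %.4f\n", x$tree_names[i], x$totals[i]))
  invisible(x)
}

#' Assemble a sitewise table from raw values
#'
#' @param lnl Numeric matrix, one row per candidate tree, one column
#'   per site.
#' @param tree_names Row labels; defaults to existing row names.
#' @return A \code{"sitewise_table"}.
#' @export
sitewise_table <- function(lnl, tree_names = rownames(lnl)) {
  stopifnot(is.matrix(lnl), nrow(lnl) >= 2L)
  if (is.null(tree_names)) tree_names <- paste0("tr", seq_len(nrow(lnl)))
  rownames(lnl) <- tree_names
  structure(list(tree_names = tree_names, lnl = lnl,
                 totals = rowSums(lnl), alphas = rep(NA_real_, nrow(lnl)),
                 trees = NULL, n_sites = ncol(lnl)),
            class = "sitewise_table")
}
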