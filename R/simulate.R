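# Simulator of supermatrices with the signal structure the sitewise
# analysis assumes: a large background of sites carrying essentially
# no signal for one contested deep node (simulated on a star-like
# resolution with a collapsed internal branch), plus small planted
# minorities of sites simulated under each of the three resolutions
# with a non-trivial contested branch. Four leaf groups A, B, C and
# outgroup O surround the contested edge; the three resolutions pair
# {B,C}, {A,C} and {A,B} against the rest.

#' Specification of a planted-signal mixture
#'
#' Defaults describe the package's reference validation matrix: 12
#' taxa, 20,000 sites, 1% / 0.8% / 0.5% of sites planted under the
#' three resolutions (contested branch 0.5 substitutions/site), the
#' remaining ~97.7% on the collapsed-branch star analog. Background
#' branches average 0.05 substitutions/site (a slow-evolving gene set),
#' calibrated once so the realized strength distribution matches the
#' structure the analysis assumes: ~99% of sites with near-zero signal
#' and the 0.5 threshold roughly 3 standard deviations above the mean.
#'
#' @param clade_sizes Named integer vector: leaves in groups A, B, C,
#'   O (all >= 1).
#' @param proportions Named fractions of sites simulated under T1, T2,
#'   T3; the remainder is background ("star") sites. Must sum to <= 1.
#' @param internal_branch Length of the contested internal edge for
#'   planted-signal sites.
#' @param star_branch Contested-edge length for background sites.
#' @param background_mean Mean of the exponential distribution from
#'   which all other branch lengths are drawn (once per spec, shared
#'   across the three topologies).
#' @param background_scale Multiplier on \code{background_mean}.
#' @param n_sites Total site count.
#' @param seed RNG seed (single stream; draw order is topology branch
#'   lengths, per-site Gamma categories, site states per block in T1,
#'   T2, T3, star order, then the site shuffle).
#' @return List of class \code{"mixture_spec"}.
#' @export
mixture_spec <- function(clade_sizes = c(A = 3L, B = 3L, C = 4L, O = 2L),
                         proportions = c(T1 = 0.01, T2 = 0.008, T3 = 0.005),
                         internal_branch = 0.5,
                         star_branch = 1e-6,
                         background_mean = 0.2,
                         background_scale = 0.25,
                         n_sites = 20000L,
                         seed = 42L) {
  stopifnot(length(clade_sizes) == 4L, all(clade_sizes >= 1L))
  names(clade_sizes) <- c("A", "B", "C", "O")
  stopifnot(length(proportions) == 3L, all(proportions >= 0))
  if (sum(proportions) > 1) stop("proportions must sum to <= 1")
  names(proportions) <- c("T1", "T2", "T3")
  stopifnot(n_sites >= 1L, internal_branch >= 0, star_branch >= 0)
  clade_sizes <- stats::setNames(as.integer(clade_sizes), names(clade_sizes))
  structure(list(clade_sizes = clade_sizes,
                 proportions = proportions,
                 internal_branch = internal_branch,
                 star_branch = star_branch,
                 background_mean = background_mean,
                 background_scale = background_scale,
                 n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

# caterpillar newick for one leaf group; every tip and internal edge
# carries a drawn length (the group's stem is added by the caller)
group_newick <- function(labels, tip_lens, node_lens) {
  m <- length(labels)
  if (m == 1L) return(labels)
  s <- sprintf("%s:%.6f", labels[1L], tip_lens[1L])
  for (i in 2:m) {
    s <- sprintf("(%s,%s:%.6f)", s, labels[i], tip_lens[i])
    if (i < m) s <- sprintf("%s:%.6f", s, node_lens[i])
  }
  s
}

#' The three resolutions of the contested node
#'
#' Builds trees T1, T2, T3 over identical leaves, identical everywhere
#' except the pairing of groups A and B around the contested internal
#' edge: T1 separates {B,C} (group A sister to the rest, the
#' Ctenophora-sister analog), T2 separates {A,C} (Porifera-sister
#' analog), T3 separates {A,B} (the sponge+ctenophore clade).
#' Background branch lengths are drawn from an exponential
#' distribution (mean \code{background_mean * background_scale}) once
#' and shared, so the trees differ only at the contested edge.
#'
#' @param spec A \code{"mixture_spec"}.
#' @param contested_length Length of the contested edge; defaults to
#'   \code{spec$internal_branch}.
#' @param reseed If \code{TRUE} (default) the RNG is seeded from
#'   \code{spec$seed} so standalone calls are reproducible; internal
#'   callers that manage the stream themselves pass \code{FALSE}.
#' @return Named list of three unrooted \code{phylo} trees.
#' @export
make_topologies <- function(spec, contested_length = spec$internal_branch,
                            reseed = TRUE) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (reseed) set.seed(spec$seed)
  mean_bl <- spec$background_mean * spec$background_scale
  groups <- c("A", "B", "C", "O")
  subs <- character(4L); names(subs) <- groups
  stems <- numeric(4L); names(stems) <- groups
  for (g in groups) {
    m <- spec$clade_sizes[g]
    labels <- paste0(g, seq_len(m))
    tip_lens <- stats::rexp(m, rate = 1 / mean_bl)
    node_lens <- stats::rexp(m, rate = 1 / mean_bl)
    subs[g] <- group_newick(labels, tip_lens, node_lens)
    stems[g] <- stats::rexp(1L, rate = 1 / mean_bl)
  }
  arm <- function(g) sprintf("%s:%.6f", subs[g], stems[g])
  pairings <- list(T1 = c("B", "C"), T2 = c("A", "C"), T3 = c("A", "B"))
  trees <- lapply(pairings, function(p) {
    rest <- setdiff(groups, p)
    txt <- sprintf("(%s,%s,(%s,%s):%.8f);", arm(rest[1L]), arm(rest[2L]),
                   arm(p[1L]), arm(p[2L]), contested_length)
    ape::read.tree(text = txt)
  })
  for (i in seq_along(trees)) attr(trees[[i]], "name") <- names(pairings)[i]
  trees
}

#' Simulate alignment sites along a tree
#'
#' Forward simulation: the root state is drawn from the model's
#' stationary frequencies, a Gamma rate category is drawn per site,
#' and states propagate edge by edge with the model's transition
#' matrices. Uses the current RNG stream.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param model An \code{aa_model}.
#' @param n Number of sites.
#' @return Character matrix (taxa x n) of residues.
#' @export
simulate_sites <- function(tree, model, n) {
  n <- as.integer(n)
  tree <- stats::reorder(tree, "cladewise")   # parent precedes child
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  K <- model$k
  rates <- discrete_gamma_rates(model$alpha, K)
  cat_of <- sample.int(K, n, replace = TRUE)
  states <- matrix(NA_integer_, nnode, n)
  root <- tree$edge[1L, 1L]
  states[root, ] <- sample.int(20L, n, replace = TRUE, prob = model$freq)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    for (k in seq_len(K)) {
      P <- pmat(model, tree$edge.length[e], rates[k])
      for (s in unique(states[p, cat_of == k])) {
        idx <- which(cat_of == k & states[p, ] == s)
        states[c, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                     prob = P[s, ])
      }
    }
  }
  out <- matrix(aa_states()[states[seq_len(ntip), , drop = FALSE]],
                ntip, n, dimnames = list(tree$tip.label, NULL))
  out
}

#' Simulate a planted-signal supermatrix
#'
#' Concatenates sites simulated under the three resolutions and the
#' star-like background in spec proportions, shuffles the column
#' order, and returns the ground-truth class of every site.
#'
#' @param spec A \code{"mixture_spec"}.
#' @param model An \code{aa_model} used for simulation; defaults to
#'   LG frequencies with Gamma shape 1 over 4 categories.
#' @return List with \code{alignment} (an \code{aa_alignment}),
#'   \code{truth} (data frame: site, true_tree with values
#'   T1/T2/T3/star), \code{trees} (the three signal topologies),
#'   \code{model} and \code{spec}.
#' @export
simulate_mixture <- function(spec = mixture_spec(), model = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (is.null(model)) model <- build_model("lg", alpha = 1, k = 4L)
  set.seed(spec$seed)
  trees <- make_topologies(spec, reseed = FALSE)
  cluster <- c(paste0("B", seq_len(spec$clade_sizes["B"])),
               paste0("C", seq_len(spec$clade_sizes["C"])))
  star <- make_star_analog(trees$T1, spec$star_branch, cluster)
  n <- spec$n_sites
  n_sig <- vapply(spec$proportions, function(p) as.integer(round(p * n)), 0L)
  n_star <- n - sum(n_sig)
  if (n_star < 0L) stop("signal proportions exceed the site budget")
  taxa <- sort(trees$T1$tip.label)   # canonical row order across blocks
  blocks <- list()
  labels <- character(0)
  for (t in c("T1", "T2", "T3")) {
    if (n_sig[t] > 0L) {
      blocks[[t]] <- simulate_sites(trees[[t]], model, n_sig[t])[taxa, ,
                                                                 drop = FALSE]
      labels <- c(labels, rep(t, n_sig[t]))
    }
  }
  if (n_star > 0L) {
    blocks[["star"]] <- simulate_sites(star, model, n_star)[taxa, ,
                                                            drop = FALSE]
    labels <- c(labels, rep("star", n_star))
  }
  mat <- do.call(cbind, blocks)
  ord <- sample.int(n)
  aln <- aa_alignment(mat[, ord, drop = FALSE])
  list(alignment = aln,
       truth = data.frame(site = seq_len(n), true_tree = labels[ord]),
       trees = trees, model = model, spec = spec)
}

# same tree with the contested internal edge (the edge whose child
# subtends exactly `cluster`) collapsed to star_branch
make_star_analog <- function(tree, star_branch, cluster) {
  po <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(po)
  below <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- po$tip.label[i]
  hit <- NA_integer_
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; c <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
    if (c > ntip && setequal(below[[c]], cluster)) hit <- e
  }
  if (is.na(hit)) stop("contested edge not found")
  po$edge.length[hit] <- star_branch
  po
}

#' Write the canonical test fixtures
#'
#' Produces the small plain-text fixtures used by the test-suite and
#' documentation: a quartet alignment (FASTA) with its three candidate
#' topologies (newick), a 12-taxon mixture alignment (relaxed PHYLIP)
#' with ground truth, a per-site log-likelihood file, a partition
#' file, and a reference protein-length table. Deterministic for a
#' given seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_sites Sites in the small mixture fixture.
#' @return Invisibly, named list of the written paths.
#' @export
fixture_suite <- function(out_dir, seed = 42L, n_sites = 400L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  # quartet
  qspec <- mixture_spec(clade_sizes = c(A = 1L, B = 1L, C = 1L, O = 1L),
                        proportions = c(0.1, 0.1, 0.1),
                        n_sites = 60L, seed = seed)
  qsim <- simulate_mixture(qspec)
  write_alignment(qsim$alignment, p("quartet.fasta"), "fasta")
  for (t in names(qsim$trees)) write_newick(qsim$trees[[t]], p(paste0("quartet_", t, ".nwk")))
  # 12-taxon mixture
  mspec <- mixture_spec(n_sites = n_sites, seed = seed)
  msim <- simulate_mixture(mspec)
  write_alignment(msim$alignment, p("mixture12.phy"), "phylip")
  utils::write.table(msim$truth, p("mixture12_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (t in names(msim$trees)) write_newick(msim$trees[[t]], p(paste0("mixture12_", t, ".nwk")))
  # per-site lnL file for the quartet under fixed parameters
  model <- build_model("lg", alpha = 1)
  lnl <- t(vapply(qsim$trees, function(tr)
    tree_loglik(tr, model, qsim$alignment, per_site = TRUE)$site_lnl,
    numeric(qsim$alignment$n_sites)))
  write_persite(sitewise_table(lnl, names(qsim$trees)), p("quartet_persite.txt"))
  # partitions and reference lengths for the mixture
  half <- n_sites %/% 2L
  writeLines(c(sprintf("LG, gene1 = 1-%d", half),
               sprintf("LG, gene2 = %d-%d", half + 1L, n_sites)),
             p("mixture12_partitions.txt"))
  writeLines(c("gene\tlength",
               sprintf("gene1\t%d", as.integer(half * 1.2)),
               sprintf("gene2\t%d", as.integer((n_sites - half) * 1.2))),
             p("mixture12_reflengths.tsv"))
  invisible(list(quartet = p("quartet.fasta"),
                 mixture = p("mixture12.phy"),
                 truth = p("mixture12_truth.tsv"),
                 persite = p("quartet_persite.txt"),
                 partitions = p("mixture12_partitions.txt"),
                 ref_lengths = p("mixture12_reflengths.tsv")))
}
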