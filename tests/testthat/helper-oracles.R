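# Independent oracles used across the suite. These deliberately avoid
# the package's pruning recursion: site likelihoods are computed by
# explicit enumeration over internal-node states, and matrix
# exponentials by scaling-and-squaring.

# random reversible model: LG exchangeabilities, random frequencies
random_model <- function(alpha = stats::runif(1, 0.3, 2),
                         k = sample(c(1L, 4L), 1L)) {
  f <- stats::rgamma(20, shape = 2) + 0.05
  f <- f / sum(f)
  mod <- build_model("lg", alpha = alpha, k = k)
  mod$freq <- stats::setNames(f, aa_states())
  qq <- topofilter:::build_q(mod$exch, mod$freq)
  for (nm in names(qq)) mod[[nm]] <- qq[[nm]]
  mod
}

# matrix exponential by scaling and squaring (series), independent of
# the model's eigendecomposition
expm_oracle <- function(M, order = 18L) {
  n <- nrow(M)
  s <- max(0L, ceiling(log2(max(1e-300, norm(M, "1")))) + 4L)
  A <- M / 2^s
  P <- diag(n); term <- diag(n)
  for (i in seq_len(order)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# site log-likelihood by brute-force enumeration over internal states,
# for trees with <= 2 internal nodes (any tree of <= 4 leaves)
brute_site_lnl <- function(tree, model, site) {
  tree <- if (ape::Ntip(tree) >= 3L && ape::is.rooted(tree))
    ape::unroot(tree) else tree
  tree <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internals <- (ntip + 1L):nnode
  stopifnot(length(internals) <= 2L)
  root <- ntip + 1L
  rates <- discrete_gamma_rates(model$alpha, model$k)
  states <- match(toupper(site[tree$tip.label]), aa_states())
  lik_cat <- numeric(model$k)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  for (cat in seq_len(model$k)) {
    Ps <- list()
    for (e in seq_len(nrow(tree$edge)))
      Ps[[e]] <- transition_matrix(model, tree$edge.length[e], rates[cat])
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= ntip) states[node] else grid[g, match(node, internals)]
      }
      p <- model$freq[assign_state(root)]
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        sp <- assign_state(tree$edge[e, 1L])
        sc <- assign_state(tree$edge[e, 2L])
        if (is.na(sc)) next       # missing tip integrates to 1
        p <- p * Ps[[e]][sp, sc]
      }
      tot <- tot + p
    }
    lik_cat[cat] <- tot
  }
  log(mean(lik_cat))
}

# quadrature oracle for discrete Gamma band means
gamma_band_means_oracle <- function(alpha, k) {
  bounds <- c(0, stats::qgamma(seq_len(k - 1L) / k, alpha, rate = alpha), Inf)
  vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                     bounds[i], bounds[i + 1L], rel.tol = 1e-10)$value * k
  }, 0)
}

# quartet helpers
quartet_trees <- function(bl = 0.2, internal = 0.2) {
  list(T1 = read_newick(sprintf("((A:%g,O:%g):%g,B:%g,C:%g);", bl, bl,
                                internal, bl, bl)),
       T2 = read_newick(sprintf("((B:%g,O:%g):%g,A:%g,C:%g);", bl, bl,
                                internal, bl, bl)),
       T3 = read_newick(sprintf("((A:%g,B:%g):%g,C:%g,O:%g);", bl, bl,
                                internal, bl, bl)))
}

random_alignment <- function(taxa, nsites, gap_rate = 0) {
  m <- matrix(sample(aa_states(), length(taxa) * nsites, TRUE),
              length(taxa), nsites, dimnames = list(taxa, NULL))
  if (gap_rate > 0)
    m[stats::runif(length(m)) < gap_rate] <- "-"
  aa_alignment(m)
}
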