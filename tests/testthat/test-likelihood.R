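test_that("two-taxon site likelihoods match closed forms", {
  mod <- build_model("lg", alpha = 1, k = 1)
  tr0 <- read_newick("(t1:0,t2:0);")
  expect_equal(site_log_likelihood(tr0, mod, c(t1 = "A", t2 = "A")),
               log(unname(mod$freq["A"])), tolerance = 1e-12)
  tr <- read_newick("(t1:0.1,t2:0.2);")
  P <- transition_matrix(mod, 0.3)
  expect_equal(site_log_likelihood(tr, mod, c(t1 = "A", t2 = "R")),
               log(unname(mod$freq["A"] * P["A", "R"])), tolerance = 1e-10)
  expect_error(site_log_likelihood(tr, mod, c(t1 = "A")), "t2")
  expect_warning(v <- site_log_likelihood(tr, mod, c(t1 = "-", t2 = "X")),
                 "missing in all")
  expect_equal(v, 0)
})

test_that("pruning equals brute-force enumeration on trees of <= 4 leaves", {
  set.seed(101)
  trees <- list(read_newick("(t1:0.2,t2:0.35);"),
                read_newick("(t1:0.15,t2:0.3,t3:0.08);"),
                read_newick("((t1:0.2,t2:0.1):0.12,t3:0.3,t4:0.25);"),
                read_newick("((t1:0.2,t3:0.1):0.3,t2:0.02,t4:0.6);"))
  for (tr in trees) {
    taxa <- tr$tip.label
    mod <- random_model()
    for (i in 1:8) {
      site <- sample(c(aa_states(), "-"), length(taxa), TRUE,
                     prob = c(rep(1, 20), 3))
      names(site) <- taxa
      if (all(site == "-")) next
      got <- suppressWarnings(site_log_likelihood(tr, mod, site))
      want <- brute_site_lnl(tr, mod, site)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("site likelihoods conserve probability over all patterns", {
  mod1 <- build_model("lg", alpha = 1, k = 1)
  tr2 <- read_newick("(t1:0.2,t2:0.4);")
  pats2 <- as.matrix(expand.grid(aa_states(), aa_states(),
                                 stringsAsFactors = FALSE))
  aln2 <- aa_alignment(t(matrix(pats2, ncol = 2,
                                dimnames = list(NULL, c("t1", "t2")))))
  res2 <- tree_loglik(tr2, mod1, aln2, per_site = TRUE)
  expect_equal(sum(exp(res2$site_lnl)), 1, tolerance = 1e-8)

  mod4 <- build_model("lg", alpha = 0.6, k = 4)
  tr3 <- read_newick("(t1:0.15,t2:0.35,t3:0.6);")
  pats3 <- as.matrix(expand.grid(aa_states(), aa_states(), aa_states(),
                                 stringsAsFactors = FALSE))
  m3 <- t(pats3); rownames(m3) <- c("t1", "t2", "t3")
  res3 <- tree_loglik(tr3, mod4, aa_alignment(m3), per_site = TRUE)
  expect_equal(sum(exp(res3$site_lnl)), 1, tolerance = 1e-6)
})

test_that("per-site likelihoods are invariant to rerooting and taxon order", {
  set.seed(21)
  tr <- ape::unroot(ape::rtree(7))
  aln <- random_alignment(tr$tip.label, 40, gap_rate = 0.1)
  mod <- build_model("empirical", aln, alpha = 0.8)
  base <- tree_loglik(tr, mod, aln, per_site = TRUE)$site_lnl
  for (node in c(2L, 5L)) {
    rr <- ape::root(tr, node = ape::Ntip(tr) + node, resolve.root = TRUE)
    expect_equal(tree_loglik(rr, mod, aln, per_site = TRUE)$site_lnl, base,
                 tolerance = 1e-9)
  }
  perm <- aa_alignment(aln$mat[sample(nrow(aln$mat)), , drop = FALSE])
  expect_equal(tree_loglik(tr, mod, perm, per_site = TRUE)$site_lnl, base,
               tolerance = 1e-12)
})

test_that("totals match an independent pruning implementation", {
  set.seed(31)
  tr <- ape::unroot(ape::rtree(6))
  m <- matrix(sample(aa_states(), 6 * 80, TRUE), 6, 80,
              dimnames = list(tr$tip.label, NULL))
  m[sample(length(m), 40)] <- "-"
  aln <- aa_alignment(m)
  mod <- build_model("empirical", aln, alpha = 0.9, k = 4)
  fit <- phangorn::pml(tr, phangorn::phyDat(m, type = "AA"), model = "LG",
                       bf = unname(mod$freq), k = 4, shape = 0.9)
  expect_equal(tree_loglik(tr, mod, aln), as.numeric(stats::logLik(fit)),
               tolerance = 1e-8)
})

test_that("branch-length optimization matches a direct likelihood scan", {
  # 2-taxon alignment: 100 identical + 10 differing sites; only the
  # total path length is identifiable
  set.seed(41)
  mod <- build_model("lg", alpha = 1, k = 1)
  m <- cbind(matrix("A", 2, 100), rbind(rep("A", 10), rep("R", 10)))
  rownames(m) <- c("t1", "t2")
  aln <- aa_alignment(m)
  f <- function(t) {
    P <- transition_matrix(mod, t)
    100 * log(mod$freq["A"] * P["A", "A"]) +
      10 * log(mod$freq["A"] * P["A", "R"])
  }
  scan <- stats::optimize(f, c(1e-6, 5), maximum = TRUE)
  fit <- optimize_tree(read_newick("(t1:0.05,t2:0.05);"), mod, aln,
                       optimize_alpha = FALSE)
  total <- sum(fit$tree$edge.length)
  expect_equal(total, scan$maximum, tolerance = 0.05 * scan$maximum)
  expect_equal(fit$logLik, scan$objective, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("optimization is a fixed point and never decreases the likelihood", {
  set.seed(51)
  spec <- mixture_spec(clade_sizes = c(A = 2, B = 1, C = 2, O = 1),
                       proportions = c(0, 0, 0), n_sites = 800, seed = 51)
  sim <- simulate_mixture(spec)
  mod <- build_model("empirical", sim$alignment, alpha = 1)
  fit <- optimize_tree(sim$trees$T1, mod, sim$alignment)
  expect_gte(fit$logLik, tree_loglik(sim$trees$T1, mod, sim$alignment))
  mod2 <- mod; mod2$alpha <- fit$alpha
  fit2 <- optimize_tree(fit$tree, mod2, sim$alignment)
  expect_lt(abs(fit2$logLik - fit$logLik), 1e-3)
})

test_that("recovered branch lengths are close to simulation truth", {
  set.seed(61)
  spec <- mixture_spec(clade_sizes = c(A = 2, B = 1, C = 2, O = 1),
                       proportions = c(1, 0, 0), internal_branch = 0.3,
                       n_sites = 5000, seed = 61)
  sim <- simulate_mixture(spec)
  truth <- stats::reorder(ape::unroot(sim$trees$T1), "postorder")
  fit <- optimize_tree(sim$trees$T1,
                       build_model("empirical", sim$alignment, alpha = 1),
                       sim$alignment)
  est <- fit$tree$edge.length
  keep <- truth$edge.length > 0.02    # short edges carry little signal
  rel <- abs(est[keep] - truth$edge.length[keep]) / truth$edge.length[keep]
  expect_lt(mean(rel), 0.15)
})

test_that("per-site tables are consistent with totals and topology-blind sites", {
  set.seed(71)
  trees <- quartet_trees()
  aln <- random_alignment(c("A", "B", "C", "O"), 30)
  aln$mat[, 1] <- "A"   # constant column
  tab <- per_site_table(aln, trees, optimize = FALSE,
                        model = build_model("lg", alpha = 1))
  expect_equal(rowSums(tab$lnl), tab$totals, tolerance = 1e-6,
               ignore_attr = TRUE)
  # a constant site cannot prefer a topology
  expect_lt(max(tab$lnl[, 1]) - min(tab$lnl[, 1]), 1e-6)
  # the same tree twice gives identical rows
  tab2 <- per_site_table(aln, list(X = trees$T1, Y = trees$T1),
                         optimize = FALSE,
                         model = build_model("lg", alpha = 1))
  expect_equal(tab2$lnl["X", ], tab2$lnl["Y", ], tolerance = 1e-12)
  # unequal leaf sets are refused
  bad <- trees
  bad$T3$tip.label[1] <- "ZZ"
  expect_error(per_site_table(aln, bad), "ZZ")
})
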