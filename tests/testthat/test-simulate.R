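test_that("mixture specs validate their inputs", {
  expect_error(mixture_spec(proportions = c(0.5, 0.4, 0.3)), "sum")
  expect_error(mixture_spec(clade_sizes = c(A = 0, B = 1, C = 1, O = 1)))
  spec <- mixture_spec()
  expect_equal(sum(spec$clade_sizes), 12L)
  expect_equal(unname(spec$proportions), c(0.01, 0.008, 0.005))
})

test_that("the three generated topologies differ only at the contested edge", {
  spec <- mixture_spec(clade_sizes = c(A = 3, B = 2, C = 4, O = 2), seed = 5)
  trees <- make_topologies(spec)
  n <- sum(spec$clade_sizes)
  for (tr in trees) {
    expect_equal(sort(tr$tip.label), sort(trees$T1$tip.label))
    expect_length(bipartitions(tr), n - 3L)
  }
  expect_true(all(rf_matrix(trees)[upper.tri(diag(3))] == 2L))
  # quartet case: the three quartet resolutions
  qt <- make_topologies(mixture_spec(clade_sizes = c(A = 1, B = 1, C = 1,
                                                     O = 1), seed = 5))
  expect_equal(unname(vapply(qt, ape::Ntip, 0L)), c(4L, 4L, 4L))
  expect_true(all(rf_matrix(qt)[upper.tri(diag(3))] == 2L))
})

test_that("forward simulation honors the model", {
  mod <- build_model("lg", alpha = 1, k = 1)
  # zero branch lengths: all leaves share the root state
  tr0 <- read_newick("(a:0,b:0,c:0);")
  set.seed(141)
  m0 <- simulate_sites(tr0, mod, 50)
  expect_true(all(m0["a", ] == m0["b", ] & m0["b", ] == m0["c", ]))

  # two taxa at distance t: mismatch probability 1 - sum pi_a P_aa(t)
  set.seed(142)
  t <- 0.2
  tr2 <- read_newick(sprintf("(a:%g,b:0);", t))
  n <- 50000
  m2 <- simulate_sites(tr2, mod, n)
  P <- transition_matrix(mod, t)
  p_match <- sum(mod$freq * diag(P))
  got <- mean(m2["a", ] != m2["b", ])
  se <- sqrt(p_match * (1 - p_match) / n)
  expect_lt(abs(got - (1 - p_match)), 3 * se)

  # leaf residue frequencies follow the stationary distribution
  freq_hat <- tabulate(match(m2["b", ], aa_states()), 20) / n
  se_f <- sqrt(mod$freq * (1 - mod$freq) / n)
  expect_true(all(abs(freq_hat - mod$freq) < 4 * se_f + 1e-9))
})

test_that("mixtures are deterministic and labelled site by site", {
  spec <- mixture_spec(clade_sizes = c(A = 1, B = 1, C = 1, O = 1),
                       proportions = c(0.1, 0.05, 0.05), n_sites = 200,
                       seed = 7)
  s1 <- simulate_mixture(spec)
  s2 <- simulate_mixture(spec)
  expect_identical(s1$alignment$mat, s2$alignment$mat)
  expect_identical(s1$truth, s2$truth)
  expect_equal(as.vector(table(s1$truth$true_tree)[c("T1", "T2", "T3")]),
               c(20L, 10L, 10L))
  # no signal proportions -> all background
  s0 <- simulate_mixture(mixture_spec(clade_sizes = c(A = 1, B = 1, C = 1,
                                                      O = 1),
                                      proportions = c(0, 0, 0),
                                      n_sites = 50, seed = 8))
  expect_true(all(s0$truth$true_tree == "star"))
})

test_that("strong-site yield grows with the contested branch length", {
  yields <- vapply(c(0.05, 0.3, 1.0), function(b) {
    spec <- mixture_spec(clade_sizes = c(A = 1, B = 1, C = 1, O = 1),
                         proportions = c(0.5, 0, 0), internal_branch = b,
                         n_sites = 300, seed = 17)
    sim <- simulate_mixture(spec)
    tab <- per_site_table(sim$alignment, sim$trees,
                          model = build_model("lg", alpha = 1),
                          optimize = FALSE)
    sum(classify_sites(tab, 0.5)$is_strong)
  }, 0)
  expect_true(all(diff(yields) >= 0))
  expect_gt(yields[3], yields[1])
})

test_that("the fixture suite writes a consistent, reproducible set", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  f1 <- fixture_suite(d1, seed = 42, n_sites = 120)
  f2 <- fixture_suite(d2, seed = 42, n_sites = 120)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), label = nm)
  aln <- read_alignment(f1$quartet, "fasta")
  tab <- read_persite(f1$persite)
  expect_equal(tab$n_sites, n_sites(aln))
  mix <- read_alignment(f1$mixture, "phylip")
  expect_equal(n_sites(mix), 120L)
  pm <- read_partitions(f1$partitions)
  expect_equal(max(pm$end), 120L)
})
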