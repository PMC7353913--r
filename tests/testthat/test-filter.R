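make_records <- function(dlnl, best, threshold = 0.5) {
  rec <- data.frame(site = seq_along(dlnl), best_tree = best, dlnl = dlnl,
                    tie = dlnl == 0, is_strong = dlnl >= threshold & dlnl > 0,
                    shen = NA_real_)
  attr(rec, "threshold") <- threshold
  attr(rec, "tree_names") <- c("T1", "T2", "T3")
  class(rec) <- c("site_strength_df", "data.frame")
  rec
}

test_that("removal targets strong sites of the favored topologies only", {
  rec <- make_records(c(0.8, 0.6, 0.2), c("T1", "T3", "T1"))
  expect_equal(select_removals(rec, c("T1", "T2")), 1L)
  expect_equal(select_removals(rec, c("T1", "T2", "T3")), c(1L, 2L))
  expect_equal(select_removals(make_records(rep(0, 3), rep("T1", 3)), "T1"),
               integer(0))
  expect_error(select_removals(rec, "T9"), "unknown")
  expect_error(select_removals(rec, character(0)), "non-empty")
})

test_that("filtering removes columns and reports consistent counts", {
  aln <- aa_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIK-"))
  res <- apply_filter(aln, c(2, 5))
  expect_equal(n_sites(res$alignment), 8L)
  expect_equal(res$report$removed_fraction, 0.2)
  expect_equal(res$report$n_removed + res$report$n_kept, res$report$n_total)
  expect_equal(unname(res$alignment$mat["a", 1:3]), c("A", "D", "E"))

  # identity and degenerate cases
  none <- apply_filter(aln, integer(0))
  expect_identical(none$alignment$mat, aln$mat)
  expect_equal(none$report$removed_fraction, 0)
  expect_error(apply_filter(aln, 1:10), "every site")
  expect_error(apply_filter(aln, 11), "out of range")

  # kept columns are bit-identical to the input
  rec <- make_records(c(0.9, 0, 0.7, 0, 0, 0, 0, 0, 0, 0.6),
                      c("T1", "T1", "T3", rep("T1", 6), "T2"))
  rem <- select_removals(rec, c("T1", "T2"))
  expect_equal(rem, c(1L, 10L))
  filt <- apply_filter(aln, rem, rec)
  kept_src <- setdiff(1:10, rem)
  expect_identical(filt$alignment$mat, aln$mat[, kept_src])
  expect_equal(filt$report$removed_by_tree, list(T1 = 1L, T2 = 1L))
})

test_that("removed sites are attributed to genes, binomially for random removal", {
  pm <- partition_map(data.frame(gene = c("g1", "g2"),
                                 start = c(1, 6), end = c(5, 10)))
  got <- attribute_to_genes(c(2, 3, 9), pm, 10)
  expect_equal(got, list(g1 = 2L, g2 = 1L))
  expect_equal(attribute_to_genes(c(2, 3, 11), pm, 12)$unpartitioned, 1L)

  set.seed(91)
  pm2 <- partition_map(data.frame(gene = c("a", "b"),
                                  start = c(1, 1001), end = c(1000, 2000)))
  rem <- sample(2000, 1000)
  counts <- attribute_to_genes(rem, pm2, 2000)
  # hypergeometric 99.9% bounds around 500
  expect_true(abs(counts$a - 500) < 60)
})

test_that("fixed-parameter filtering is exactly idempotent", {
  set.seed(92)
  trees <- quartet_trees(internal = 0.4)
  spec <- mixture_spec(clade_sizes = c(A = 1, B = 1, C = 1, O = 1),
                       proportions = c(0.2, 0.1, 0.1), n_sites = 300,
                       seed = 92)
  sim <- simulate_mixture(spec)
  mod <- build_model("lg", alpha = 1)
  tab <- per_site_table(sim$alignment, sim$trees, model = mod,
                        optimize = FALSE)
  rec <- classify_sites(tab, 0.5)
  rem <- select_removals(rec, c("T1", "T2"))
  filt <- apply_filter(sim$alignment, rem)$alignment
  # re-score the filtered matrix with the same fixed parameters
  tab2 <- per_site_table(filt, sim$trees, model = mod, optimize = FALSE)
  rec2 <- classify_sites(tab2, 0.5)
  expect_equal(select_removals(rec2, c("T1", "T2")), integer(0))
})

test_that("comparing a matrix with itself cannot flip the winner", {
  set.seed(93)
  spec <- mixture_spec(clade_sizes = c(A = 1, B = 1, C = 1, O = 1),
                       proportions = c(0.3, 0, 0), n_sites = 150, seed = 93)
  sim <- simulate_mixture(spec)
  flip <- evaluate_flip(sim$alignment, sim$alignment, sim$trees,
                        reoptimize = FALSE,
                        model = build_model("lg", alpha = 1))
  expect_equal(flip$winner_before, flip$winner_after)
  expect_false(flip$flipped)
  expect_equal(flip$totals_before, flip$totals_after, tolerance = 1e-12)
  expect_equal(unname(flip$margins_before[flip$winner_before]), 0)
})
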