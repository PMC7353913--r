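test_that("occupancy statistics match direct counting", {
  aln <- aa_alignment(c(t1 = "ACDE", t2 = "AC--"))
  pm <- partition_map(data.frame(gene = c("g1", "g2"),
                                 start = c(1, 3), end = c(2, 4)))
  cov <- coverage_stats(aln, pm)
  expect_equal(cov$coverage_by_gene, 0.75)   # t2 absent from g2
  expect_equal(cov$coverage_by_site, 6 / 8)
  expect_identical(cov$per_taxon_gene_presence["t2", ],
                   c(g1 = TRUE, g2 = FALSE))

  # fully occupied matrix
  full <- aa_alignment(c(a = "AC", b = "DE"))
  pm1 <- partition_map(data.frame(gene = "g", start = 1, end = 2))
  cfull <- coverage_stats(full, pm1)
  expect_equal(cfull$coverage_by_gene, 1)
  expect_equal(cfull$coverage_by_site, 1)

  # integer identity: by-site coverage times cells = non-missing count
  set.seed(111)
  big <- random_alignment(paste0("s", 1:10), 1000, gap_rate = 0.3)
  cb <- coverage_stats(big, partition_map(data.frame(gene = "g", start = 1,
                                                     end = 1000)))
  n_present <- sum(!is.na(encode_alignment(big)))
  expect_equal(cb$coverage_by_site * 10 * 1000, n_present)
  expect_equal(cb$coverage_by_site, 0.7, tolerance = 0.02)
})

test_that("kept fractions follow reference protein lengths", {
  # 3 genes, reference row ungapped in 86% of each gene's columns
  ref <- c(rep(c(rep("A", 86), rep("-", 14)), 1),
           rep(c(rep("C", 86), rep("-", 14)), 2),
           rep(c(rep("D", 86), rep("-", 14)), 1))
  other <- rep("G", 400)
  aln <- aa_alignment(rbind(human = ref, sp2 = other))
  pm <- partition_map(data.frame(gene = c("g1", "g2", "g3"),
                                 start = c(1, 101, 301), end = c(100, 300, 400)))
  kf <- kept_fraction(aln, pm, "human",
                      c(g1 = 100, g2 = 200, g3 = 100))
  expect_equal(kf$per_gene$kept_fraction, c(0.86, 0.86, 0.86))
  expect_equal(kf$total_kept_percent, 86.0)
  # total is the length-weighted mean of per-gene fractions
  expect_equal(kf$total_kept_percent / 100,
               sum(kf$per_gene$kept_fraction * kf$per_gene$ref_length) /
                 sum(kf$per_gene$ref_length))

  # absent ortholog flagged; missing reference length is an error
  gapped <- aa_alignment(rbind(human = c("-", "-", "A"), sp2 = c("A", "A", "A")))
  pm2 <- partition_map(data.frame(gene = c("gA", "gB"), start = c(1, 3),
                                  end = c(2, 3)))
  kf2 <- kept_fraction(gapped, pm2, "human", c(gA = 10, gB = 10))
  expect_true(kf2$per_gene$absent[1])
  expect_equal(kf2$per_gene$kept_fraction[1], 0)
  expect_error(kept_fraction(gapped, pm2, "human", c(gA = 10)), "gB")
})

test_that("pairwise differences honor the gap convention", {
  aln <- aa_alignment(c(x = "AAAA", y = "AAAR"))
  expect_equal(pairwise_difference(aln, "x", "y", "both-present"), 25)
  expect_equal(pairwise_difference(aln, "x", "x") |> suppressMessages(), 0)

  gappy <- aa_alignment(c(x = "AA-A-", y = "AR-AA"))
  # all-columns: mismatch, missing-vs-missing match, residue-vs-missing diff
  expect_equal(pairwise_difference(gappy, "x", "y", "all-columns"), 40)
  expect_equal(pairwise_difference(gappy, "x", "y", "both-present"), 1 / 3 * 100)
  # both-present mode ignores appended gap columns; all-columns does not
  ext <- aa_alignment(c(x = "AA-A--", y = "AR-AA-"))
  expect_equal(pairwise_difference(ext, "x", "y", "both-present"),
               pairwise_difference(gappy, "x", "y", "both-present"))

  # binomial check at the divergence scale reported for distant taxa
  set.seed(121)
  n <- 20000
  a <- sample(aa_states(), n, TRUE)
  b <- a
  flip <- stats::runif(n) < 0.14
  b[flip] <- vapply(b[flip], function(s) sample(setdiff(aa_states(), s), 1), "")
  pair <- aa_alignment(rbind(hs = a, dr = b))
  expect_equal(pairwise_difference(pair, "hs", "dr", "all-columns"), 14,
               tolerance = 0.05)
})

test_that("gene-set overlaps match brute-force membership tabulation", {
  ov <- gene_overlap(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(ov$regions$A, 1L)
  expect_equal(ov$regions$B, 1L)
  expect_equal(ov$regions$`A&B`, 1L)
  expect_equal(ov$union, 3L)

  dis <- gene_overlap(list(A = 1:3, B = 4:6))
  expect_equal(dis$regions$`A&B`, 0L)
  expect_equal(dis$common_all, 0L)

  set.seed(131)
  sets <- list(s1 = sample(1431, 400), s2 = sample(1431, 400),
               s3 = sample(1431, 400))
  ov3 <- gene_overlap(sets)
  ids <- sort(unique(unlist(sets)))
  member <- sapply(sets, function(s) ids %in% s)
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  brute <- table(key)
  for (nm in names(ov3$regions)) {
    want <- if (nm %in% names(brute)) as.integer(brute[[nm]]) else 0L
    expect_equal(ov3$regions[[nm]], want, label = nm)
  }
  expect_equal(ov3$union, length(ids))
  expect_equal(sum(unlist(ov3$regions)), ov3$union)
})
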