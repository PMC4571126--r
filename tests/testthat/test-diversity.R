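test_that("pairwise differences match the hand-counted toy set", {
  aln <- toy_alignment()
  D <- pairwise_diffs(aln)
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0L, 4))
  expect_equal(sort(D[upper.tri(D)]), c(0L, 1L, 1L, 1L, 1L, 2L))

  ident <- dna_alignment(c("ACGT", "ACGT", "ACGT"))
  expect_true(all(pairwise_diffs(ident) == 0L))
  expect_equal(pairwise_diffs(dna_alignment(c("ACGT", "ACGA")))[1, 2], 1L)
})

test_that("sites with N are skipped pairwise", {
  aln <- dna_alignment(c("ACGT", "NCGA"))
  D <- pairwise_diffs(aln)
  expect_equal(D[1, 2], 1L)  # only site 4 differs among the 3 comparable sites
  expect_equal(attr(D, "comparable")[1, 2], 3L)
  expect_equal(nuc_diversity(aln), 1 / 3)
})

test_that("nucleotide diversity follows the mean-pairwise definition", {
  expect_equal(nuc_diversity(toy_alignment()), 0.10)
  expect_equal(nuc_diversity(dna_alignment(c("ACGT", "ACGA"))), 0.25)
  expect_equal(nuc_diversity(dna_alignment(c("ACGT", "ACGT"))), 0)
  expect_error(nuc_diversity(dna_alignment("ACGT")), "n >= 2")

  # pi * k equals the mean of the pairwise difference matrix when N-free
  set.seed(5)
  sim <- sim_alignment(15, 400, theta0 = 2, theta1 = 2, tau = 0)
  D <- pairwise_diffs(sim$alignment)
  expect_equal(nuc_diversity(sim$alignment) * 400,
               mean(D[upper.tri(D)]))
})

test_that("haplotype diversity uses the n/(n-1) sample correction", {
  expect_equal(hap_diversity(c(2, 2)), 4 / 3 * 0.5)
  expect_equal(hap_diversity(c(5)), 0)
  expect_equal(hap_diversity(rep(1, 10)), 1)  # h = n forces Hd = 1 exactly
  expect_error(hap_diversity(c(1)), "n >= 2")
})

test_that("K2P distance matches its closed form and ape's implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  expect_equal(k2p_distance("ACGT", "GCGT"), -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(k2p_distance("ACGT", "CCGT"),        # P = 0, Q = 1/4
               -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
  expect_error(k2p_distance("AAAA", "GGGG"), "saturation")

  set.seed(9)
  sim <- sim_alignment(10, 600, theta0 = 3, theta1 = 3, tau = 0)
  ours <- k2p_matrix(sim$alignment)
  bin <- ape::as.DNAbin(tolower(sim$alignment$seqs))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(ref[rownames(ours), colnames(ours)]),
               tolerance = 1e-10, ignore_attr = TRUE)

  # correction can only inflate the p-distance
  p <- pairwise_diffs(sim$alignment)[1, 2] / 600
  expect_gte(ours[1, 2], p)
})

test_that("mismatch histograms conserve the pair total", {
  mm <- mismatch(toy_alignment())
  expect_equal(mm$counts, c(1, 4, 1))
  expect_equal(sum(mm$counts), choose(4, 2))

  ident <- dna_alignment(c("AC", "AC", "AC", "AC", "AC"))
  mmi <- mismatch(ident)
  expect_equal(mmi$counts, 10)
  expect_equal(mmi$classes, 0L)

  set.seed(3)
  sim <- sim_alignment(20, 500, theta0 = 1, theta1 = 100, tau = 4)
  expect_equal(sum(mismatch(sim$alignment)$counts), choose(20, 2))
})

test_that("a strong star expansion yields a unimodal mismatch near tau", {
  set.seed(21)
  sim <- sim_alignment(60, 3000, theta0 = 0.01, theta1 = 1e6, tau = 5,
                       model = "infinite_sites")
  mm <- mismatch(sim$alignment)
  mode_class <- mm$classes[which.max(mm$counts)]
  expect_lt(abs(mode_class - 5), 3)
  expect_lt(abs(mismatch_distribution(mm$counts, n = 60)$counts |>
                  (\(x) sum((seq_along(x) - 1) * x) / sum(x))() - 5), 1)
})

test_that("diversity summary collects the per-group statistics", {
  ds <- diversity_summary(toy_alignment())
  expect_equal(ds$n, 4L)
  expect_equal(ds$S, 2L)
  expect_equal(ds$h, 3L)
  expect_equal(ds$pi, 0.10)
  expect_equal(ds$mean_pairwise, 1.0)
  expect_equal(ds$hd, 4 / 3 * (1 - (2^2 + 1 + 1) / 16))
})
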