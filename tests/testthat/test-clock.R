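test_that("UPGMA heights are half the cluster distances", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma_tree(d2)
  expect_equal(max(attr(tr2, "heights")), 0.1)

  d3 <- matrix(c(0, 0.1, 0.4,
                 0.1, 0, 0.4,
                 0.4, 0.4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma_tree(d3)
  h <- sort(unique(round(attr(tr3, "heights"), 10)))
  expect_equal(h, c(0, 0.05, 0.2))
  # (A,B) must be the cherry
  expect_true(ape::is.monophyletic(tr3, c("A", "B")))
  expect_true(ape::is.ultrametric(tr3, tol = 1e-10))

  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("identical taxa collapse to a zero-height tree deterministically", {
  d <- matrix(0, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  tr <- upgma_tree(d)
  expect_equal(unname(attr(tr, "heights")), rep(0, 5))
  # lexicographic tie-break: repeated calls give identical topology
  tr2 <- upgma_tree(d)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("UPGMA trees are ultrametric with parent above child", {
  set.seed(42)
  sim <- sim_alignment(12, 500, theta0 = 3, theta1 = 3, tau = 0)
  tr <- upgma_tree(k2p_matrix(sim$alignment))
  expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  depths <- ape::node.depth.edgelength(tr)
  heights <- max(depths) - depths
  for (e in seq_len(nrow(tr$edge))) {
    expect_gte(heights[tr$edge[e, 1]], heights[tr$edge[e, 2]] - 1e-12)
  }
})

test_that("height-to-time conversion is linear with the expected scale", {
  expect_equal(height_to_time(0, 17.1), 0)
  expect_equal(height_to_time(0.0293 / 2, 17.1), 85672.5, tolerance = 1e-4)
  expect_equal(height_to_time(0.02, 10), 2 * height_to_time(0.01, 10))
  expect_equal(height_to_time(0.02, 20), height_to_time(0.02, 10) / 2)
  expect_error(height_to_time(0.1, 0), "> 0")
})

test_that("two-population split times are recovered from simulated data", {
  # two demes simulated separately from root sequences a known distance apart:
  # with net divergence the within-deme coalescent depth cancels on average
  set.seed(77)
  k <- 2000
  mu_pct <- 10                       # %/site/myr
  t_true <- 100000                   # years
  m <- round(2 * (mu_pct * 1e-8) * k * t_true)  # expected root-to-root diffs
  root <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  root2 <- root
  flip <- sample(k, m)
  root2[flip] <- vapply(root[flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  t_hat <- replicate(8, {
    a <- sim_alignment(20, k, 0.5, 0.5, 0, root_seq = root)$alignment
    b <- sim_alignment(20, k, 0.5, 0.5, 0, root_seq = root2)$alignment
    both <- dna_alignment(rbind(a$seqs, b$seqs),
                          ids = c(paste0("a", 1:20), paste0("b", 1:20)))
    grp <- stats::setNames(rep(c("A", "B"), each = 20), both$ids)
    date_groups(both, grp, mu_pct, net = TRUE)$t_years
  })
  expect_lt(abs(mean(t_hat) - t_true) / t_true, 0.30)
})
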