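test_that("simulation is deterministic and replayable", {
  s1 <- sim_alignment(12, 300, theta0 = 1, theta1 = 200, tau = 3, seed = 11)
  s2 <- sim_alignment(12, 300, theta0 = 1, theta1 = 200, tau = 3, seed = 11)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(replay_sim(s1$truth)$alignment$seqs, s1$alignment$seqs)

  # identical FASTA bytes
  p1 <- tempfile(); p2 <- tempfile()
  write_fasta(s1$alignment, p1)
  write_fasta(s2$alignment, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  t1 <- sim_genealogy(8, 1, 1, 0, seed = 4)
  t2 <- sim_genealogy(8, 1, 1, 0, seed = 4)
  expect_identical(t1$edge, t2$edge)
  expect_identical(t1$edge.length, t2$edge.length)
})

test_that("genealogies are valid ultrametric coalescent trees", {
  tr <- sim_genealogy(15, theta0 = 0.5, theta1 = 50, tau = 2, seed = 2)
  expect_s3_class(tr, "phylo")
  expect_equal(tr$Nnode, 14L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(all(tr$edge.length >= 0))
  expect_error(sim_genealogy(1, 1, 1, 0), ">= 2")
})

test_that("constant-size pairwise path length converges to theta", {
  set.seed(101)
  theta <- 2
  paths <- replicate(10000, {
    h <- expansionclock:::coal_history(2, theta, theta, 0)
    sum(expansionclock:::branch_lengths(h)[1:2])
  })
  expect_lt(abs(mean(paths) - theta) / theta, 0.05)
  expect_lt(abs(mean(paths) - theta), 3 * sd(paths) / sqrt(length(paths)))
})

test_that("strong expansion drives mean mismatch to tau + theta0", {
  set.seed(202)
  mp <- replicate(5000,
    expansionclock:::sim_infsites_stats(2, theta0 = 0, theta1 = 1e6, tau = 5)$mp)
  expect_lt(abs(mean(mp) - 5), 3 * sd(mp) / sqrt(length(mp)))
})

test_that("segregating sites match E[S] = theta * a1(n) under neutrality", {
  set.seed(303)
  n <- 10; theta <- 2
  S <- replicate(5000,
    expansionclock:::sim_infsites_stats(n, theta, theta, 0)$S)
  a1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - theta * a1), 3 * sd(S) / sqrt(length(S)))
})

test_that("degenerate demographies produce monomorphic samples", {
  s <- sim_alignment(6, 100, theta0 = 0, theta1 = 0, tau = 0, seed = 1)
  expect_equal(seg_sites(s$alignment), 0L)
  expect_equal(nuc_diversity(s$alignment), 0)
})

test_that("finite-sites mutations honour the transition bias", {
  set.seed(7)
  s <- sim_alignment(30, 2000, theta0 = 5, theta1 = 5, tau = 0,
                     kappa = 50, model = "k2p")
  # count transitions vs transversions across all pairs
  purine <- c("A", "G")
  m <- s$alignment$seqs
  ts <- 0; tv <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    d <- m[i, ] != m[j, ]
    same_class <- (m[i, ] %in% purine) == (m[j, ] %in% purine)
    ts <- ts + sum(d & same_class)
    tv <- tv + sum(d & !same_class)
  }
  expect_gt(ts / max(tv, 1), 5)  # kappa = 50 => expected ratio ~ 25
  expect_error(sim_alignment(5, 100, 1, 1, 0, kappa = -1), "kappa")
})

test_that("expansion simulations show the star-like negative-D signature", {
  set.seed(404)
  neg <- replicate(200, {
    st <- expansionclock:::sim_infsites_stats(50, theta0 = 1, theta1 = 1000,
                                              tau = 2.7)
    st$S > 0 && tajima_d(50, st$S, st$mp) < 0
  })
  expect_gt(mean(neg), 0.90)
})
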