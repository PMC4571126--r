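test_that("expected mismatch collapses to the equilibrium geometric", {
  # tau = 0: geometric(theta0) regardless of theta1
  f <- expected_mismatch(0, 1, 777, 5)
  expect_equal(as.numeric(f), 0.5^(1:6), tolerance = 1e-14)
  # theta0 = theta1: geometric for any tau
  g <- expected_mismatch(3.7, 2, 2, 10)
  expect_equal(as.numeric(g), 2^(0:10) / 3^(1:11), tolerance = 1e-12)
})

test_that("expected mismatch matches the Poisson*geometric oracle as theta1 -> Inf", {
  for (tau in c(0.5, 3, 8)) {
    for (theta0 in c(0, 0.5, 2)) {
      ours <- expected_mismatch(tau, theta0, 1e12, 30)
      expect_equal(as.numeric(ours), pois_geom_conv(tau, theta0, 30),
                   tolerance = 1e-10)
    }
  }
  # Poisson special case
  expect_equal(expected_mismatch(5, 0, 1e15, 8)[1], exp(-5), tolerance = 1e-10)
})

test_that("expected mismatch normalizes and has the limiting mean tau + theta0", {
  for (tau in c(0, 1, 5)) {
    for (theta0 in c(0, 1)) {
      for (theta1 in c(1, 10, 50)) {
        f <- expected_mismatch(tau, theta0, theta1, 1200)
        expect_gte(sum(f), 1 - 1e-6)
        expect_lte(sum(f), 1 + 1e-9)
      }
    }
  }
  f <- expected_mismatch(3, 0.5, 1e9, 120)
  expect_equal(sum((0:120) * f), 3.5, tolerance = 1e-4)
})

test_that("expected mismatch validates degenerate parameters", {
  expect_error(expected_mismatch(2, 0, 0, 5), "theta1 = 0")
  expect_error(expected_mismatch(-1, 1, 1, 5), ">= 0")
  expect_equal(as.numeric(expected_mismatch(0, 0, 0, 3)), c(1, 0, 0, 0))
})

test_that("raggedness follows the no-padding convention", {
  expect_equal(raggedness(c(0.5, 0.5)), 0)
  expect_equal(raggedness(c(0.8, 0.2)), 0.36)
  expect_equal(raggedness(1), 0)
  expect_error(raggedness(numeric(0)), "empty")
  expect_error(raggedness(c(0.2, 0.2)), "sum to 1")
  mm <- mismatch(toy_alignment())
  expect_equal(raggedness(mm), sum(diff(mm$counts / 6)^2))
})

test_that("noiseless model frequencies are recovered essentially exactly", {
  f_true <- expected_mismatch(3, 0.5, 50, 150)
  fit <- sudden_expansion(1e4 * as.numeric(f_true))
  expect_lt(abs(coef(fit)["tau"] - 3), 0.05)
  expect_lt(fit$ssd, 1e-8)
})

test_that("the model nests the equilibrium geometric", {
  g <- expected_mismatch(0, 2, 2, 40)
  fit <- sudden_expansion(1e4 * as.numeric(g))
  # the fit must do at least as well as any coarse-grid candidate
  expect_lte(fit$ssd, fit$grid_ssd)
  expect_lt(fit$ssd, 1e-10)
})

test_that("fitting validates degenerate observations", {
  expect_error(sudden_expansion(c(10)), "no variation")
  expect_error(sudden_expansion(c(1, 1)), "3 sequence pairs")
})

test_that("fit accessors expose frequencies, residuals and predictions", {
  set.seed(12)
  sim <- sim_alignment(30, 700, theta0 = 0.5, theta1 = 500, tau = 3)
  fit <- sudden_expansion(sim$alignment)
  expect_named(coef(fit), c("tau", "theta0", "theta1"))
  expect_equal(length(fitted(fit)), fit$d + 1)
  expect_equal(residuals(fit), fit$obs_freq - fitted(fit))
  expect_equal(sum(fit$obs_freq), 1)
  pr <- predict(fit, max_class = fit$d + 20)
  expect_equal(length(pr), fit$d + 21)
  expect_equal(as.numeric(pr[seq_len(fit$d + 1)]), fitted(fit),
               tolerance = 1e-12)
  expect_lte(fit$ssd, fit$grid_ssd)
  expect_equal(fit$n, 30)
  expect_equal(fit$k, 700)

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$alignment$n, 30)
})

test_that("goodness-of-fit bootstrap is seed-deterministic", {
  set.seed(13)
  sim <- sim_alignment(25, 600, theta0 = 0.5, theta1 = 500, tau = 3)
  fit <- sudden_expansion(sim$alignment)
  g1 <- gof_test(fit, reps = 100, seed = 77)
  g2 <- gof_test(fit, reps = 100, seed = 77)
  expect_identical(g1$p_ssd, g2$p_ssd)
  expect_identical(g1$p_r, g2$p_r)
  expect_true(g1$p_ssd >= 0 && g1$p_ssd <= 1)
  expect_error(gof_test(fit, reps = 10), ">= 100")
})

test_that("parameter recovery holds at the study scale (small replicate set)", {
  set.seed(14)
  tau_hat <- replicate(15, {
    sim <- sim_alignment(50, 1140, theta0 = 1, theta1 = 1000, tau = 2.7)
    unname(coef(sudden_expansion(sim$alignment))["tau"])
  })
  expect_gt(median(tau_hat), 1.5)
  expect_lt(median(tau_hat), 4.0)
})
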