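#' Expected mismatch distribution under sudden expansion
#'
#' The Rogers-Harpending expectation for the distribution of pairwise
#' differences after an instantaneous expansion from scaled diversity `theta0`
#' to `theta1` at `tau` mutational time units before the present. With the
#' equilibrium geometric `Fhat_j(theta) = theta^j / (theta + 1)^(j + 1)`,
#'
#' `F_i = Fhat_i(theta1) + exp(-tau (theta1 + 1) / theta1) *
#'        sum_{j = 0..i} tau^(i - j) / (i - j)! * (Fhat_j(theta0) - Fhat_j(theta1))`
#'
#' At `tau = 0` (or `theta0 = theta1`) this collapses to the equilibrium
#' geometric; in the limit `theta1 -> Inf` it is the convolution of a
#' Poisson(`tau`) with a geometric(`theta0`), with mean `tau + theta0`.
#'
#' @param tau expansion time in mutational units (>= 0).
#' @param theta0 ancestral scaled diversity (>= 0).
#' @param theta1 current scaled diversity (>= 0; `theta1 = 0` with `tau > 0`
#'   is undefined and raises an error).
#' @param max_class largest difference class to return (>= 0).
#' @return Probability vector over classes `0..max_class` (clipped at 0 within
#'   numerical tolerance); the mass beyond `max_class` is in attribute
#'   `"tail_mass"`.
#' @examples
#' expected_mismatch(0, 1, 50, 3)       # geometric(1): 0.5 0.25 ...
#' expected_mismatch(5, 0, 1e6, 3)[1]   # ~ exp(-5) (Poisson limit)
#' @export
expected_mismatch <- function(tau, theta0, theta1, max_class) {
  if (any(!is.finite(c(tau, theta0, theta1))) ||
      tau < 0 || theta0 < 0 || theta1 < 0) {
    stop("tau, theta0, theta1 must be finite and >= 0")
  }
  if (max_class < 0) stop("max_class must be >= 0")
  if (theta1 == 0 && tau > 0) {
    stop("theta1 = 0 with tau > 0 is undefined (exponent diverges)")
  }
  f <- mismatch_kernel(tau, theta0, theta1, as.integer(max_class))
  attr(f, "tail_mass") <- max(0, 1 - sum(f))
  f
}

# Validation-free expectation kernel shared by the user surface and the
# optimizer hot path (internal).
mismatch_kernel <- function(tau, theta0, theta1, d) {
  if (tau == 0) return(geometric_mismatch(theta0, d))
  g0 <- geometric_mismatch(theta0, d)
  g1 <- geometric_mismatch(theta1, d)
  pois <- stats::dpois(0:d, tau)
  P <- stats::toeplitz(pois)
  P[upper.tri(P)] <- 0
  pmax(as.numeric(g1 + exp(-tau / theta1) * (P %*% (g0 - g1))), 0)
}

# Equilibrium geometric mismatch distribution, computed in log space so that
# arbitrarily large theta cannot overflow (internal).
geometric_mismatch <- function(theta, d) {
  if (theta == 0) return(c(1, rep(0, d)))
  exp((0:d) * (log(theta) - log1p(theta)) - log1p(theta))
}

# Expected mismatch for one tau and vectors of (theta0, theta1), as a
# (d+1) x m matrix; vectorized for the coarse-grid search (internal).
expected_mismatch_grid <- function(tau, theta0, theta1, d) {
  G0 <- vapply(theta0, geometric_mismatch, numeric(d + 1L), d = d)
  G1 <- vapply(theta1, geometric_mismatch, numeric(d + 1L), d = d)
  if (tau == 0) return(G0)
  pv <- stats::dpois(0:d, tau)
  P <- stats::toeplitz(pv)
  P[upper.tri(P)] <- 0
  G1 + (P %*% (G0 - G1)) * rep(exp(-tau / theta1), each = d + 1L)
}

#' Raggedness index
#'
#' Harpending's raggedness statistic `r = sum_{i=1..d} (x_i - x_{i-1})^2` over
#' the relative mismatch frequencies, with no zero-padding beyond the last
#' class (conventions differ; this contract is fixed and documented). Smooth,
#' unimodal (expansion-like) distributions give small `r`.
#'
#' @param x a `"mismatch_distribution"` or a vector of relative frequencies
#'   summing to 1 (tolerance 1e-3).
#' @return The raggedness index (0 for a single class).
#' @examples
#' raggedness(c(0.8, 0.2))  # 0.36
#' @export
raggedness <- function(x) {
  if (inherits(x, "mismatch_distribution")) x <- x$counts / sum(x$counts)
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty frequency vector")
  if (abs(sum(x) - 1) > 1e-3) stop("frequencies must sum to 1")
  if (length(x) == 1L) return(0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares estimation of the expansion parameters `(tau, theta0,
#' theta1)`: minimizes the sum of squared deviations (SSD) between the observed
#' relative mismatch frequencies over classes `0..d` (`d` = largest observed
#' class) and the [expected_mismatch()] probabilities. The optimizer is a
#' deterministic multi-start search: a coarse grid (21 tau values on
#' `[0, 2d]`, 10 theta0 values on `[0, mean]`, 10 log-spaced theta1 values up
#' to 1e5), followed by bounded local refinement (`L-BFGS-B`) from the best
#' grid points. The bounds prevent runaway along the flat theta1 direction.
#'
#' @param x a [dna_alignment()], a `"mismatch_distribution"`, or a numeric
#'   vector of pair counts per difference class.
#' @param ... passed between methods.
#' @return An object of class `"sudden_expansion"` with components
#'   `coefficients` (`tau`, `theta0`, `theta1`), `ssd`, `raggedness` (of the
#'   observed distribution), `observed` (the input distribution), `obs_freq`,
#'   `fitted` (expected probabilities over `0..d`), `n`, `k`, `d`, and
#'   optimizer diagnostics. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`, plus [gof_test()].
#' @examples
#' obs <- round(1225 * expected_mismatch(3, 0.5, 50, 15))
#' fit <- sudden_expansion(obs)
#' coef(fit)["tau"]
#' @export
sudden_expansion <- function(x, ...) UseMethod("sudden_expansion")

#' @rdname sudden_expansion
#' @export
sudden_expansion.dna_alignment <- function(x, ...) {
  obs <- mismatch(x)
  out <- sudden_expansion.mismatch_distribution(obs, ...)
  out$k <- x$k
  out$call <- match.call()
  out
}

#' @rdname sudden_expansion
#' @export
sudden_expansion.mismatch_distribution <- function(x, ...) {
  if (sum(x$counts) < 3) stop("need at least 3 sequence pairs")
  fit <- fit_mismatch(x$counts)
  fit$observed <- x
  fit$n <- x$n
  fit$call <- match.call()
  fit
}

#' @rdname sudden_expansion
#' @export
sudden_expansion.default <- function(x, ...) {
  sudden_expansion.mismatch_distribution(mismatch_distribution(x), ...)
}

# Core least-squares fit on a vector of class counts (internal, deterministic).
fit_mismatch <- function(counts) {
  counts <- as.numeric(counts)
  d <- max(which(counts > 0)) - 1L
  if (d == 0L) stop("no variation: all pairs identical")
  counts <- counts[seq_len(d + 1L)]
  x <- counts / sum(counts)
  mean_obs <- sum((0:d) * x)
  ssd_of <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || p[3] <= 0) return(1e10)
    sum((x - mismatch_kernel(p[1], p[2], p[3], d))^2)
  }
  # coarse grid; tau resolution both on the class range [0, 2d] and on the
  # scale of the observed mean, where the expansion wave actually sits
  taus <- sort(unique(c(seq(0, 2 * d, length.out = 21),
                        seq(0, min(3 * mean_obs, 2 * d), length.out = 15))))
  th0 <- seq(0, max(mean_obs, 1e-3), length.out = 10)
  th1 <- 10^seq(-1, 5, length.out = 10)
  combos <- expand.grid(theta0 = th0, theta1 = th1)
  best <- NULL
  cand <- list()
  for (tv in taus) {
    F <- expected_mismatch_grid(tv, combos$theta0, combos$theta1, d)
    ssd <- colSums((x - F)^2)
    ord <- order(ssd)[1:2]
    for (i in ord) {
      cand[[length(cand) + 1L]] <- list(par = c(tv, combos$theta0[i],
                                                combos$theta1[i]),
                                        ssd = ssd[i])
    }
  }
  grid_ssd <- vapply(cand, `[[`, 0, "ssd")
  grid_best <- min(grid_ssd)
  starts <- cand[order(grid_ssd)[seq_len(min(5L, length(cand)))]]
  # method-of-moments starts: wave near the observed mean over a large or a
  # moderate current size
  th0_mm <- if (x[1] > 0 && x[1] < 1) min(1 / x[1] - 1, mean_obs) else 0.1
  for (st in list(c(max(mean_obs - th0_mm, 0), th0_mm, 1e3),
                  c(mean_obs, 0.05, 1e4),
                  c(which.max(x) - 1L, 0.5, 100))) {
    cand_ssd <- ssd_of(st)
    starts[[length(starts) + 1L]] <- list(par = st, ssd = cand_ssd)
    grid_best <- min(grid_best, cand_ssd)
  }
  lower <- c(0, 0, 1e-6)
  upper <- c(2 * d, max(mean_obs, 1e-3), 1e5)
  best_par <- starts[[1L]]$par
  best_ssd <- starts[[1L]]$ssd
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(pmin(pmax(s$par, lower), upper), ssd_of,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < best_ssd) {
      best_par <- opt$par
      best_ssd <- opt$value
    }
  }
  # derivative-free polish (the box is enforced by the objective's error guard)
  pol <- tryCatch(
    stats::optim(best_par, function(p) {
      if (any(p < lower) || any(p > upper)) return(1e10)
      ssd_of(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best_ssd) {
    best_par <- pol$par
    best_ssd <- pol$value
  }
  fitted <- expected_mismatch(best_par[1], best_par[2], best_par[3], d)
  structure(list(coefficients = c(tau = best_par[1], theta0 = best_par[2],
                                  theta1 = best_par[3]),
                 ssd = best_ssd,
                 raggedness = raggedness(x),
                 obs_freq = x,
                 fitted = as.numeric(fitted),
                 d = d, n = NULL, k = NULL,
                 grid_ssd = grid_best),
            class = "sudden_expansion")
}

#' @export
print.sudden_expansion <- function(x, ...) {
  cat("Sudden-expansion mismatch fit\n")
  cat(sprintf("  tau = %.4g, theta0 = %.4g, theta1 = %.4g\n",
              x$coefficients["tau"], x$coefficients["theta0"],
              x$coefficients["theta1"]))
  cat(sprintf("  SSD = %.4g, raggedness r = %.4g, classes 0..%d\n",
              x$ssd, x$raggedness, x$d))
  invisible(x)
}

#' @export
coef.sudden_expansion <- function(object, ...) object$coefficients

#' @export
fitted.sudden_expansion <- function(object, ...) object$fitted

#' @export
residuals.sudden_expansion <- function(object, ...) {
  object$obs_freq - object$fitted
}

#' Predicted mismatch probabilities from a fit
#'
#' @param object a `"sudden_expansion"` fit.
#' @param max_class largest class (default: observed `d`).
#' @param ... unused.
#' @return Expected probabilities over `0..max_class` at the fitted
#'   parameters.
#' @export
predict.sudden_expansion <- function(object, max_class = object$d, ...) {
  cf <- object$coefficients
  expected_mismatch(cf["tau"], cf["theta0"], cf["theta1"], max_class)
}

#' @export
plot.sudden_expansion <- function(x, main = "Mismatch distribution", ...) {
  mids <- graphics::barplot(x$obs_freq, names.arg = 0:x$d,
                            xlab = "Pairwise differences",
                            ylab = "Relative frequency",
                            col = "grey85", border = "grey40",
                            main = main, ...)
  graphics::lines(mids, x$fitted, lwd = 2)
  graphics::points(mids, x$fitted, pch = 16, cex = 0.7)
  invisible(x)
}

#' Simulate alignments from a fitted expansion model
#'
#' Parametric simulation under the fitted `(tau, theta0, theta1)` via the
#' coalescent engine ([sim_alignment()]).
#'
#' @param object a `"sudden_expansion"` fit with a known sample size `n`.
#' @param nsim number of alignments.
#' @param seed optional integer seed.
#' @param n,k sample size and sequence length (defaults from the fit).
#' @param model mutation model, `"infinite_sites"` (the mismatch model's own
#'   assumption) or `"k2p"`.
#' @param ... unused.
#' @return A list of `"expansion_sim"` objects.
#' @export
simulate.sudden_expansion <- function(object, nsim = 1, seed = NULL,
                                      n = object$n, k = object$k,
                                      model = "infinite_sites", ...) {
  if (is.null(n)) stop("sample size n unknown; supply n")
  if (is.null(k)) k <- 1000L
  if (!is.null(seed)) set.seed(seed)
  cf <- object$coefficients
  lapply(seq_len(nsim), function(i) {
    sim_alignment(n, k, cf["theta0"], cf["theta1"], cf["tau"],
                  model = model)
  })
}

#' @export
summary.sudden_expansion <- function(object, ...) {
  structure(list(fit = object, gof = attr(object, "gof")),
            class = "summary.sudden_expansion")
}

#' @export
print.summary.sudden_expansion <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean pairwise (obs) = %.4g, fitted tail mass = %.3g\n",
              sum((0:x$fit$d) * x$fit$obs_freq),
              attr(predict(x$fit), "tail_mass")))
  if (!is.null(x$gof)) print(x$gof)
  invisible(x)
}

#' Parametric-bootstrap goodness of fit
#'
#' Tests the sudden-expansion model by simulating `reps` coalescent replicates
#' under the fitted parameters (infinite-sites mutation, the model's own
#' assumption), refitting each with the identical optimizer settings, and
#' comparing statistics: `p_ssd` is the fraction of replicate SSDs at least as
#' large as the observed SSD, `p_r` the analogue for the raggedness of the
#' replicate distributions. Small p-values reject the sudden-expansion model.
#'
#' @param fit a `"sudden_expansion"` with known `n` (fit from an alignment or a
#'   mismatch distribution carrying `n`).
#' @param reps bootstrap replicates (>= 100).
#' @param seed optional integer seed; fixed seed gives identical p-values.
#' @return An object of class `"gof_test"`: `p_ssd`, `p_r`, `reps`, `seed`,
#'   and the replicate statistics `boot_ssd`, `boot_r`.
#' @export
gof_test <- function(fit, reps = 1000, seed = NULL) {
  stopifnot(inherits(fit, "sudden_expansion"))
  if (is.null(fit$n)) stop("fit has no sample size n; fit from an alignment")
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  cf <- fit$coefficients
  boot_ssd <- numeric(reps)
  boot_r <- numeric(reps)
  for (r in seq_len(reps)) {
    mm <- sim_infsites_mismatch(fit$n, cf["theta0"], cf["theta1"], cf["tau"])
    freq <- mm$counts / sum(mm$counts)
    boot_r[r] <- raggedness(freq)
    boot_ssd[r] <- if (length(mm$counts) == 1L) {
      0  # monomorphic replicate: a refit is degenerate; perfect fit by convention
    } else {
      fit_mismatch(mm$counts)$ssd
    }
  }
  structure(list(p_ssd = mean(boot_ssd >= fit$ssd),
                 p_r = mean(boot_r >= fit$raggedness),
                 reps = reps, seed = seed,
                 boot_ssd = boot_ssd, boot_r = boot_r),
            class = "gof_test")
}

#' @export
print.gof_test <- function(x, ...) {
  cat(sprintf("Parametric bootstrap GOF (%d replicates): p_SSD = %.4g, p_r = %.4g\n",
              x$reps, x$p_ssd, x$p_r))
  invisible(x)
}
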