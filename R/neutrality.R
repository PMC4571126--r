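#' Tajima's D
#'
#' Normalized difference between the mean-pairwise and segregating-sites
#' estimators of theta: `D = (mean_pairwise - S/a1) / sqrt(e1*S + e2*S*(S-1))`
#' with the usual constants computed from the sample size. Negative values
#' indicate an excess of rare variants, as after a population expansion.
#'
#' @param n sample size (>= 4).
#' @param S number of segregating sites (>= 1; `S = 0` leaves D undefined and
#'   raises an error).
#' @param mean_pairwise mean number of pairwise differences (per sequence).
#' @return Tajima's D statistic.
#' @examples
#' tajima_d(4, 3, 1.5)  # -0.754
#' @export
tajima_d <- function(n, S, mean_pairwise) {
  if (n < 4) stop("Tajima's D needs n >= 4")
  if (S < 1) stop("Tajima's D undefined for S = 0")
  cst <- tajima_constants(n)
  (mean_pairwise - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# Tajima (1989) constants (internal).
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Ewens distribution of the number of haplotypes
#'
#' Probability mass function of the number of distinct haplotypes `K` in a
#' sample of `n` non-recombining sequences under neutrality given the scaled
#' mutation parameter `theta`:
#' `P(K = k) = |s(n, k)| theta^k / theta_(n)` with unsigned Stirling numbers of
#' the first kind and the rising factorial `theta_(n)`. Computed with the
#' numerically stable sequential recurrence
#' `p[m+1, k] = m/(theta+m) p[m, k] + theta/(theta+m) p[m, k-1]`
#' (every step a convex combination, so no overflow for any `n`).
#'
#' @param n sample size (>= 1).
#' @param theta scaled mutation parameter (> 0).
#' @return Numeric vector of length `n`; element `k` is `P(K = k)`. Sums to 1.
#' @export
ewens_k_pmf <- function(n, theta) {
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  p <- c(1, rep(0, n - 1))
  if (n > 1) {
    for (m in seq_len(n - 1)) {
      w <- theta / (theta + m)
      p <- (1 - w) * p + w * c(0, p[-n])
    }
  }
  p
}

#' Fu's Fs
#'
#' Log-odds of observing at least the sampled number of haplotypes under the
#' Ewens distribution with `theta` set to the mean pairwise diversity:
#' `S' = P(K >= h_obs | theta)`, `Fs = log(S'/(1 - S'))`. Large negative values
#' indicate an excess of haplotypes relative to the diversity, the hallmark of
#' recent expansion.
#'
#' @param n sample size (>= 2).
#' @param h_obs observed number of haplotypes (`2 <= h_obs <= n`; a single
#'   haplotype makes `S' = 1` and `Fs` undefined).
#' @param theta_pi mean pairwise differences (per sequence), > 0.
#' @return Fu's Fs statistic.
#' @examples
#' fu_fs(4, 2, 1)  # log(3)
#' @export
fu_fs <- function(n, h_obs, theta_pi) {
  if (n < 2) stop("Fu's Fs needs n >= 2")
  if (h_obs < 1 || h_obs > n) stop("h_obs must be in 1..n")
  if (h_obs == 1) stop("degenerate: single haplotype (S' = 1, Fs undefined)")
  if (!is.finite(theta_pi) || theta_pi <= 0) stop("theta_pi must be > 0")
  sp <- sum(ewens_k_pmf(n, theta_pi)[h_obs:n])
  log(sp) - log1p(-sp)
}

#' Neutrality tests with coalescent-simulation p-values
#'
#' Computes Tajima's D and Fu's Fs for an alignment and obtains one-tailed
#' p-values in the expansion (negative) direction from `reps` constant-size
#' coalescent replicates. The null is conditioned on the observed mean
#' pairwise diversity (theta-hat-pi): each replicate simulates an
#' infinite-sites sample of the same `n` with `theta = theta_pi`, and
#' `p = fraction of replicates with statistic <= observed`. Null replicates
#' with `S = 0` contribute `D = 0`, and single-haplotype replicates contribute
#' `Fs = +Inf` (never more extreme than a negative observed value).
#'
#' @param aln a gap-free [dna_alignment()] with `n >= 4`.
#' @param reps number of coalescent replicates (>= 100).
#' @param seed optional integer seed; fixed seed gives identical p-values.
#' @return An object of class `"neutrality_test"`: `D`, `Fs`, `p_D`, `p_Fs`,
#'   `reps`, `seed`, plus the observed `n`, `S`, `h`, `theta_pi`. For a
#'   degenerate alignment (`S = 0`) all statistics are `NA`.
#' @export
neutrality_test <- function(aln, reps = 1000, seed = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (aln$n < 4) stop("neutrality tests need n >= 4")
  if (reps < 100) stop("reps must be >= 100")
  n <- aln$n
  S <- seg_sites(aln)
  if (S == 0) {
    res <- list(D = NA_real_, Fs = NA_real_, p_D = NA_real_, p_Fs = NA_real_,
                reps = reps, seed = seed, n = n, S = 0L, h = 1L,
                theta_pi = 0)
    return(structure(res, class = "neutrality_test"))
  }
  D <- pairwise_diffs(aln)
  mp <- mean(D[upper.tri(D)])
  h <- haplotypes(aln)$h
  D_obs <- tajima_d(n, S, mp)
  Fs_obs <- fu_fs(n, h, mp)
  if (!is.null(seed)) set.seed(seed)
  D_null <- numeric(reps)
  Fs_null <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- sim_infsites_stats(n, theta0 = mp, theta1 = mp, tau = 0)
    D_null[r] <- if (st$S > 0) tajima_d(n, st$S, st$mp) else 0
    Fs_null[r] <- if (st$h > 1) fu_fs(n, st$h, max(st$mp, 1e-12)) else Inf
  }
  structure(list(D = D_obs, Fs = Fs_obs,
                 p_D = mean(D_null <= D_obs),
                 p_Fs = mean(Fs_null <= Fs_obs),
                 reps = reps, seed = seed, n = n, S = S, h = h,
                 theta_pi = mp),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  star <- function(p) {
    if (is.na(p)) "" else if (p < 0.001) " **" else if (p < 0.05) " *" else ""
  }
  cat("Neutrality tests (n =", x$n, ", S =", x$S, ", h =", x$h, ")\n")
  if (is.na(x$D)) {
    cat("  no variation: statistics undefined (NA)\n")
  } else {
    cat(sprintf("  Tajima's D = %.3f  (p = %.4g)%s\n", x$D, x$p_D, star(x$p_D)))
    cat(sprintf("  Fu's Fs    = %.3f  (p = %.4g)%s\n", x$Fs, x$p_Fs, star(x$p_Fs)))
    cat("  one-tailed toward expansion;", x$reps,
        "constant-size coalescent replicates conditioned on theta-hat-pi\n")
  }
  invisible(x)
}
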