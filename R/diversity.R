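#' Pairwise difference matrix
#'
#' Number of differing sites between every pair of sequences. Only sites where
#' both bases are in `A C G T` are compared; sites with `N` in either sequence
#' of a pair are skipped for that pair (pairwise deletion). The per-pair number
#' of comparable sites is returned as attribute `"comparable"`.
#'
#' @param aln a gap-free [dna_alignment()].
#' @return An `n x n` symmetric integer matrix of pairwise differences with a
#'   zero diagonal.
#' @export
pairwise_diffs <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (any(aln$seqs == "-")) {
    stop("alignment contains gaps; apply exclude_indels() first")
  }
  n <- aln$n
  code <- match(aln$seqs, c("A", "C", "G", "T"))  # N -> NA
  dim(code) <- dim(aln$seqs)
  D <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  L <- matrix(aln$k, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      xi <- code[i, ]
      for (j in seq(i + 1L, n)) {
        xj <- code[j, ]
        ok <- !is.na(xi) & !is.na(xj)
        D[i, j] <- D[j, i] <- sum(xi[ok] != xj[ok])
        L[i, j] <- L[j, i] <- sum(ok)
      }
    }
  }
  attr(D, "comparable") <- L
  D
}

#' Nucleotide diversity
#'
#' Mean per-site pairwise difference: the average over all sequence pairs of
#' (differences / comparable sites). With no missing data this equals the mean
#' pairwise difference divided by `k`. The simple mean-pairwise estimator is
#' used (no `n/(n-1)` correction), matching the convention of the standard
#' population-genetics packages for this statistic.
#'
#' @param aln a gap-free [dna_alignment()] with `n >= 2`.
#' @return Nucleotide diversity as a fraction in `[0, 1]` (multiply by 100 to
#'   report as a percentage).
#' @export
nuc_diversity <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (aln$n < 2) stop("nucleotide diversity needs n >= 2")
  D <- pairwise_diffs(aln)
  L <- attr(D, "comparable")
  up <- upper.tri(D)
  if (any(L[up] == 0)) stop("a sequence pair has no comparable sites")
  mean(D[up] / L[up])
}

#' Haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` where `p_i` are haplotype frequencies:
#' the probability that two sequences drawn without replacement carry
#' different haplotypes.
#'
#' @param x a [haplotypes()] table, a [dna_alignment()], or a vector of
#'   haplotype counts.
#' @return Haplotype diversity in `[0, 1]`.
#' @examples
#' hap_diversity(c(2, 2))  # 0.6667
#' @export
hap_diversity <- function(x) {
  counts <- if (inherits(x, "haplotype_table")) {
    x$counts
  } else if (inherits(x, "dna_alignment")) {
    haplotypes(x)$counts
  } else {
    x
  }
  counts <- as.numeric(counts)
  if (any(counts <= 0)) stop("haplotype counts must be positive")
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Segregating sites
#'
#' Number of columns with at least two distinct bases among `A C G T`
#' (`N` ignored).
#'
#' @param aln a gap-free [dna_alignment()].
#' @return Integer count `S`.
#' @export
seg_sites <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  sum(apply(aln$seqs, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) > 1L
  }))
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' transition and transversion proportions over comparable sites (both bases in
#' `A C G T`). Saturated pairs (non-positive log argument) raise an error
#' rather than returning `NaN`.
#'
#' @param a,b equal-length sequences (character vectors of bases or single
#'   strings).
#' @return Distance in substitutions/site.
#' @examples
#' k2p_distance("ACGT", "GCGT")  # one transition in four sites
#' @export
k2p_distance <- function(a, b) {
  tobase <- function(x) {
    x <- toupper(as.character(x))
    if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
    x
  }
  a <- tobase(a); b <- tobase(b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  acgt <- c("A", "C", "G", "T")
  ok <- a %in% acgt & b %in% acgt
  L <- sum(ok)
  if (L == 0) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  purine <- c("A", "G")
  diff <- a != b
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / L
  Q <- sum(diff & !ts) / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P saturation: log argument <= 0 (P=", signif(P, 4),
         ", Q=", signif(Q, 4), ")")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter distance matrix
#'
#' All pairwise [k2p_distance()] values of an alignment, with pairwise deletion
#' of sites containing `N`.
#'
#' @param aln a gap-free [dna_alignment()].
#' @return Symmetric numeric matrix (substitutions/site), zero diagonal, with
#'   attribute `"model" = "K2P"`.
#' @export
k2p_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- aln$n
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        D[i, j] <- D[j, i] <- k2p_distance(aln$seqs[i, ], aln$seqs[j, ])
      }
    }
  }
  attr(D, "model") <- "K2P"
  D
}

#' Mismatch distribution
#'
#' Histogram of the `choose(n, 2)` pairwise difference counts of an alignment:
#' the central observable of demographic-expansion analysis. Class `j` holds
#' the number of sequence pairs differing at exactly `j` sites.
#'
#' @param aln a gap-free [dna_alignment()] with `n >= 2`.
#' @return An object of class `"mismatch_distribution"`: `counts` over classes
#'   `0..d`, `classes`, and the sample size `n`.
#' @export
mismatch <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (aln$n < 2) stop("mismatch distribution needs n >= 2")
  D <- pairwise_diffs(aln)
  d <- D[upper.tri(D)]
  mismatch_distribution(tabulate(d + 1L, nbins = max(d) + 1L), n = aln$n)
}

#' Construct a mismatch distribution from counts
#'
#' @param counts non-negative pair counts for difference classes `0, 1, ...`.
#' @param n sample size the pairs came from; `sum(counts)` must equal
#'   `choose(n, 2)` when given.
#' @return A `"mismatch_distribution"`.
#' @export
mismatch_distribution <- function(counts, n = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be non-negative and finite")
  }
  if (!is.null(n) && sum(counts) != choose(n, 2)) {
    stop("sum(counts) must equal choose(n, 2) pairs")
  }
  # trim trailing empty classes so d is the largest observed class
  d <- max(c(0L, which(counts > 0) - 1L))
  counts <- counts[seq_len(d + 1L)]
  structure(list(counts = counts, classes = 0:d, n = n),
            class = "mismatch_distribution")
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat("Mismatch distribution:", sum(x$counts), "pairs",
      if (!is.null(x$n)) paste0("(n = ", x$n, ")"), "\n")
  cat("Classes 0..", max(x$classes), "; mean = ",
      round(mismatch_mean(x), 3), "\n", sep = "")
  invisible(x)
}

# Mean pairwise difference of a mismatch distribution (internal).
mismatch_mean <- function(x) {
  sum(x$classes * x$counts) / sum(x$counts)
}

#' Summary diversity statistics of an alignment
#'
#' The per-group summary used in expansion scans: sample size, segregating
#' sites, haplotype count, nucleotide diversity, haplotype diversity, and mean
#' pairwise differences.
#'
#' @param aln a gap-free [dna_alignment()] with `n >= 2`.
#' @return A one-row `data.frame` with columns `n`, `k`, `S`, `h`, `pi`
#'   (fraction), `pi_pct`, `hd`, `mean_pairwise`.
#' @export
diversity_summary <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (aln$n < 2) stop("diversity summary needs n >= 2")
  D <- pairwise_diffs(aln)
  L <- attr(D, "comparable")
  up <- upper.tri(D)
  pi <- mean(D[up] / L[up])
  data.frame(n = aln$n, k = aln$k, S = seg_sites(aln), h = haplotypes(aln)$h,
             pi = pi, pi_pct = 100 * pi, hd = hap_diversity(aln),
             mean_pairwise = mean(D[up]))
}
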