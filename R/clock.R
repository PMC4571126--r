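#' UPGMA clock tree
#'
#' Average-linkage agglomeration of a distance matrix into a rooted ultrametric
#' tree with node heights equal to half the cluster distance — the
#' deterministic strict-clock surrogate for Bayesian dating. Labels are sorted
#' lexicographically before clustering so ties break deterministically.
#'
#' @param d a symmetric distance matrix (substitutions/site) with labelled
#'   rows/columns, or a `dist` object; `NA`/`NaN` entries are an error.
#' @return An `ape` `"phylo"` ultrametric tree; node heights (subs/site) in
#'   attribute `"heights"`.
#' @examples
#' d <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma_tree(d)
#' max(attr(tr, "heights"))  # 0.2
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2) {
    stop("d must be a square distance matrix with n >= 2")
  }
  if (any(!is.finite(d))) stop("distance matrix contains NA/NaN/Inf")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("g", seq_len(nrow(d)))
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)  # heights = cluster distance / 2
  depths <- ape::node.depth.edgelength(phy)
  heights <- max(depths) - depths
  names(heights) <- c(phy$tip.label, rep("", phy$Nnode))
  attr(phy, "heights") <- heights
  phy
}

#' Convert a clock-tree height to a divergence time
#'
#' Under a strict clock, a node height `h` in substitutions/site corresponds to
#' `T = h / mu` years with `mu` in per-site-per-year units; equivalently, for a
#' pair of lineages at distance `d`, `T = d / (2 mu)`. `mu` is given in
#' %/site/myr, the reporting unit of [tau_to_rate()]. Linear in height,
#' inverse-linear in `mu`. Note that distance-based point estimates date the
#' sequence split, which precedes population splits by the within-population
#' coalescent depth, so they differ systematically from coalescent-based TMRCA
#' machinery.
#'
#' @param height node height in substitutions/site (>= 0).
#' @param mu_pct_per_myr evolutionary rate in %/site/myr (> 0).
#' @return Time in years.
#' @examples
#' height_to_time(0.0293 / 2, 17.1)  # ~ 85.7 kyr
#' @export
height_to_time <- function(height, mu_pct_per_myr) {
  if (any(mu_pct_per_myr <= 0)) stop("mu must be > 0")
  if (any(height < 0)) stop("height must be >= 0")
  height / (mu_pct_per_myr * 1e-8)
}

#' Date the split between sequence groups
#'
#' Strict-clock pairwise dating: the mean between-group K2P distance is
#' converted to years via `T = d / (2 mu)`. With `net = TRUE` the average
#' within-group diversity is subtracted (net divergence, `d_A`), which removes
#' the ancestral-coalescent component and materially lowers recent dates.
#'
#' @param aln a gap-free [dna_alignment()].
#' @param groups named character vector or factor mapping each sequence id to a
#'   group label (names = ids), or a list of id vectors by group.
#' @param mu_pct_per_myr vector of rates in %/site/myr.
#' @param net subtract mean within-group distance (default `FALSE`).
#' @return A `data.frame` with one row per group pair and rate: `group1`,
#'   `group2`, `d` (distance used), `mu_pct_per_myr`, `t_years`.
#' @export
date_groups <- function(aln, groups, mu_pct_per_myr, net = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.list(groups)) {
    groups <- stats::setNames(rep(names(groups), lengths(groups)),
                              unlist(groups))
  }
  ids <- names(groups)
  if (is.null(ids) || !all(ids %in% aln$ids)) {
    stop("groups must be named by sequence ids present in the alignment")
  }
  g <- as.character(groups)[match(aln$ids, ids)]
  if (anyNA(g)) stop("every sequence must be assigned to a group")
  D <- k2p_matrix(aln)
  labs <- sort(unique(g))
  if (length(labs) < 2) stop("need at least two groups")
  within <- vapply(labs, function(a) {
    i <- which(g == a)
    if (length(i) < 2) 0 else mean(D[i, i][upper.tri(D[i, i])])
  }, 0)
  out <- list()
  for (a in seq_len(length(labs) - 1L)) {
    for (b in seq(a + 1L, length(labs))) {
      dxy <- mean(D[g == labs[a], g == labs[b], drop = FALSE])
      dd <- if (net) dxy - (within[a] + within[b]) / 2 else dxy
      dd <- max(dd, 0)
      out[[length(out) + 1L]] <- data.frame(
        group1 = labs[a], group2 = labs[b], d = dd,
        mu_pct_per_myr = mu_pct_per_myr,
        t_years = dd / 2 / (mu_pct_per_myr * 1e-8))
    }
  }
  do.call(rbind, out)
}
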