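#' @title Coalescent simulation under an instantaneous-expansion demography
#'
#' @description
#' The simulator realizes the n-coalescent for a haploid population whose
#' scaled diversity switches, looking backward in time, from the current
#' `theta1` to the ancestral `theta0` at the expansion time `tau`. Time is
#' measured in mutational units (the units of `tau` = 2*u*t), and branch
#' lengths are expressed in expected mutations per sequence, so that under a
#' constant size `theta` the expected pairwise difference equals `theta`, and
#' in the strong-expansion limit (`theta1 >> theta0`) it approaches
#' `tau + theta0`.
#'
#' @name coalescent-simulation
NULL

# Simulate one coalescent genealogy. Internal workhorse; uses the current RNG
# stream (callers seed). Returns parent/time vectors over nodes 1..2n-1
# (tips 1..n at time 0, internal nodes n+1..2n-1 in coalescence order, root
# last) with times in mutational units (tau units).
coal_history <- function(n, theta0, theta1, tau) {
  if (n < 2) stop("n must be >= 2")
  if (!all(is.finite(c(theta0, theta1, tau))) ||
      theta0 < 0 || theta1 < 0 || tau < 0) {
    stop("theta0, theta1 and tau must be finite and >= 0")
  }
  nn <- 2L * n - 1L
  parent <- integer(nn)
  time <- numeric(nn)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  repeat {
    j <- length(active)
    if (j == 1L) break
    th <- if (t < tau) theta1 else theta0
    if (th == 0) {
      # infinite coalescence rate: merge immediately at current time
      dt <- 0
    } else {
      dt <- stats::rexp(1L, rate = choose(j, 2) / th)
    }
    if (t < tau && t + dt >= tau && theta0 != theta1) {
      # epoch boundary crossed: restart the (memoryless) wait under theta0
      t <- tau
      next
    }
    t <- t + dt
    pick <- sample.int(j, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    parent[a] <- nxt; parent[b] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(n = n, parent = parent, time = time)
}

# Branch lengths in expected-mutation units (per sequence): half the time span
# of each branch, so a pairwise path of total time T carries T expected
# mutations. Indexed by child node; the root has no branch (length 0).
branch_lengths <- function(hist) {
  len <- numeric(length(hist$parent))
  has_parent <- hist$parent > 0L
  len[has_parent] <- (hist$time[hist$parent[has_parent]] -
                        hist$time[has_parent]) / 2
  len
}

# Children list indexed by node id (internal).
children_list <- function(hist) {
  nn <- length(hist$parent)
  kids <- vector("list", nn)
  for (v in which(hist$parent > 0L)) {
    p <- hist$parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

# Number of tip descendants per node (internal).
tip_counts <- function(hist) {
  n <- hist$n
  nn <- 2L * n - 1L
  cnt <- c(rep(1L, n), rep(0L, n - 1L))
  for (v in seq_len(nn - 1L)) cnt[hist$parent[v]] <- cnt[hist$parent[v]] + cnt[v]
  cnt
}

# Logical tip-membership matrix: desc[b, i] is TRUE if tip i descends from
# node b (internal; rows = nodes).
tip_membership <- function(hist) {
  n <- hist$n
  nn <- 2L * n - 1L
  m <- matrix(FALSE, nn, n)
  m[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (v in seq_len(nn - 1L)) m[hist$parent[v], ] <- m[hist$parent[v], ] | m[v, ]
  m
}

#' Simulate a coalescent genealogy
#'
#' Draws one genealogy of `n` haploid sequences under the instantaneous
#' expansion demography (`theta1` at times more recent than `tau`, `theta0`
#' beyond it, backward in time). Branch lengths are in expected mutations per
#' sequence: under constant size `theta` the expected pairwise path length is
#' `theta`.
#'
#' @param n sample size (>= 2).
#' @param theta0 ancestral scaled diversity (2*N0*u per sequence), >= 0.
#' @param theta1 current scaled diversity, >= 0.
#' @param tau expansion time in mutational units (2*u*t), >= 0.
#' @param seed optional integer seed; the same seed reproduces the same tree.
#' @return An `ape` `"phylo"` tree (rooted, binary, ultrametric in time), with
#'   coalescent node times (mutational units) in attribute `"times"`.
#' @examples
#' tr <- sim_genealogy(5, theta0 = 1, theta1 = 1, tau = 0, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
sim_genealogy <- function(n, theta0, theta1, tau, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hist <- coal_history(n, theta0, theta1, tau)
  history_to_phylo(hist)
}

# Convert a coal_history to an ape phylo object (internal). Internal node ids
# are remapped so the root becomes n+1, per ape convention.
history_to_phylo <- function(hist) {
  n <- hist$n
  nn <- 2L * n - 1L
  remap <- seq_len(nn)
  remap[(n + 1L):nn] <- 3L * n - (n + 1L):nn  # root (2n-1) -> n+1
  len <- branch_lengths(hist)
  child <- which(hist$parent > 0L)
  edge <- cbind(remap[hist$parent[child]], remap[child])
  phy <- list(edge = edge,
              edge.length = len[child],
              tip.label = paste0("t", seq_len(n)),
              Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  times <- hist$time
  names(times) <- remap
  attr(phy, "times") <- times[order(remap)]
  phy
}

#' Simulate an alignment under the sudden-expansion coalescent
#'
#' Generates a genealogy with [sim_genealogy()]'s model and drops mutations on
#' it: counts are Poisson with mean equal to the branch length (expected
#' mutations per sequence). Two mutation models are available:
#'
#' * `"k2p"` (finite sites): each mutation hits a uniformly chosen site of a
#'   `k`-bp sequence and is a transition with probability `kappa/(kappa + 2)`
#'   or each transversion with probability `1/(kappa + 2)`; the root sequence
#'   is uniform over ACGT. Homoplasy (multiple hits) occurs as in real data.
#' * `"infinite_sites"`: every mutation creates a new segregating column
#'   (ancestral `A`, derived `G`), matching coalescent theory exactly; `k` is
#'   ignored except as metadata.
#'
#' @param n sample size (>= 2).
#' @param k sequence length in bp (>= 1).
#' @param theta0,theta1,tau demography; see [sim_genealogy()].
#' @param kappa transition/transversion rate ratio (> 0). The default 10
#'   reflects the strong transition bias typical of mammalian mtDNA.
#' @param model `"k2p"` or `"infinite_sites"`.
#' @param seed optional integer seed; identical seeds give identical output.
#' @param root_seq optional root sequence (character vector of length `k`) for
#'   the finite-sites model.
#' @return A list of class `"expansion_sim"` with elements `alignment` (a
#'   [dna_alignment()], ids `t1..tn`) and `truth` (the generating parameters,
#'   model, and seed; replaying `truth` with [replay_sim()] reproduces the
#'   alignment exactly).
#' @examples
#' sim <- sim_alignment(10, 500, theta0 = 1, theta1 = 100, tau = 3, seed = 7)
#' sim$alignment$n
#' @export
sim_alignment <- function(n, k, theta0, theta1, tau, kappa = 10,
                          model = c("k2p", "infinite_sites"),
                          seed = NULL, root_seq = NULL) {
  model <- match.arg(model)
  if (k < 1) stop("k must be >= 1")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.null(seed)) set.seed(seed)
  hist <- coal_history(n, theta0, theta1, tau)
  len <- branch_lengths(hist)
  muts <- stats::rpois(length(len), len)
  seqs <- if (model == "k2p") {
    mutate_k2p(hist, muts, k, kappa, root_seq)
  } else {
    mutate_infinite_sites(hist, muts)
  }
  aln <- dna_alignment(seqs, ids = paste0("t", seq_len(n)))
  truth <- list(n = n, k = k, theta0 = theta0, theta1 = theta1, tau = tau,
                kappa = kappa, model = model, seed = seed)
  structure(list(alignment = aln, truth = truth), class = "expansion_sim")
}

#' @export
print.expansion_sim <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "Simulated alignment: n=%d, k=%d bp, model=%s\n  theta0=%g theta1=%g tau=%g kappa=%g seed=%s\n",
    tr$n, tr$k, tr$model, tr$theta0, tr$theta1, tr$tau, tr$kappa,
    if (is.null(tr$seed)) "none" else tr$seed))
  invisible(x)
}

#' Replay a recorded simulation
#'
#' Re-runs [sim_alignment()] from a truth record; with the recorded seed the
#' output alignment is reproduced exactly.
#'
#' @param truth the `truth` element of an `"expansion_sim"`.
#' @return An `"expansion_sim"`.
#' @export
replay_sim <- function(truth) {
  sim_alignment(truth$n, truth$k, truth$theta0, truth$theta1, truth$tau,
                kappa = truth$kappa, model = truth$model, seed = truth$seed)
}

# Finite-sites K2P-style mutation along the genealogy (internal).
# Transitions: A<->G, C<->T.
mutate_k2p <- function(hist, muts, k, kappa, root_seq = NULL) {
  n <- hist$n
  nn <- 2L * n - 1L
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  if (is.null(root_seq)) {
    root_seq <- sample(bases, k, replace = TRUE)
  } else {
    root_seq <- toupper(as.character(root_seq))
    if (length(root_seq) == 1L && k > 1L) {
      root_seq <- strsplit(root_seq, "", fixed = TRUE)[[1L]]
    }
    if (length(root_seq) != k) stop("root_seq must have length k")
  }
  kids <- children_list(hist)
  seqs <- matrix(NA_character_, nn, k)
  seqs[nn, ] <- root_seq
  # process internal nodes from the root down (ids decrease toward the present)
  for (v in seq(nn, n + 1L)) {
    for (ch in kids[[v]]) {
      s <- seqs[v, ]
      m <- muts[ch]
      if (m > 0L) {
        sites <- sample.int(k, m, replace = TRUE)
        is_ts <- stats::runif(m) < kappa / (kappa + 2)
        for (j in seq_len(m)) {
          b <- s[sites[j]]
          s[sites[j]] <- if (is_ts[j]) {
            ts_partner[[b]]
          } else {
            # two transversion targets, equally likely
            tv <- setdiff(bases, c(b, ts_partner[[b]]))
            tv[1L + (stats::runif(1) < 0.5)]
          }
        }
      }
      seqs[ch, ] <- s
    }
  }
  seqs[seq_len(n), , drop = FALSE]
}

# Infinite-sites realization: one new column per mutation (internal).
mutate_infinite_sites <- function(hist, muts) {
  n <- hist$n
  S <- sum(muts[seq_len(2L * n - 2L)])
  if (S == 0L) return(matrix("A", n, 1L))
  desc <- tip_membership(hist)
  out <- matrix("A", n, S)
  col <- 1L
  for (b in which(muts > 0L & seq_along(muts) < 2L * n - 1L)) {
    for (j in seq_len(muts[b])) {
      out[desc[b, ], col] <- "G"
      col <- col + 1L
    }
  }
  out
}

# Fast summary statistics (S, mean pairwise, haplotype count) of one
# infinite-sites coalescent replicate, without building sequences. Used by the
# neutrality-test null distribution. Internal; uses current RNG stream.
sim_infsites_stats <- function(n, theta0, theta1, tau) {
  hist <- coal_history(n, theta0, theta1, tau)
  nb <- 2L * n - 2L
  muts <- stats::rpois(nb, branch_lengths(hist)[seq_len(nb)])
  S <- sum(muts)
  cnt <- tip_counts(hist)[seq_len(nb)]
  npairs <- choose(n, 2)
  mp <- sum(muts * cnt * (n - cnt)) / npairs
  # haplotype count: tips are identical iff no mutated branch separates them
  lab <- rep("", 2L * n - 1L)
  kids <- children_list(hist)
  for (v in seq(2L * n - 1L, n + 1L)) {
    for (ch in kids[[v]]) {
      lab[ch] <- if (muts[ch] > 0L) paste0(lab[v], ",", ch) else lab[v]
    }
  }
  h <- length(unique(lab[seq_len(n)]))
  list(S = S, mp = mp, h = h)
}

# Mismatch counts of one infinite-sites replicate, from the genealogy
# (pairwise difference = mutations on the connecting path). Internal.
sim_infsites_mismatch <- function(n, theta0, theta1, tau) {
  hist <- coal_history(n, theta0, theta1, tau)
  nb <- 2L * n - 2L
  muts <- stats::rpois(nb, branch_lengths(hist)[seq_len(nb)])
  D <- matrix(0, n, n)
  if (any(muts > 0L)) {
    desc <- tip_membership(hist)
    for (b in which(muts > 0L)) {
      v <- desc[b, seq_len(n)]
      D <- D + muts[b] * (outer(v, !v) + outer(!v, v))
    }
  }
  d <- D[upper.tri(D)]
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  mismatch_distribution(counts, n = n)
}
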