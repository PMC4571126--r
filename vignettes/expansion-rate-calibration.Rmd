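---
title: "Dating sudden population expansions and calibrating molecular rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating sudden population expansions and calibrating molecular rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expansionclock)
```

## The problem

A population that expands abruptly — for example, a temperate small mammal
recolonizing a northern island as forests return after a glacial period —
leaves a characteristic signature in a sample of non-recombining sequences
such as mitochondrial DNA: a star-like genealogy, many low-frequency
haplotypes (low nucleotide diversity $\pi$, high haplotype diversity $H_d$),
strongly negative neutrality statistics (Tajima's $D$, Fu's $F_S$), and a
smooth unimodal *mismatch distribution* (the histogram of pairwise sequence
differences) whose mode sits near the expansion parameter $\tau$.

Because $\tau = 2ut$ measures the expansion age in *mutational* time, knowing
the calendar age $t$ of the expansion from an independent source (here,
paleoclimatic anchors: postglacial forest recovery at roughly 7–10 kyr BP, the
end of the last glacial maximum at 15 kyr BP, or earlier glacial terminations
at 60 and 130 kyr BP) turns the fitted $\tau$ into an estimate of the
molecular evolutionary rate:

$$ t = \frac{\tau}{2u}, \qquad u = \mu k g, $$

where $\mu$ is the rate per site per year, $k$ the sequence length in bp and
$g$ the generation time in years. The package reports $\mu$ in %/site/myr
(full precision retained internally; one decimal on report surfaces).

## The sudden-expansion mismatch model

For a haploid population jumping instantaneously from scaled diversity
$\theta_0$ to $\theta_1$ (both per sequence, $\theta = 2Nu$) at $\tau$
mutational units before the present, the expected proportion of sequence
pairs differing at $i$ sites is

$$ F_i = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
   \sum_{j=0}^{i} \frac{\tau^{\,i-j}}{(i-j)!}
   \left[\hat F_j(\theta_0) - \hat F_j(\theta_1)\right], \qquad
   \hat F_j(\theta) = \frac{\theta^j}{(\theta+1)^{j+1}}. $$

Useful limits, all covered by tests:

* $\tau = 0$ or $\theta_0 = \theta_1$: the equilibrium geometric
  $\hat F(\theta_0)$.
* $\theta_1 \to \infty$, i.e. a very large present-day population: the
  convolution of a Poisson($\tau$) with a geometric($\theta_0$), with mean
  $\tau + \theta_0$ — the "wave" that travels right at one mutation per unit
  of $\tau$.

```{r expected}
round(expected_mismatch(tau = 0, theta0 = 1, theta1 = 50, max_class = 4), 4)
round(expected_mismatch(tau = 5, theta0 = 0, theta1 = 1e6, max_class = 4), 4)
```

### Fitting

`sudden_expansion()` minimizes the unweighted sum of squared deviations (SSD)
between observed relative frequencies over classes $0..d$ ($d$ = largest
observed class) and $F_i(\tau, \theta_0, \theta_1)$. Generalized least
squares with the sampling covariance is a known alternative; ordinary least
squares is the implemented contract, matching how SSD is then used as the
goodness-of-fit statistic. The optimizer is deterministic: a coarse grid
(21 $\tau$ values on $[0, 2d]$ plus 15 on $[0, 3\bar m]$ where $\bar m$ is the
observed mean, 10 $\theta_0$ values on $[0, \bar m]$, 10 log-spaced $\theta_1$
values up to $10^5$), method-of-moments starts, bounded `L-BFGS-B` refinement
from the best five candidates, and a final Nelder–Mead polish. The
$\theta_1 \le 10^5$ and $\tau \le 2d$ bounds stop runaway along the flat
upper-$\theta_1$ direction; the fitted SSD can never exceed the best grid
candidate.

One identifiability caveat matters for interpretation: the wave position is
$\tau + \theta_0$, and with a single noisy sample the likelihood is nearly
flat along that trade-off, so the least-squares optimum frequently sits at
$\hat\theta_0 = 0$ with $\hat\tau$ near the observed mean. Estimated $\tau$
therefore tracks $\tau + \theta_0$ rather than $\tau$ itself whenever the
pre-expansion population was not tiny. This is a property of the estimator
family, not of the implementation; rate calibrations inherit it.

### Goodness of fit

`gof_test()` is a parametric bootstrap: `reps` coalescent samples are
simulated under the fitted $(\hat\tau, \hat\theta_0, \hat\theta_1)$, each is
*refitted with identical optimizer settings*, and

* $p_{SSD}$ = fraction of replicate SSDs $\ge$ the observed SSD,
* $p_r$ = fraction of replicate raggedness values $\ge$ the observed
  raggedness $r = \sum_{i=1}^{d}(x_i - x_{i-1})^2$ (no zero-padding beyond the
  last class; conventions differ across software, so the contract is fixed
  here).

Bootstrap replicates use infinite-sites mutation — the mismatch model's own
assumption — so the test asks exactly "does the model reproduce data like
mine?". Because each replicate is refitted, the test is conservative: under
the model itself the rejection rate at the 0.05 level stays well below
nominal (asserted in the acceptance suite). Monomorphic bootstrap replicates
(rare, only under near-zero diversity) are scored as perfect fits, which only
adds to that conservatism.

## Neutrality tests

`tajima_d(n, S, mean_pairwise)` uses the standard constants; $S = 0$ is an
error surfaced as `NA` by higher-level drivers. `fu_fs(n, h, theta_pi)`
computes $S' = P(K \ge h_{obs})$ under the Ewens distribution of the
haplotype count with $\theta$ set to the mean pairwise diversity, and
$F_S = \ln S' - \ln(1 - S')$. The Ewens probabilities come from the
sequential (Chinese-restaurant) recurrence
$p_{m+1,k} = \frac{m}{\theta+m}p_{m,k} + \frac{\theta}{\theta+m}p_{m,k-1}$,
which is a chain of convex combinations: it cannot overflow and is accurate
to close to machine precision for any practical $n$ (the test suite checks it
against exact Stirling-number enumeration for $n \le 8$ and normalization up
to $n = 150$).

`neutrality_test()` obtains one-tailed p-values in the expansion (negative)
direction from constant-size coalescent replicates *conditioned on the
observed* $\hat\theta_\pi$ (given $\theta$, simulate genealogy and
mutations), rather than conditioning on $S$; the choice follows the
construction of $F_S$ and is stated here because reference implementations
are not explicit about it. Significance marks follow the 0.05/0.001
convention; note that a stricter 0.02 cutoff is sometimes recommended for
$F_S$. Null replicates with $S=0$ contribute $D=0$, single-haplotype
replicates $F_S=+\infty$; both conventions only make the one-tailed test
conservative.

## The coalescent simulator

`sim_alignment()` and `sim_genealogy()` implement the n-coalescent with a
piecewise-constant population: looking backward, scaled size $\theta_1$ for
times younger than $\tau$ and $\theta_0$ beyond. Time is measured in
mutational units and branch lengths in expected mutations per sequence, so
that under constant $\theta$ the expected pairwise difference equals
$\theta$ and, for $\theta_1 \gg \theta_0$, the mean mismatch approaches
$\tau + \theta_0$. $\theta$ and $\tau$ are *per sequence*, not per site —
the same convention in which the rate formula converts $\tau$ with $k$
explicitly. Two mutation engines:

* **infinite sites** — every mutation a new column; exact for coalescent
  theory checks ($E[S] = \theta a_1(n)$, etc.) and used for the mismatch
  bootstrap;
* **finite sites (`k2p`)** — mutations hit uniform positions of a `k`-bp
  sequence with transition probability $\kappa/(\kappa+2)$; realistic
  homoplasy for validation at mitochondrial scale. The default
  $\kappa = 10$ reflects the strong transition bias of mammalian mtDNA;
  it is a documented default, not an estimate.

Everything stochastic takes an explicit integer seed, and each simulated
alignment carries a truth record that `replay_sim()` reproduces exactly.

What the generator does *not* emulate: rate heterogeneity among sites,
selection, recombination (appropriate for mtDNA), population structure and
migration, and sequencing error. Passing the validation suite therefore
shows the inference chain is correct *under the model*, not that any real
data set satisfies the model.

## Diversity statistics and distances

$\pi$ is the simple mean of per-pair per-site differences (no $n/(n-1)$
correction), $H_d = \frac{n}{n-1}(1 - \sum p_i^2)$; both follow the common
reporting conventions of population-genetics software. Sites containing `N`
are excluded *pairwise* (the least destructive option; the complete-deletion
alternative would discard whole columns), and indel columns are removed
completely by `exclude_indels()` before any statistic is computed. Ambiguity
codes other than `N` are rejected at import rather than silently recoded.
Haplotype collapsing compares sequences literally including `N` — two
sequences differing only by an `N` are distinct haplotypes — because any
merging rule would be inferential and order-dependent.

K2P distances use
$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ over comparable sites
and raise an error on saturation instead of returning `NaN`.

## Strict-clock dating

`upgma_tree()` (average-linkage agglomeration, node height = cluster
distance/2, lexicographic tie-breaks) and `height_to_time()` ($T = h/\mu$,
equivalently $T = d/2\mu$ for a pair) provide a transparent, deterministic
point estimate of divergence times. This deliberately replaces Bayesian
MCMC dating: the posterior machinery (tree priors, HPD intervals) is out of
proportion to what a point calibration needs, and the strict-clock kernel
makes the units auditable. Note the systematic difference: sequence
divergence predates population divergence by the ancestral coalescent depth,
so distance-based dates for recent splits are *older* than
population-history dates unless net distances are used
(`date_groups(..., net = TRUE)` subtracts the mean within-group diversity).

## Problem sizes and numerical choices

The validation experiments run at the scale of the motivating study design —
samples of $n = 50$ sequences of $k = 1{,}140$ bp under
$(\theta_0, \theta_1, \tau) = (1, 1000, 2.7)$, 100 fitting replicates,
100–200 simulation replicates per p-value, 100 bootstrap replicates per
goodness-of-fit call — chosen so the full suite completes on a single CPU in
minutes while keeping Monte-Carlo error well inside the asserted bands.
Expected-mismatch vectors are clipped at zero within numerical tolerance;
tail classes beyond the observed $d$ are available from `predict()` but SSD
is always computed over $0..d$ only. Degenerate inputs (monomorphic
alignments, single haplotypes, saturated distances) raise informative errors
at the statistic level and are downgraded to per-group warnings/`NA` by
`run_analysis()`.

## A complete run

```{r pipeline, eval = FALSE}
rep <- run_analysis(list(
  simulate = list(n = 50, k = 1140, theta0 = 1, theta1 = 1000, tau = 2.7),
  scenarios = "postglacial",
  reps = 1000, seed = 42))
rep
```

The report contains, per group, the diversity summary, the neutrality
statistics with simulation p-values, the mismatch fit with bootstrap
goodness of fit, and one rate per calibration scenario; the provenance block
records the configuration hash and seed, and reruns are byte-identical.

## Known limitations

* $\hat\tau$ absorbs $\theta_0$ on the flat ridge (see above); treat rate
  estimates from populations with substantial ancestral diversity as upper
  bounds on $\tau$-per-se.
* The OLS objective ignores the strong correlation between mismatch classes
  induced by the shared genealogy; p-values from the parametric bootstrap are
  calibrated, but parameter uncertainty is not quantified (no CIs on
  $\hat\tau$).
* Calibration scenarios are inputs: choosing among paleoclimatic anchors is
  a scientific judgment, not a computation.
* The strict-clock module dates sequence splits, not population splits.
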