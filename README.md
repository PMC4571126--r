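# expansionclock

Detecting sudden demographic expansions in haploid (mitochondrial) sequence
data and calibrating molecular evolutionary rates against paleoclimatic
expansion times.

Phylogeographic studies routinely date recent events with mtDNA, but the
apparent evolutionary rate depends strongly on the timescale over which it is
measured. When an independent calendar anchor for a population expansion
exists — e.g. postglacial forest recovery on a recolonized island — the
expansion signature in sequence data provides a calibration point. This
package implements that inference chain:

1. **Diversity and neutrality** — segregating sites, haplotype counts,
   nucleotide (π) and haplotype (Hd) diversity; Tajima's D and Fu's Fs with
   one-tailed p-values from coalescent simulation.
2. **Mismatch analysis** — the distribution of pairwise differences, fitted
   by least squares to the sudden-expansion (Rogers–Harpending) model
   F(τ, θ0, θ1), with parametric-bootstrap goodness of fit (SSD and
   Harpending's raggedness r).
3. **Rate calibration** — the core conversion t = τ/2u with u = μkg: given a
   fitted τ, an assumed expansion time t (years), sequence length k (bp) and
   generation time g (years), the rate is μ = τ/(2 t k g), reported in
   %/site/myr.
4. **Strict-clock dating** — UPGMA trees on K2P distances and T = d/(2μ)
   point estimates for group splits.
5. **Coalescent simulation** — a seeded instantaneous-expansion simulator
   (infinite-sites or finite-sites with transition bias) used throughout the
   validation suite and available as a data generator.

## Worked example

Simulate a Hokkaido-like expansion sample (n = 50 sequences, 1,140 bp,
θ0 = 1 → θ1 = 1000 at τ = 2.7) and run the full chain with the postglacial
calibration preset:

```r
library(expansionclock)
rep <- run_analysis(list(
  simulate = list(n = 50, k = 1140, theta0 = 1, theta1 = 1000, tau = 2.7),
  scenarios = "postglacial", reps = 1000, seed = 42))
rep
```

```
Expansion analysis report (1 group(s); config 4cc0b6d7, seed 42)

== Group all ==
  n=50 k=1140 S=51 h=34 pi=0.299% Hd=0.952
  Tajima's D=-2.420 (p=0.001)  Fu's Fs=-35.627 (p=0)
  tau=3.619  SSD=0.001017 r=0.02075  p_SSD=0.696 p_r=0.657
    post-YD 7 kyr              t=  7000 yr  mu= 22.7 %/site/myr
    early Holocene 10 kyr      t= 10000 yr  mu= 15.9 %/site/myr
    post-LGM 15 kyr            t= 15000 yr  mu= 10.6 %/site/myr
```

Reading the output: diversity is low (π ≈ 0.3%) while haplotype diversity is
high (34 haplotypes among 50 sequences, Hd = 0.95) — the star-like pattern of
a recent expansion. Both neutrality tests are strongly negative and
significant against 1,000 constant-size coalescent replicates. The mismatch
distribution is smooth (r = 0.02) and the sudden-expansion model is not
rejected (bootstrap p_SSD = 0.70). The fitted τ ≈ 3.6 sits near
τ_true + θ0 = 3.7: with a single sample, least squares cannot separate the
expansion age from ancestral diversity, so τ̂ tracks their sum (see the
vignette). Each calibration line then converts τ̂ into a rate; e.g. an
expansion assumed 10,000 years ago implies ≈ 16 %/site/myr — an order of
magnitude above the 2–4 %/site/myr obtained from interspecific fossil
calibrations, the expected time-dependence of mtDNA rates.

Real alignments enter the same way (`fasta = "aln.fasta"`, optional group
TSV), or piecewise:

```r
aln <- exclude_indels(read_fasta("cytb.fasta"))
diversity_summary(aln)
neutrality_test(aln, reps = 1000, seed = 7)
fit <- sudden_expansion(aln)
gof_test(fit, reps = 1000, seed = 7)
rate_table(coef(fit)["tau"], calibration_scenarios("postglacial"), k = aln$k)
```

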