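# mutbias

Analysis of how mutation rates and mutational biases evolve along a circular
bacterial chromosome, built for annotated mutation tables from long-term
evolution experiments sequenced as metagenomic time series (one row per
observed mutation: position, class, base change, gene, appearance time,
fate). It is aimed at experimental-evolution and microbial population
genetics researchers who want to go from such a table to the standard
battery of local-rate and bias analyses with explicit, tested nulls.

## What it computes

* **Mutation dynamics by class** — cumulative counts of point, indel and
  structural (IS-associated or not) mutations over time, with least-squares
  slopes between analyst-chosen breakpoints to quantify hypermutator and
  antimutator rate regimes.
* **Point-mutation spectra over time** — the twelve ordered base changes
  folded into the six strand-symmetric classes (A:T→C:G, A:T→G:C, A:T→T:A,
  G:C→A:T, G:C→T:A, G:C→C:G), counted in time windows; mismatch-repair loss
  shows as A:T→G:C / G:C→A:T excess, mutT loss as A:T→C:G excess.
* **The oriC-centered "wave"** — mutation densities in 46 equal bins on a
  coordinate axis centered on the replication origin, two-sample
  Kolmogorov–Smirnov comparisons of position distributions, and wave
  amplitude estimation (trough-to-peak ratio).
* **Gene-orientation bias** — an exact two-tailed binomial test of mutation
  counts in co-directional versus head-on genes against the
  coding-composition null: each mutation falls in orientation class *i*
  with probability *nt_i / (nt₁ + nt₂)*, the fraction of coding
  nucleotides in that class.
* **Gene-set depletion** — the closed form *P = (1 − t/g)ⁿ* for zero hits
  on a *t*-bp target among *n* uniform placements on a *g*-bp chromosome;
  an effective target size that rescales *t* by local binned mutation
  density; and a one-tailed placement-randomization test scanned over bin
  sizes from 100 kb to the whole chromosome.
* **Selection on gene sets (STIMS style)** — a one-tailed resampling test
  comparing a focal gene set's mutation count to random gene sets of equal
  cardinality (optionally length-matched).
* **Per-gene rate models by AIC** — one-parameter Poisson models
  *k_g ~ Poisson(c·L_g)* (uniform) versus *k_g ~ Poisson(c·θ_g·L_g)*
  (gene-specific diversity θ_s as a relative rate), fitted by closed-form
  maximum likelihood and ranked by AIC = 2k − 2·lnL.
* **A synthetic generator** — mutator-genotype timelines with class-specific
  rates and spectra, a symmetric cosine rate wave over oriC, and
  orientation bias, producing validated mutation tables with known ground
  truth for calibration and parameter recovery.

## Worked example

```r
library(mutbias)
rel606 <- GenomeLayout(4629812, oric_pos = 3886082, n_bins = 46L)

# Orientation bias of synonymous mutations summed over MMR-deficient
# populations: 2,066 vs 2,664 observed against 1,730,238 vs 2,066,587
# coding nucleotides
orientationBinomialTest(2066, 2664, 1730238, 2066587)
#> exact binomial test of orientation bias (two-tailed)
#>   statistic = 0.436786, p = 0.008975
#>   null: mutations fall in category 1 with probability
#>         1730238/3796825 = 0.45571 (coding-composition null)
#>   n = 4730
```

The observed fraction of mutations in the first orientation class (0.437)
is significantly below the 0.456 expected from coding composition alone
(p ≈ 0.009): more orientation bias than gene content explains.

```r
# Probability that a hypermutator with 4,368 non-synonymous mutations hits
# a 3,861 bp three-gene target zero times, under uniform placement
depletionProbability(3861, 4629812, 4368)
#> [1] 0.02614275
```

A population can leave a 3.9 kb target untouched by chance with only
~2.6% probability — evidence the target is depleted of mutations.

```r
# Simulate an MMR hypermutator (onset at 2,750 generations) carrying a
# wave of amplitude 0.5 (trough:peak = 25:75), then recover the amplitude
tl <- presetPopulations()[["Ara+3"]]
m  <- simulatePopulation(tl, rel606, genes = NULL,
                         wave = WaveParams(0.5), seed = 42)
nrow(m)                       # 3944 observed mutations
cnt <- binnedDistribution(m, rel606)$count
estimateWaveAmplitude(cnt, rel606, "cosfit")
#> [1] 0.528
```

The cosine-regression estimator recovers the simulated amplitude 0.5
within sampling error at ~3,400 point mutations.

## Documentation

See the methods vignette (`vignettes/mutation-rate-biases.Rmd`) for the
models, their assumptions, the synthetic generator's scope, and numerical
conventions (circular coordinates, bin edges, tie-breaking, p-value
corrections).
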