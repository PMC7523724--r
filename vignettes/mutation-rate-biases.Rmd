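---
title: "Local mutation-rate variation and bias on a circular chromosome: methods"
author: "mutbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local mutation-rate variation and bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutbias)
```

This vignette documents the models and conventions behind the package: how
the circular coordinate system works, what each statistical test assumes,
what the synthetic generator does and does not emulate, and the design
choices made where the underlying methodology left them open.

## The data model

The unit of analysis is an *observed mutation*: a variant detected in a
population's metagenomic time series, annotated with its chromosome
position, mutation class (`point`, `indel`, `sv`), base change (for
points), functional annotation, gene, appearance time in generations, and
fate (`fixed`, `extinct`, `polymorphic`). Appearance time — the first
generation at which the variant is reliably detected — is the time axis
everywhere; fixation dynamics are not modelled. Analyses default to
counting *every* observed mutation, fixations and doomed lineages alike,
because in large asexual populations many beneficial or neutral mutations
are outcompeted by clonal interference without that saying anything about
the mutation rate that produced them. Upstream variant calling and
allele-frequency trajectory inference are out of scope: the package
consumes their output table.

## Circular coordinates, bins, and orientation

Coordinates are 1-based and inclusive. Position `p` maps to a signed
offset from the replication origin in `(-L/2, L/2]`, computed modulo the
chromosome length `L`; the antipodal point resolves to `+L/2`. Replichore
1 is the arc from oriC in the increasing-coordinate direction to the
antipode. The chromosomal terminus is not part of the data model; the
antipode stands in for it, which is accurate to the extent replication
terminates opposite the origin (a testable sensitivity, not a verified
fact, for any particular genome).

Binning partitions the offset axis into `n_bins` equal *real-valued*
widths `L / n_bins` (46 by default, roughly 100 kb for an *E. coli*-sized
chromosome, whose length is typically not divisible by 46). A position's
bin is `floor(((offset + L/2) mod L) / width)`. This is gap-free and
deterministic; every bin receives `floor(L/n_bins)` or
`ceiling(L/n_bins)` positions; with an even bin count oriC falls at the
left edge of bin `n_bins/2` (the first bin right of center), and the
antipode wraps to bin 0 — the same physical point as the left edge,
circularly.

A gene is *co-directional* when its transcription direction equals the
travel direction of the replisome through it (strand `+1` on replichore
1, or `-1` on replichore 2), and *head-on* otherwise; head-on genes
suffer replication–transcription conflicts. The gene's midpoint decides
its replichore. Genes spanning oriC or the antipode have no single
replisome direction; they are flagged `NA` with a warning and excluded
from orientation tallies. The orientation null for mutation counts is the
*coding composition*: the number of coding nucleotides per orientation
class, i.e. gene density weighted by gene length. Overlapping genes are
counted once per gene (the tally is about per-gene coding sequence, and
the overlapping bases are reported); a strict mode refuses overlaps.

## Statistical tests

**Orientation binomial test.** With `k₁:k₂` mutations observed in the two
orientation (or strand) classes and `nt₁:nt₂` coding nucleotides, the
null is Binomial(`k₁+k₂`, `nt₁/(nt₁+nt₂)`). The two-tailed p-value uses
the minimum-likelihood method — the sum of probabilities of all outcomes
no more probable than the observed one — which is the convention of
standard exact-test implementations (`stats::binom.test` provides the
computation; the test suite checks it against a from-scratch enumeration
oracle). This null deliberately ignores the mutator's base-change
spectrum interacting with per-gene base composition; a spectrum-adjusted
null would need per-gene composition stratified by class and is not
implemented.

**Kolmogorov–Smirnov comparison.** Two sets of mutation positions are
compared on the oriC-centered axis with the asymptotic two-sample KS
test; `D` is the ECDF supremum over raw positions, not binned counts
(binning discards within-bin information; a binned chi-square variant is
provided as a non-default alternative). `D` is invariant under any common
strictly monotone remapping of both samples, so centering affects
interpretation, not the statistic.

**Gene-set depletion.** Zero hits on a target of `t` bp among `n`
independent uniform placements has probability `(1 − t/g)ⁿ`, evaluated in
log space. Because a target in the trough of a rate wave is expected to
collect fewer hits anyway, the *effective* target size multiplies each
gene's length by its bin's mutation density relative to the genome mean
(length-weighted across bins for genes spanning an edge); under exactly
uniform density it equals the physical size. The randomization version
re-places the `n` mutations by a multinomial draw over bins with the
empirical bin probabilities, uniform within bins, and counts placements
in the gene set; with one whole-chromosome bin this *is* the uniform
null, which is how the test is validated against the closed form. The
default mutation filter for depletion analyses is missense + indel +
structural (synonymous changes are excluded as the neutral marker class);
the filter is an explicit argument. The randomization scheme itself is a
design choice — a placement null, as opposed to the gene-set resampling
null below — and both are named in each result's null description.

**Gene-set selection test (STIMS style).** The focal statistic is the
number of (optionally annotation-filtered) mutations in a named gene set;
the null resamples gene sets of equal cardinality from the annotation and
recomputes it. Cardinality matching follows the resampling convention of
gene-level parallelism tests; an optional length-matched mode
(accept/reject on total length within a tolerance) is offered because
target size drives expected counts when gene lengths vary widely. Lower
tail = purifying selection, upper = positive selection. All randomization
p-values use the `(1 + b)/(1 + n_boot)` correction and are therefore
never zero; all randomization functions require a seed and are
reproducible bit for bit.

**Per-gene rate models.** Synonymous counts per gene are modelled as
`k_g ~ Poisson(c·L_g)` (uniform rate) or `k_g ~ Poisson(c·θ_g·L_g)`,
where `θ_g` is a per-gene synonymous nucleotide diversity from natural
isolates treated as a relative rate per bp. Both models have exactly one
free parameter, the scale `c`, with closed-form MLEs `Σk/ΣL` and
`Σk/Σ(θL)` (cross-checked against numerical optimization to 1e−8). AIC
= 2 − 2·lnL; with `k = 1` shared and the `Σ ln k_g!` term common to both
models, ΔAIC depends only on the fitted means — the package tests this
cancellation explicitly. Genes missing from the θ table are dropped from
*both* fits (the comparison must be on identical data, enforced through a
data fingerprint), with the dropped count reported. Gene length defaults
to the full annotated length; a synonymous-site length column is used
when supplied. A gene with `θ_g = 0` but observed mutations makes the θ
model's likelihood zero; this is reported as `lnL = −∞` rather than
patched.

## The synthetic generator

The generator produces tables with the statistical structure the analyses
assume, with known ground truth:

* **Timelines.** Piecewise-constant regimes (`MutatorTimeline`): per
  interval, class-specific rates (expected observed mutations per
  generation per population) and a six-class spectrum. Counts per
  interval are Poisson(rate × duration) — not fixed-n — so cumulative
  series show realistic stochasticity; appearance times are uniform
  within intervals.
* **Wave.** The positional rate multiplier is
  `m(d) = 1 − A·cos(2πd/(L/2))`, `d` = circular distance to oriC: a
  symmetric two-peak cosine with troughs at oriC and the antipode and a
  trough-to-peak ratio `(1−A)/(1+A)`, so `A = 0.5` gives 25:75. The
  cosine form and the trough-at-oriC phase follow the
  mutation-accumulation literature on origin-centered rate waves; the
  underlying data constrain symmetry, not functional form, so users
  fitting real data should treat both as assumptions.
* **Orientation bias.** A factor `β` multiplies the rate inside head-on
  genes (β = 1 unbiased). Positions are drawn by rejection sampling
  against `m(d)·β(pos)`, so the realized orientation ratio converges to
  the β-weighted coding composition.
* **Annotation.** Genic point mutations are labelled
  synonymous/missense/nonsense with probabilities 0.25/0.70/0.05 by
  default — an arbitrary, documented split, not a biological fit —
  noncoding outside genes; structural variants are IS-associated with
  probability 0.8; fates are drawn as 0.30/0.55/0.15
  fixed/extinct/polymorphic.

The twelve presets (`presetPopulations()`) emulate the qualitative
mutator histories of the twelve LTEE populations over 60,000 generations:
which repair pathway broke, when (taken from the curated allele
appearance times, e.g. mismatch-repair loss at 2,750 generations for the
Ara+3-like preset), the phase-variation reversion that restores the
Ara−2-like preset's ancestral rates exactly, mutY-loss spectrum shifts
toward G:C→T:A, and IS-element structural mutators including the
three-slope structural regime of the Ara−3-like preset. The *rates* are
chosen once, not fitted: baseline rates give a nonmutator on the order of
10² observed mutations over the experiment and an MMR hypermutator a few
thousand, matching the magnitudes such experiments report.

What the generator does **not** emulate: within-population lineage
structure and clonal interference (competing clades with different rates
appear only as their marginal rate regimes), linkage between mutations,
context-dependent rates at finer scale than the wave, GC-skew
asymmetries between replichores, and the detection filters of real
metagenomic pipelines. Tests passing on synthetic data therefore validate
the *statistical machinery* — nulls, estimators, calibration — not any
claim about a particular biological dataset.

## Numerical conventions and degenerate inputs

* Antipode offset ties resolve to `+L/2`; the antipode bins with bin 0.
* Bin edges are real-valued; positions are integers; per-bin position
  counts differ by at most one.
* Multinomial/binomial placement nulls are vectorized; identical seeds
  give identical results to the bit.
* Zero trials (binomial), empty samples (KS), zero genome-wide mutations
  (effective target size) and zero-length simulation horizons are errors,
  not NAs; `n_boot < 100` warns about unstable p-values.
* All-zero counts fit cleanly in both Poisson models (`c = 0`,
  `lnL = 0`, AIC = 2).
* Spectrum folding complements both bases when the reference base is a
  pyrimidine; the 12 ordered pairs map 2-to-1 onto the six classes.

## Problem sizes used by the test suite

The suite validates calibration properties at sizes chosen to balance
statistical resolution against a fast default run: the uniform-null
goodness of fit uses ~5,000 mutations per seed over 20 seeds; wave
recovery uses ~50,000 mutations per seed (20 seeds in the end-to-end
suite, 3 in the unit tests); the gene-set selection calibration uses 200
replicate neutral datasets with 1,000 resamples each (the analysis
default remains 10,000 resamples); model-selection consistency uses 100
genes × 100 seeds. These are the package's chosen test conditions and are
stated here so users know what the green suite does — and does not —
demonstrate.

## Known limitations

* The interface is R functions plus the acceptance script; there is no
  shell subcommand wrapper.
* Head-on/co-directional assignment near the terminus inherits the
  antipode-as-terminus assumption; genomes with displaced termini need a
  layout with an adjusted length or external orientation calls.
* The orientation binomial null ignores mutator spectrum × base
  composition interactions (documented above).
* Multi-base substitutions are not modelled; the import adapter drops
  point records whose base change cannot be parsed as a single-base pair,
  with a message.
* The θ-model comparison is only as good as the supplied θ table; no
  uncertainty in θ is propagated.
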