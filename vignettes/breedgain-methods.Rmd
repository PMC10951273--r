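---
title: "Models and methods behind breedgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind breedgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedgain)
```

`breedgain` chains together the quantitative-genetics machinery used to
document long-term genetic change in a clonally propagated crop such as
strawberry: relationship matrices, single-step BLUP breeding values,
change-point regression of breeding values on birth year, replicated-trial
mixed models with genetic-gain contrasts, and genomic prediction of cross
means and variances. This vignette explains each model, the tunable
parameters, the synthetic data generator that the test suite runs the whole
chain against, and the numerical and design choices that were genuinely
open.

## Relationship matrices

The pedigree numerator relationship matrix **A** is built by the tabular
method over a topologically sorted pedigree: `a(i,i) = 1 + a(s,d)/2` with
unknown parents contributing zero, and `a(i,j) = (a(j,s) + a(j,d))/2` for
previously processed `j`. Inbreeding is `F = diag(A) - 1`. Cycles are
detected before any arithmetic and reported with the offending ids.

The genomic matrix **G** follows VanRaden's first method:
`W = dosage - 2p` per marker and `G = WW' / (2 * sum p(1-p))`. Allele
frequencies are computed from the genotyped panel itself, since no
base-population frequencies are available for a historical genealogy; the
consequence is that G is expressed relative to the current panel rather
than the founders, which the single-step tuning step (below) corrects
against A. Missing dosages are mean-imputed (`2p`) for G only; QC
(`qc_genotypes()`) first drops markers with minor allele frequency below
0.05 or missingness above 0.10 — both thresholds are arguments, and these
defaults are the conventional array-QC values for this crop.

The unified single-step matrix **H** replaces the genotyped block of A and
its cross-terms:

* optional tuning solves `mean(diag(a + bG)) = mean(diag(A22))` and
  `mean(offdiag(a + bG)) = mean(offdiag(A22))`, putting G on A's scale;
* blending `Gb = (1-w) G* + w A22` with `w = 0.05` by default guarantees an
  invertible genotyped block;
* the block identity `H22 = Gb`, `H12 = A12 A22^-1 Gb`,
  `H11 = A11 + A12 A22^-1 (Gb - A22) A22^-1 A21` fills in the rest.

Tuning on and `w = 0.05` follow common single-step practice; both constants
are recorded in the matrix metadata so a run is self-describing.

## Single-step BLUP

Breeding values solve `y = 1 mu + Z g + e` with `g ~ N(0, H sigma2_g)` and
`e ~ N(0, I sigma2_e)`, where `y` holds one estimated marginal mean per
phenotyped hybrid (unweighted; weighting by the EMM standard error is
deliberately not the default because the trial design here is nearly
balanced and the published analysis treats EMMs as plain observations).
Variance components are estimated by REML profiled over the ratio
`theta = sigma2_e / sigma2_g`: after projecting out the intercept the
restricted likelihood depends on theta only through the eigenvalues of the
phenotyped block of H, so a one-dimensional grid-plus-golden-section search
over `log theta` in [-14, 14] (tolerance 1e-10) is exact, deterministic and
cheap. BLUPs, prediction error variances and accuracies
(`1 - sqrt(PEV/sigma2_g)`, clipped to [0,1] with a clip flag) come from the
V-inverse form of the mixed-model equations; the test suite checks them
against an independent dense MME solve. PEVs require a dense inverse, so
`fit_ssblup()` refuses problems beyond `max_ids = 5000` individuals instead
of approximating silently; raising the limit is an explicit user decision.

Individuals with no phenotype and no informative relatives shrink to 0 —
the model's population mean. GEBVs are therefore reported as deviations
from the fitted intercept; every downstream regression on birth year is
invariant to that centering.

## Trial analysis

`fit_trial_lmm()` delegates REML to `lme4` and marginal means to
`emmeans` — the standard tools for this design — behind a stable surface.
With hybrids fixed, the model is
`value ~ hybrid + (1|block) + (1|year) + (1|hybrid:year)` plus location
terms when more than one location is present; single-level factors are
dropped automatically. With hybrids random, the variance components feed
the clone-mean broad-sense heritability

`H2 = s2_G / (s2_G + s2_GxY/y + s2_GxL/l + s2_GxYxL/(ly) + s2_E/(rly))`

with `r` the harmonic-mean replicate count per hybrid and environment.
Genetic-gain contrasts between extreme hybrids report
`dG = EMM_1 - EMM_2`, `dG% = dG/EMM_2 * 100`, a t statistic with
Satterthwaite degrees of freedom combined from the two EMM standard errors,
and a Bonferroni adjustment over two tests per trait (the two
low-benchmark choices). EMM degrees of freedom use the Satterthwaite method
up to 60 hybrids; beyond that its per-mean cost grows quickly and the
asymptotic normal reference is used (the `df` argument overrides either
way). AUDPS disease scores extend the trapezoid AUDPC with the endpoint
term `(y_1 + y_n)/2 * D/(n-1)`.

## Change-point analysis

`fit_changepoint()` fits a two-segment linear model continuous at a single
knot, scanning every observed candidate year exhaustively and minimizing
the error sum of squares; ties break to the earliest year so output is
deterministic. Candidates must leave `guard = 5` observations and two
distinct years per side, which keeps degenerate one-sided fits out of the
search. The flat-then-trending trajectory expected of breeding values is a
special case the model recovers when the data demand it. A discontinuous
variant (`continuous = FALSE`) exists for sensitivity analysis: when a
series genuinely jumps, the continuous model places its knot roughly one
generation interval early, and comparing the two fits diagnoses that.
Change-point uncertainty is reported by a seeded case-resampling bootstrap
(percentile interval, 200 resamples by default) rather than a posterior,
keeping the estimator free of prior choices.

Percent changes of the fitted population mean are computed from predicted
values at the range start, the change point and the range end:
`(yhat_cp - yhat_start)/yhat_start * 100` and
`(yhat_end - yhat_cp)/yhat_cp * 100`, with per-year rates obtained by
dividing by the segment lengths. The additive-variance trend re-runs the
change-point machinery on `sqrt((y - yhat)^2) = |residual|`; a positive
post-knot slope indicates growing dispersion of breeding values.

Production series (yield, area, production against calendar year) use
ordinary least squares, and percent changes between two predicted values
follow the same arithmetic; `trend_from_coefficients()` lets published
regression coefficients be evaluated without the raw series.

## Cross prediction

`estimate_marker_effects()` is ridge-regression BLUP,
`effects = W'(WW' + lambda I)^-1 (y - mu)` on centered dosages, with
`lambda` estimated by REML on the equivalent kinship model unless supplied.
`simulate_cross()` generates each progeny as one recombinant gamete per
phased parent, recombining between adjacent markers with Haldane
probabilities `c = (1 - exp(-2d/100))/2` from the map's centimorgan
distances, without interference — the standard progeny-simulation
assumption. `predict_cross()` scores progeny as
`intercept + sum_j (dosage - center) * effect` and reports the progeny mean
and the `n-1` variance over `n_progeny = 200` simulated offspring.
Reciprocal crosses are exchangeable by construction. For real, unphased
parents `parent_phase()` draws a random phase consistent with the dosages
and flags it: between-site linkage in the parent is then not preserved,
which inflates apparent recombination and should be interpreted
accordingly. `compare_eras()` labels a cross pre-era only when both parents
were born in or before the threshold year (1953 by default, the
conventional break between the random-mating and directional-selection
phases of the emulated program).

## The synthetic breeding program

The generator exists so the entire chain can be exercised against known
truth. It produces a pedigree spanning 1775–2015, phased haplotypes
gene-dropped through it with Haldane recombination, true breeding values,
and replicated-trial phenotypes with the block/year/interaction variance
structure the trial model assumes.

Defaults, chosen once to emulate a long-lived clonal program of the
strawberry type and frozen before the recovery harnesses were run at full
replication:

* 40 founders in 1775 with site-wise independent haplotypes at allele
  frequencies uniform on [0.05, 0.95] (no founder LD; LD accrues from the
  pedigree);
* 3 crosses per year with 4 progeny each, parents drawn from the cohorts of
  the previous 15 years — short cycles, as in clonal fruit breeding;
* exotic accessions (fresh draws from the base-population frequencies)
  enter with probability 0.5 per year until 35 years after the selection
  onset, emulating the steady germplasm influx of the pre-modern era and
  the closure of an elite population once a breeding program matures;
* random parent choice until `cp_year = 1953`; from then on truncation
  selection on true breeding value, with intensity phasing in linearly over
  10 years to the default selected fraction of 0.5. The ramp models a
  program scaling up rather than switching on overnight; an instantaneous
  switch puts a step discontinuity in the breeding-value trajectory that a
  continuous change-point model systematically antedates by about one
  generation interval (the discontinuous variant recovers such a step
  correctly, which is how we diagnosed it);
* a trait architecture with a configurable number of effect loci among the
  markers, effects drawn from a multivariate normal across traits (shared
  loci induce the genetic correlations), oriented so the minor founder
  allele is favorable and scaled by `(2p(1-p))^(-1/2)` — the classic
  inverse effect-size/frequency pattern. Under directional selection rare
  favorable alleles climb towards intermediate frequency, which sustains
  long-term response and makes post-onset crosses segregate more additive
  variance than pre-onset crosses, the qualitative signature the era
  comparison tests for. One designated marker acts as a dominant
  day-neutrality locus (carrier bonus on its trait), supporting the 3:1 and
  1:1 segregation checks;
* a genotyped subset (training hybrids plus 25% of the remainder) with 2%
  missing dosages.

What the generator does **not** emulate: founder linkage disequilibrium,
population structure beyond the migrant stream, non-additive architecture
beyond the single dominant locus, mutation, selection on estimated (rather
than true) breeding values, and genotyping error. Passing tests therefore
demonstrate that the estimators recover truth under the model's own
assumptions — pedigree-consistent inheritance, additive trait control,
balanced trials — not that they are robust to the full messiness of real
array data and unbalanced multi-decade phenotype archives.

## Problem sizes and determinism

The shipped test-suite and acceptance harnesses use a program of roughly
1,500–3,000 individuals and 500–1,000 markers, 20-seed batches for every
stochastic recovery claim, 1e5 gene drops for the pedigree oracle, and
200-progeny crosses; these sizes give stable medians while keeping a full
run in minutes on a single core. Every stochastic operation consumes a
named substream derived from one integer seed, so identical configuration
and seed reproduce byte-identical artifacts — the pipeline writes an md5
manifest (`manifest.json`) to make that checkable.

## Known limitations

* The change-point model fits a single knot; multi-phase histories are out
  of scope.
* PEV-based accuracies inherit the H scale; comparing accuracies across
  relationship matrices of different base populations is not meaningful.
* The ridge marker-effect model assumes an additive panel; the dominant
  flowering locus is deliberately mis-specified under it (its effect is
  absorbed additively), mirroring how such loci are treated by
  whole-genome regression in practice.
* Estimated effects can only be informative for markers segregating in the
  training set; predicted variances of deep-pedigree crosses are
  correspondingly conservative.
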