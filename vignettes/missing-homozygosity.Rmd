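---
title: "Detecting recessive embryonic lethals by missing homozygosity"
author: "lethalScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recessive embryonic lethals by missing homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalScan)
```

## The problem

A fully recessive embryonic lethal allele never appears in homozygous state
among live, genotyped animals: affected embryos die in utero, usually
before implantation. In a closed breeding population the allele is
invisible at the individual level but leaves two population-level
signatures:

1. the haplotype on which it segregates shows a **deficit of homozygotes**
   relative to its frequency, and
2. matings between two carriers (CxC) produce litters reduced by up to the
   Mendelian 25%, without any excess of stillborn or mummified piglets.

`lethalScan` turns these signatures into a tested pipeline: a haplotype
scan, recombinant fine mapping, candidate-variant filtering by
co-segregation and linkage disequilibrium, fertility-impact arithmetic,
and Wright-Fisher simulation of the underlying population genetics. A
synthetic-data generator reproduces the statistical structure the scan
assumes, because the genotype and litter records of real nucleus
populations are proprietary.

## The scan model

Phased genotypes are viewed as `2N` haploid allele sequences over a marker
map. Within a sliding window, a haplotype is an exact allele-vector match;
an animal missing any call in the window is excluded from that window's
counts (exact matching admits no partial evidence). For a haplotype with
`k` copies among the `2N` counted haploids, frequency `f = k/(2N)`:

* **Expected homozygotes (frequency method)**: `E_f = N f^2` by
  Hardy-Weinberg; when all carriers are heterozygous this is `C^2/(4N)`
  for `C` carriers. Homozygous carriers, if any, contribute two copies to
  the allele count before squaring.
* **Expected homozygotes (trio method)**: each genotyped offspring of two
  heterozygous-carrier parents is homozygous with Mendelian probability
  `0.25`; the default mode counts only such CxC offspring, so
  `E_t = 0.25 * n_CxC`. An extended mode substitutes the population
  haplotype frequency for parents of unknown status — this mode is this
  package's extension and is never the default.
* **Deficit test**: one-sided lower-tail exact binomial,
  `p = P(X <= O)` with `X ~ Bin(N, f^2)` (frequency parameterization) or
  `X ~ Bin(n_CxC, 0.25)` (trio parameterization). For `O = 0` the former
  collapses to `(1 - f^2)^N`. Published scans of this kind print exact
  binomial p-values whose precise parameterization is typically not
  recoverable from the reports; the package therefore defines its test
  explicitly as above and treats printed p-values as indicative, not as
  reproduction targets.

Windows of 0.5, 1, 2 and 5 Mb slide with a step of half the window length
— a geometric ladder covering the span lengths at which such haplotypes
have been reported. Haplotypes below 0.5% frequency are not tested
(`minHapFreq`); significance is declared at raw `alpha = 5e-3` per test,
the threshold customary for this scan. The number of tests and a
Bonferroni-adjusted level are attached to the result as advisory
attributes; no adjusted filtering is applied, because the raw threshold is
part of the method being implemented.

### Merging and haplotype extension

The same lethal haplotype triggers many overlapping windows at several
scales. Significant window-haplotypes are merged into one candidate when
their spans intersect and their carrier sets agree. Agreement is measured
by the **overlap coefficient** (intersection over the smaller set) at
threshold 0.8, not by the Jaccard index: a short window nested inside the
haplotype matches, besides the true carriers, a tail of animals whose few
markers coincide by chance; these chance matches inflate the union and can
push the Jaccard index below any fixed threshold even though the two
windows tag the same lethal.

Each merged candidate is then re-expressed as a single haplotype across
the union of its windows: the carrier-defining haploids of the most
significant window are followed outwards and their per-marker consensus
becomes the candidate allele vector. The consensus is trimmed where
per-marker agreement among those haploids falls below 0.9 — the shared
haplotype ends where the flanking sequence becomes individual-specific.
The long vector is vastly more specific than any single window, so the
final carrier set is free of chance matches; counts, frequency and the
deficit test are recomputed for it. The most significant window's bounds
are retained inside the reported span.

### Fine mapping

Carrier animals that are homozygous for part of the candidate haplotype
prove that that part cannot harbour the lethal. `finemapRecombinants`
splits the span into consecutive 1 Mb sub-haplotypes, excludes any
sub-haplotype observed homozygous among carriers, and returns the maximal
remaining contiguous interval. Ties between equally long runs resolve to
the leftmost run; sub-intervals containing no markers provide no evidence
and are retained; a candidate whose every sub-haplotype is excluded is
returned with missing bounds and the full exclusion mask — a contradiction
worth inspecting, not an error.

### Marker quality control

`qcFilter` drops animals below 70% call rate first, then markers with
MAF <= 0.01, call rate < 0.85, or an exact Hardy-Weinberg test p-value
below `1e-5`. The HWE threshold is deliberately liberal: markers tagging a
lethal haplotype are themselves mildly out of equilibrium, and a stringent
filter would remove the very signal the scan needs. A strict re-scan mode
(e.g. `hweAlpha = 1e-30`) is available as a sensitivity check. The exact
HWE test is the standard conditional enumeration of heterozygote counts
given allele counts, implemented here because no installed dependency
provides it; it is validated in the tests against a Monte-Carlo allele
permutation oracle.

## Candidate-variant filtering

For a candidate haplotype and an annotated variant panel sharing animal
identifiers, `candidateVariants` applies four criteria: distance (within
5 Mb of the haplotype span), a maximum of one homozygous-alternate animal
(one false genotype assignment tolerated), carrier co-segregation
(heterozygous in haplotype carriers, absent from non-carriers, one
discordant animal tolerated), and dosage LD `r^2 >= 0.8` with the
haplotype dosage. The default threshold is 0.8 with 0.7 supported — both
values circulate in this literature and neither is canonical; results at
0.7 are always a superset of results at 0.8, a monotonicity the tests
assert. Ranking puts splice, frameshift, stop and start-loss classes
first, deleterious missense second, everything else third, ordered by
`r^2` within rank. An empty result is a valid outcome — some lethal
haplotypes tag no coding candidate at all. `r^2` is the squared Pearson
correlation of dosages over complete pairs (the convention of standard
association toolkits); constant vectors yield a missing value with a
warning rather than an error.

## Drift simulation

Allele-frequency change is modelled per generation as deterministic
viability selection followed by binomial sampling of `twoN` haploid draws
(`p' = Bin(twoN, p*) / twoN`). For genotype fitnesses `(w_AA, w_Aa, w_aa)`
with A the focal allele,

    p* = (p^2 w_AA + p(1-p) w_Aa) / (p^2 w_AA + 2p(1-p) w_Aa + (1-p)^2 w_aa),

which for the fully recessive lethal `(0, 1, 1)` reduces to
`p* = p/(1+p)`; the package uses that closed form directly in the lethal
case (it is defined at `p = 1`, where the general ratio is a removable
0/0). Zero mean fitness in any other configuration is an error.

Two population sizes appear deliberately side by side: drift intensity is
governed by `twoN = 300` haploid draws (an effective size of 150
diploids, the magnitude estimated for intensively selected pig lines),
while the de novo mutation start frequency uses the census denominator
(one copy among 2050 diploids, `1/4100 ≈ 0.024%`). The two knobs are
independent in `DriftConfig` because they describe different things — the
variance of reproduction and the arithmetic of a single new mutation — and
the reconstruction keeps both at their stated values. Replicates default
to 1000 for trajectory summaries; persistence estimates use 10,000 or more
for tighter intervals. "Segregating" means strictly `0 < p < 1`; under
lethality fixation is impossible, so loss is the only absorbing fate.

`equilibriumSegregating` estimates the mutation-drift-selection balance by
injecting `Poisson(2 * census * U)` new lethal loci per generation, each
evolving independently under the same update, and time-averaging the
number above a detection floor (default 2%, roughly the minimum frequency
a large-cohort scan can see) after burn-in. It is exposed as a simulation
estimate; no closed-form target exists for it.

## Fertility impact

`impactTable` reproduces the standard impact arithmetic: reduction
`(TNB_CxNC - TNB_CxC)/TNB_CxNC`, affected-litter fraction = squared
carrier frequency (random mating), piglet loss = observed CxC litters
times the TNB difference, population death fraction = affected x
reduction, and per-litter population reduction = mean TNB x death
fraction. Inputs are the published rounded summaries when reproducing
printed tables, which is why an optional `affected` override column
exists: a published affected-litter figure may derive from an unrounded
carrier frequency and then cannot be recovered from the rounded one —
supplying the printed figure keeps downstream sums consistent. CxNC
litters pool both carrier-sire and carrier-dam matings; the genotype-ratio
validation test is a plain Pearson chi-square against 1:2:1 (df = 2, no
continuity correction — the convention that reproduces published litter
p-values) plus a lower-tail exact binomial for the homozygote count.
`heterosisAttribution` divides the population TNB reduction by the
purebred-to-crossbred litter difference, clipping at 1 with a warning.

## What the generator emulates — and what it does not

`simulateFounders` + `plantLethal` + `simulateGenerations` produce: a
two-tier population (50 boars, 2000 sows by default; census 2050),
biallelic phased markers at 50K-chip density (20 markers/Mb over a 50 Mb
autosome) with founder allele frequencies uniform on [0.1, 0.5] —
reflecting the common-variant ascertainment of array content — a lethal
allele riding one founder haplotype (complete LD with a `hostWindowBp`-
wide region, default 2 Mb; no homozygous founder), Poisson litters with
Mendelian segregation in which mutant homozygotes die pre-implantation,
truncation at uterine capacity, ~50% replacement per generation with
sex-balanced random selection of replacements, and Poisson crossovers at
1 cM/Mb with uniform breakpoint positions. Phase is known by construction
because parental origin is tracked; a real pipeline would obtain it from
statistical phasing, whose switch errors are *not* simulated. Only
breeding animals (founders and replacements) are genotyped, mirroring a
nucleus population in which commercial offspring are not.

The litter model calibrates the embryo-to-term survival probability so
that non-carrier matings average `litterMean` (default 14.18 total born)
whatever the ovulation/capacity regime: survivors of lethality are
truncated at `uterineCapacity` and then thinned binomially. With infinite
capacity, CxC litters converge to exactly 75% of non-carrier litters; with
ovulation exceeding capacity the loss of homozygous embryos is partially
compensated and the observed reduction falls below 25%, shrinking further
as the ovulation excess grows — the mechanism proposed for why observed
reductions (15-21%) undershoot the Mendelian expectation. Background
stillbirth and mummification rates (7% and 1% of total born) are
independent of carrier status; only that independence matters, the levels
are nominal. Litter sizes are Poisson before truncation — the simplest
count model consistent with a reported mean.

Not emulated: phasing and genotyping error, imputation, the X chromosome,
selection on breeding values, variation in litter-size heritability,
multi-breed structure, and linked selection. Passing tests therefore show
that the *method* behaves correctly under its own assumptions, not that
real data meet those assumptions.

## Numerical choices and degenerate inputs

* Coordinates are 1-based bp internally; reports print Mb to one decimal.
* The exact HWE p-value accumulates all heterozygote counts whose
  conditional probability is at most that of the observed count, with a
  `1 + 1e-9` relative tie tolerance; probabilities are normalized from
  log-space for stability. Monomorphic markers return 1.
* `deficitTest(O, n, p)` is `pbinom` directly — no approximation at any
  size used here.
* Windows with fewer than two markers are skipped with a warning;
  all-missing windows yield empty enumerations; an all-markers-removed QC
  result is an explicit error, as is a scan on unphased input or an
  extinct simulated population.
* The scan is invariant to animal ordering (carrier sets are sorted;
  tests assert invariance). Fixed seeds make every simulator bit-identical
  across runs.
* `plantLethal` guarantees zero lethal homozygotes even against
  astronomically unlikely coincidences by flipping one allele on the
  untouched haploid of any accidental homozygote.

## Problem sizes used by the test suite

Unit tests run on populations of 50-2,000 animals with 120-400 markers.
The end-to-end recovery test uses 5,000 animals and 1,000 markers with a
lethal planted at 13% carrier frequency — a deliberate scale stand-in for
cohorts an order of magnitude larger, chosen because the expected
homozygote count it implies (~21) already separates a true lethal from
noise by many orders of magnitude in the deficit test. Drift properties
use 1,000-20,000 replicates. These sizes are the package's own choices
for a thorough-but-quick default run; all are configurable upward.

## Known limitations

* Exact-match haplotype identity ignores partial information from animals
  with missing calls; an imputation-aware matcher would recover them.
* The trio expectation requires recorded, genotyped parents; the extended
  mode's frequency substitution for unknown parents is a pragmatic
  extension without a published reference implementation.
* At the raw `alpha = 5e-3` of this scan, borderline false-positive
  candidates (deficit p just under threshold, expected counts of 5-10)
  are expected in genome-sized scans; the advisory Bonferroni column and
  the trio-based test are the intended triage tools.
* The equilibrium lethal-load estimate depends on the interplay of census
  size, effective size and detection floor; it is a simulation, not an
  identity, and is reported as such.
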