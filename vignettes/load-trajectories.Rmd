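---
title: "Methods: inbreeding and load trajectories through a bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inbreeding and load trajectories through a bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohload)
```

This vignette documents the statistical model behind each estimator in
`rohload`, the assumptions those estimators make, the design choices that
were genuinely open, and what the synthetic cohort generator does and does
not emulate.

## The analysis callset

All estimators consume a `cohort_callset`: biallelic SNPs, sorted by
(chromosome, position), with a per-sample dosage in {0, 1, 2, NA} counting
**derived** alleles. Derived status is defined against an outgroup base
(`polarize_to_ancestral()`): if the outgroup carries the currently counted
allele the dosage flips (`d -> 2 - d`); if it carries the other allele the
dosage is unchanged; if it matches neither allele the site cannot be
polarized and is dropped (with a count). Polarizing against an outgroup
rather than the reference assembly avoids the reference bias that arises
when modern samples are more similar to the assembly than historical ones.

Site and genotype filters (`apply_site_filters()`) follow a conservative
resequencing pipeline: site QUAL ≥ 30; SNPs within 5 bp of an indel
removed; repeat/CpG BED masks (read as 0-based half-open and converted to
the 1-based inclusive convention used internally); sex-linked scaffolds
excluded; per-genotype depth required to lie within [mean/3, 2 × mean] of
the sample's mean depth; heterozygotes kept only when the REF-read
fraction lies within [0.2, 0.8]. Two choices deserve note:

- **Depth filtering is per genotype, not per site.** A single low-coverage
  sample marks its own genotype missing instead of deleting the site for
  everyone; the complete-case restriction then decides the site's fate.
  This matches the per-genotype semantics of the caller's DP field.
- **Idempotence.** Per-sample mean depths are computed once and cached on
  the callset, so re-applying the same filter specification is a no-op;
  this keeps filter provenance auditable (each filter reports its removal
  count separately).

Load and frequency statistics are computed on the **complete-case**
callset (every sample genotyped at every site), so allele-count
denominators are constant across sites and no bootstrap over allele
counts is needed.

## Diversity and inbreeding

Heterozygosity is reported as heterozygous sites per 1,000 bp of callable
sequence — direct counting from filtered genotypes. When no per-base
coverage model exists (synthetic data, or a pre-filtered SNP panel), the
callable length defaults to the number of sites passing filters; both
modes are exposed because only the user knows the true denominator.

Windowed nucleotide diversity uses non-overlapping 10-kb tiles (the common
default of the window-based VCF tools; the span is configurable). Per
site, π adds `2 p (1 - p) n / (n - 1)` with `n` the non-missing
haplotypes — exactly the mean pairwise difference among called alleles,
which the test suite verifies against exhaustive all-pairs enumeration.
Whether π should pool all samples or be computed per population is not
fixed by the estimator; the default is per population, since the cohort
mixes time points and demes whose diversities are the quantities of
interest.

ROH detection re-implements the PLINK-style sliding-window scan with an
explicit, fully specified semantics:

1. every window of `window_snp` consecutive SNPs with at most
   `window_het` heterozygous and `window_missing` missing calls is
   homozygous;
2. a SNP is ROH-eligible when at least `window_threshold` (default 5%) of
   the **full** windows containing it are homozygous;
3. maximal runs of eligible SNPs are split where the inter-SNP gap
   exceeds `gap_kb`;
4. runs are kept when they contain ≥ `min_snp` SNPs, span ≥ `min_kb`,
   average ≤ `density_kb` per SNP, and contain ≤ `max_het_in_segment`
   heterozygous calls.

At chromosome ends only full windows are scored; a chromosome shorter
than one window yields no eligible SNPs. The reference tool's behaviour at
ends is a known dialect point, so the package treats its own brute-force
oracle — direct enumeration of windows and runs under rules 1–4 — as the
authoritative semantics and proves equivalence on hundreds of randomized
instances (up to 2,000 SNPs) in the test suite. Segment spans are measured
first-SNP to last-SNP inclusive, not window bounds. Three parameter
presets ship: windows of 500/250/100 SNPs tolerating 5/3/1 heterozygous
calls respectively, all with threshold 0.05, ≥ 25 SNPs, ≥ 100 kb, ≤ 50
kb/SNP density, ≤ 1,000 kb gaps and ≤ 750 heterozygous calls per segment;
`"main"` is the 500/5 setting. `window_missing` defaults to 0 because the
analysis callset is complete-case; it is exposed for other inputs.

*F*<sub>ROH</sub> divides the summed length of segments above a threshold
(100 kb for total inbreeding, 2 Mb for recent inbreeding) by the analysed
autosomal genome length, which must be supplied by the user (it is a
property of the assembly, not of the SNP panel).

Group contrasts (heterozygosity, *F*<sub>ROH</sub>, load) use Tukey HSD
from a one-way ANOVA — appropriate for all-pairs comparison of three
groups with familywise error control; the test suite re-derives the
p-values from the studentized-range distribution directly.

## Mutational load

**Relative load (GERP mode).** For a score category, the statistic is
Σ(score × dosage) / Σ(dosage) over the individual's derived sites: a
dosage-weighted mean conservation score, with heterozygotes counted as
one allele and homozygotes as two. It is invariant to site order and
recombines across chromosomes as a weighted mean (tested). Score bins are
[0,1) ("neutral"), [1,3), [3,5), >5, with a top category for scores above
the top-1% threshold (5.88 by default) that overrides >5, making the
reported categories disjoint. Negative scores are excluded from load —
putatively unconstrained sites. When an individual carries no derived
allele in a category the ratio is undefined and reported as `NA`,
deliberately distinct from 0.

**Total load** counts an individual's derived variants per impact
category. "Sum of variants" is ambiguous between sites and alleles; the
package defaults to site counts and exposes an allele-count mode, and the
summary table reports both.

**Realised load** is n<sub>hom</sub> / (2 S<sub>category</sub>), the
fraction of the category's segregating variation an individual expresses
in homozygous state. Two choices:

- S is defined on the **cohort** complete-case callset by default so
  values are comparable across individuals; a per-population denominator
  is available (`denominator = "population"`) since either convention is
  defensible.
- The numerator is restricted to the same segregating sites that define
  S, which makes the 0.5 bound structural (attained exactly when the
  individual is homozygous at every segregating category site).

No dominance-aware fitness modelling of observed genotypes is attempted:
the zygosity breakdown is reported, but converting it into fitness would
require dominance coefficients the data do not contain.

## R_xy and variant sharing

For category C and populations x, y with per-site derived frequencies
f<sup>x</sup>, f<sup>y</sup>:

Freq<sub>x</sub>(C) = Σ<sub>i∈C</sub> f<sup>x</sup><sub>i</sub> (1 −
f<sup>y</sup><sub>i</sub>), and R<sub>xy</sub> =
Freq<sub>x</sub>/Freq<sub>y</sub>. R<sub>xy</sub> = 1 means no frequency
change; the reciprocity R<sub>xy</sub> · R<sub>yx</sub> = 1 follows from
the formula and is asserted to 1e-12 in tests.

The site-inclusion rule was a genuinely open choice. Requiring at least
one derived allele *in each* population would exclude every
population-unique variant — the very variants a sharing analysis is
about — so the default includes sites with at least one derived allele in
the **pooled** x+y sample (under which sites monomorphic ancestral in
both populations contribute nothing anyway); the stricter rule is
available as `site_rule = "each"`.

Uncertainty comes from a delete-one-chromosome jack-knife: chromosomes
are the natural exchangeable unit under linkage, and only chromosomes
contributing included sites enter. Both leave-one-out estimates and
pseudo-values are reported, since either may be wanted for plotting; the
jack-knife mean and standard error come from the pseudo-values. With
`freq_y = 0` the ratio is reported as `Inf` (and `NA` when both sums are
zero) rather than an arbitrary number.

Sharing summaries count presence (f > 0), fixation (f = 1), sharing,
uniqueness and the direction of frequency change per site; the identities
shared + unique<sub>a</sub> = total<sub>a</sub> (and the b analogue) are
property-tested.

## The synthetic cohort generator

`simulate_cohort()` is a forward diploid Wright–Fisher simulator whose
default configuration *is* the study design the package assumes: a
stable source population (40 generations at N = 500), a crash (10
generations at N = 50), one generation as a **single breeding pair**,
geometric recovery to N = 60 over 10 generations, a translocation moving
20 individuals to found a second population, and 15 further generations
of complete isolation; 13 "historical" individuals are sampled before the
crash, and 9 + 20 moderns at the end. The template mirrors the shape of a
near-extinction-and-rescue narrative at desk scale — the absolute census
numbers of any real system are not reproduced, and no attempt is made to
calibrate effective sizes of the recovery phase.

Model choices, each of which the invariants in the test suite exercise:

- **Selection convention.** s ≤ 0 is deleterious; fitness is
  multiplicative across sites with factors 1, 1 + hs, 1 + s for 0/1/2
  derived copies. Offspring survive with probability equal to their
  fitness **relative to the fittest candidate of their generation** (soft
  viability selection). Soft selection keeps selection differentials
  intact while preventing a genome-wide standing load from starving the
  census demography — with absolute viability, a population carrying
  realistic numbers of weakly deleterious alleles would spuriously
  "go extinct" even though selection among siblings is the relevant
  force. Hard demographic failure is still represented: a generation in
  which every candidate has fitness zero aborts with an error naming the
  generation.
- **Effect classes.** Sites draw a class (neutral/low/moderate/high) from
  a configurable mixture; each class carries its s, h and a conservation
  score drawn uniformly from a class-specific range, with the high class
  confined to the top GERP bin (> 5.88). Defaults: probabilities
  0.90/0.05/0.035/0.015, s = 0/−0.002/−0.02/−0.2, h = 0.5/0.5/0.3/0.05 —
  weakly deleterious mutations are common and additive, strongly
  deleterious ones rare and recessive, the standard shape of the
  deleterious mutation spectrum.
- **Initialization from standing variation.** Forward simulation from a
  monomorphic population cannot build equilibrium diversity within a
  desk-scale run at a realistic mutation rate, so generation zero seeds
  `n_init_sites` segregating sites (default 10,000 over 6 × 2 Mb, about
  one SNP per 1.2 kb — comparable to the SNP density of a real
  resequencing panel) with derived counts drawn from the neutral 1/i
  site-frequency spectrum at uniform-random positions, assigned to
  haplotypes independently (no initial linkage disequilibrium). Selected
  classes also start from this neutral SFS, which overstates their
  initial frequencies; forward selection then acts on them. This is a
  deliberate simplification — the generator is a test bed for the
  estimators, not a calibrated model of any species.
- **Genetics.** Mutation at rate 2.3e-9 per bp per generation (a direct
  passerine-lineage estimate) on an infinite-sites grid with collisions
  redrawn; recombination as Poisson crossovers (1e-8 per bp, 1 cM/Mb)
  with independent assortment across the 6 chromosomes — which is what
  makes chromosomes valid jack-knife units downstream.
- **Reproducibility.** One seeded RNG stream per run; identical
  (config, seed) pairs give byte-identical output files (tested via
  checksums). Mutation is applied to the surviving offspring's gametes
  after viability selection; at the configured rates a first-generation
  selective effect on de-novo mutations would be negligible.
- **Emission.** Sampled individuals are copied (museum specimens are dead
  to the population, but at these sample sizes removal would perturb the
  demography more than it adds realism). All sites segregating among
  emitted genomes become callset sites; sites fixed derived in every
  emitted genome are dropped and counted, mirroring what a variant caller
  polarized against an outgroup would emit as invariant.

What the generator does **not** emulate: sequencing reads and their
errors (dosages are emitted directly; optional per-genotype error and
missingness rates exist but default to 0), realistic avian karyotypes
(macro/micro-chromosome structure), background-selection or
linked-selection realism, gene structure (impact categories are site
labels, not consequences of codon changes), and any calibration of
census-to-effective size. Passing tests therefore demonstrate that the
estimators measure what they claim on data with known truth — not that
any particular wild population behaves like the defaults.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based inclusive internally (VCF convention); BED
  masks are converted at the boundary.
- Half-open [lo, hi) binning everywhere (GERP bins, ROH length spectra);
  a value exactly on an edge joins the bin it opens.
- Undefined ratios (no derived alleles; no segregating sites;
  Freq<sub>y</sub> = 0) are `NA` or `Inf` markers, never silent zeros.
- Degenerate inputs fail loudly and specifically: unknown samples or
  populations, unsorted or duplicated sites, empty complete-case
  callsets (warning), single-chromosome jack-knifes, groups with fewer
  than two values in Tukey contrasts.

## Problem sizes in the test suite

The validation suite runs the full default cohort (6 × 2 Mb, 10,000
standing sites, 42 samples) and, for replicate-based checks, smaller
variants chosen to keep statistical power while finishing quickly: 20
replicates of an all-neutral cohort (4 × 0.5 Mb, 2,000 sites) for the
neutrality martingale (derived-allele counts conserved through the
bottleneck within 5%); 20 replicates at 4 × 1 Mb / 4,000 sites with the
100-SNP ROH preset for the direction of the *F*<sub>ROH</sub> and
heterozygosity shifts; 20 replicates of a 20-generation, N = 50 cohort
under strong additive selection (s = −0.5, h = 0.5) on the high class for
the R<sub>xy</sub> purging direction; and 200 randomized instances of up
to 2,000 SNPs for exact ROH oracle equivalence. These sizes are the
package's own validation design and are stated here so they can be
scaled up by anyone wanting tighter Monte-Carlo tolerances.
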