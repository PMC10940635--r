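---
title: "Time-series QTL mapping in advanced intercross lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-series QTL mapping in advanced intercross lines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailqtl)
```

## The problem

Two closely related inbred mouse lines can differ substantially in body
weight while sharing almost all of their genome, including major obesity
loci fixed in both.  Crossing them and intercrossing the offspring for many
generations — an advanced intercross line (AIL) — accumulates
recombinations that break the genome into short founder-line mosaics, so a
single-marker association scan can localize the remaining small-effect
loci.  Because weight is recorded weekly anyway, scanning *every* weekly
measurement instead of only the terminal one reveals loci whose effect
grows, fades, or responds to environmental changes such as a diet switch.

`ailqtl` implements that analysis end to end for a two-founder AIL of `n`
males weighed weekly from weaning (week 3) to week 25, genotyped in two
stages: a genome-wide array on the phenotypic extremes, then targeted
single-SNP assays on the remainder at the top markers of an initial scan.

## Data model and conventions

* Genotype calls are coded `2` (homozygous for the founder-1 / S1 allele),
  `1` (heterozygous), `0` (homozygous founder-2 / S2).  By convention S1 is
  the line whose allele increases weight, which fixes the sign of every
  effect estimate downstream.  `GenotypeMatrix` extends
  `RangedSummarizedExperiment`: markers are rows with a `GRanges` map
  (1-based bp, strictly increasing within a chromosome), animals are
  columns.
* Weekly weights (grams, positive, missing allowed) live in a
  `PhenotypeSeries` (animals × weeks).
* The feeding protocol is a `dietSchedule()`: standard chow weeks 3–20,
  high-fat/low-carbohydrate weeks 21–22, high-fat/high-carbohydrate weeks
  23–25.

## Preprocessing

**Outliers.** A measurement is removed when it deviates from its week's
population mean by strictly more than 3 SD.  The mean and SD are computed
once per week over all non-missing values — a single pass, not iterated.
The rule is applied per week, not per animal trajectory, because the
population mean is the stated reference; a consequence (tested) is that
re-applying the rule to its own output can remove additional values, so the
single-pass contract is part of the interface.

**Markers.** A marker is kept when at least two genotype classes are
observed and its missing rate is at most 10% (configurable).  This QC
belongs to the array stage: in a two-stage design it must run *before* the
merge, because animals genotyped only at targeted markers are missing
everywhere else and would push every array-only marker over any missing-rate
threshold.

**Two-stage merge.** `mergeTwoStage()` unions the animal sets on the
array's marker map.  Targeted markers then carry calls for (nearly) all
animals while array-only markers keep the array subset — the source of the
abrupt per-marker sample-size changes, and hence LOD discontinuities,
visible at targeted markers.  Conflicting duplicate calls are an error, not
a vote.

## The scan

For each week and marker, the default test is a one-way fixed-effects ANOVA
with genotype as an (up to) three-level factor.  The model family matches
how AIL effects are reported — per-class means ± SD with absolute and
percent contrasts — and makes no additivity assumption; a least-squares
regression on the additive codes 0/1/2 is available as an option.  Evidence
is expressed as `LOD = -log10(p)`.  Weeks are scanned independently; no
longitudinal covariance model is fitted, which keeps each week's result
interpretable on its own and mirrors how the time-series scan is read
(significance traced week by week).

Genotype classes with fewer than `min_class_n = 5` animals are excluded
from a marker's test; a marker with fewer than two usable classes is
flagged `tested = FALSE` rather than silently given `p = NA`.  The F
statistic is computed vectorised from per-class sums and sums of squares;
the test suite verifies it against `stats::lm`/`anova` on random data to
ten decimal places.  Percent effects use the reference class as
denominator: `100 * (mean_S1S1 - mean_ref) / mean_ref`.

## Multiple testing: simpleM

Markers in an AIL are heavily correlated, so Bonferroni over the raw marker
count would be far too strict.  The effective number of tests is estimated
from the eigenvalue spectrum of the marker correlation matrix: markers are
partitioned chromosome-wise into consecutive map-ordered windows of at most
820 markers (disjoint, never spanning chromosomes; a final short window is
kept as-is), missing calls are mean-imputed per marker, and each window
contributes the smallest number of leading eigenvalues whose sum reaches
`C = 0.995` of the total — the published simpleM default, exposed as a
parameter.  Negative eigenvalues from numerical noise are clamped to zero.
The genome-wide LOD cutoff at level α is `-log10(α / m_eff)`; with
`m_eff = 849` this gives 4.23 and 4.93, the conventional "significant" and
"highly significant" cutoffs (4.2 / 4.9 at one decimal):

```{r}
bonferroniLodThresholds(849)
```

Whether the original windows were disjoint or sliding is not derivable from
the window-size statement alone; disjoint windows are implemented and
documented here.  The estimate is invariant to flipping any marker's allele
coding (correlation signs change, eigenvalues do not) — a property test.

## Support intervals and cross-week aggregation

A week's support interval is the 1.5-LOD-drop interval: starting from the
chromosome's top marker, walk outward while the LOD stays within 1.5 of the
top, then snap the bounds to the positions of the *first markers beyond*
that contiguous run (or the terminal markers).  The contiguous-run reading
is deliberate: a disjoint secondary peak elsewhere on the chromosome never
extends the interval.  Ties at the top break by smaller p, then smaller bp.
In a two-stage run the walk is performed on a scan restricted to the
array-genotyped animals, whose uniform sample size keeps the LOD profile
comparable along the map.

The final QTL interval takes the smallest start and highest end across
weeks.  "Across all measured weeks" is ambiguous when some weeks show no
signal: a flat-profile week's 1.5-LOD interval is essentially the whole
chromosome and would swamp the aggregate.  The default therefore
aggregates over genome-wide significant weeks only, with
`only_significant = FALSE` available and the weekly table always retained.
`significanceSpan()` reports maximal runs of consecutive significant weeks,
the structure that exposes a QTL which disappears across a diet switch and
reappears afterwards.

## Candidate prioritization

Genes overlapping the final interval (any overlap, 1-based inclusive) are
scored additively over: variant-consequence categories (deleterious or
tolerated domain missense — with SIFT < 0.05 overriding the label when a
score is present — UTR, promoter, enhancer, CTCF binding, splice site, each
assessed within a configurable ±1000 bp padding at annotation time),
differential expression per tissue (BH-adjusted p < 0.05), and KEGG pathway
membership supplied as a boolean flag.  The upstream decision-tree weights
are not published in reusable form, so the scheme is a configurable
additive surrogate.  The packaged default weights (9 / 5 for
deleterious/tolerated missense, 3 for promoter, 1 elsewhere) reproduce the
published candidate ordering on the bundled fixture — Gpt > Cbx6 > Apol6 =
Apol8 and Trap1 = Rrn3 > Mapk1 — which is the calibration target; the
absolute scores are not.  Two fixture choices deserve note: the published
table's checkmark-to-gene column alignment is typographically ambiguous for
one CTCF entry, which the fixture assigns to Apol6 (under the literal
reading Cbx6 and Apol8 would carry identical flag sets yet different
published scores, impossible for any additive scheme); and Trap1/Mapk1 are
flagged as pathway members.  Ranks are dense, ties share a rank and are
ordered by gene id.

## ChoRE motif scanning

A QTL whose significance dips exactly across a carbohydrate-poor diet phase
suggests carbohydrate-responsive regulation, so interval genes are scanned
for carbohydrate-response elements: ChoRE-a `CACGAG(N)5CACGAG` and ChoRE-b
`CACACC(N)5CACGCG` (17 bp, 12 informative positions).  The consensus is
turned into a unit-weight PWM: informative positions weight 1 on the
consensus base, `N` columns are all-zero and never affect the score.  The
window score is the fraction of matching informative positions, and
"min.score = 90%" is interpreted as ≥ 90% of the maximum achievable PWM
score — with unit weights, at most one mismatch in 12 passes (11/12 ≈
0.917).  This deterministic reading reproduces the published
one-informative-mismatch reverse-strand site upstream of *Sun2* and is
cross-checked in the tests against `Biostrings::matchPWM` at
`min.score = "90%"`.

The 2000 bp upstream of each gene-level TSS is extracted in promoter
orientation (`[tss-2000, tss-1]` for `+` genes, reverse complement of
`[tss+1, tss+2000]` for `-` genes, truncated at chromosome ends) and both
strands are scanned; hits are mapped back to forward-genome coordinates and
letters.  Transcript-level TSS choices (the published site sits in the
5'UTR of some transcripts) are out of scope: the gene-level TSS is used.

## The synthetic AIL generator

Every statistical claim above is tested against data with known truth.
`simulateAilGenotypes()` drops gametes through the pedigree: founders are
opposite-homozygous at every marker (so all markers are informative), the
F1 is fully heterozygous, and each later generation is formed by random
pairing that avoids self- and full-sib matings whenever an alternative
exists (the original randomized-mating scheme's internals are not
published; this is documented as an approximation).  Recombination uses the
Haldane map function at 0.5 cM/Mb — the pipeline's statistics do not
require the real mouse map, only realistic LD decay.  Defaults emulate the
study: F10, 397 males, ~5,171 markers over the 19 mouse autosomes.

`simulateWeightSeries()` builds
`weight = growth mean + QTL effects + polygenic + residual`.  The growth
mean is logistic (asymptote 45 g, rate 0.21/week, inflection week 9),
chosen to track the published weekly population means from ~10 g at
weaning to ~47 g at week 25.  QTL and polygenic contributions scale with
the growth fraction (mean/asymptote) so genetic effects mature with the
animals; the default QTLs mirror the two published loci (adult homozygote
contrasts 5.4 g and 4.2 g).  A QTL may carry an attenuation window —
default multiplier 0.2 over weeks 21–23, the high-fat/low-carbohydrate
phase plus the first week after the second switch — reproducing the
disappear/reappear significance pattern; a per-phase multiplier alone
cannot express the observed window, which ends mid-phase.  Residual SD
interpolates from 1 g at weaning to 3 g at adult weight and the polygenic
SD is 2.5 g, giving a combined adult within-class SD close to the published
3–4.5 g.  What the generator does *not* emulate: litter and cage effects,
X-chromosome and sex effects (males only), epistasis, genotyping error, and
real marker ascertainment — so passing tests demonstrate calibration and
power of the statistics under a faithful breeding design, not robustness
to those nuisances.

## Numerical choices and degenerate inputs

* p-values are floored at `1e-300` before LOD conversion so underflow never
  produces infinite LODs; `p ≤ 0` is an error by contract.
* An all-identical phenotype week gives F = 0, p = 1, LOD 0 — not an error.
* Zero-variance markers are excluded from simpleM windows with a warning; a
  window reduced to nothing contributes 0.
* Tie-breaks are explicit everywhere (top SNP: p, then bp, then week;
  ranking: gene id; extreme selection: animal id) so every result is
  deterministic given the inputs.
* Weights are clamped to a 0.1 g floor in the simulator only to satisfy the
  positivity invariant; with realistic noise the floor is never reached.

## Problem sizes used in the shipped checks

The package's own calibration checks run at reduced, fixed scales chosen to
make their Monte-Carlo error small relative to the margins being asserted:
power/coverage/diet-split use 20 replicates of 397 animals × 500 markers
over five 100-Mb chromosomes; null calibration uses 1000 null tests (200
markers × 5 independent null traits, markers spread over 20 chromosomes so
between-test correlation stays modest) and 200 replicate no-QTL genome
scans of 200 animals × 100 markers for the family-wise error of the
simpleM-Bonferroni threshold.  Full study scale (5,171 markers, 19
autosomes) runs through exactly the same code paths via `simConfig()`
defaults.

## Known limitations

* No kinship/mixed-model correction: an AIL has pedigree structure, and the
  plain ANOVA scan relies on the intercross randomization plus the
  empirical null calibration shipped in the tests.  Cofactor/multiple-QTL
  models are out of scope.
* Interval mapping between markers is not performed; support intervals snap
  to marker positions, so their resolution is the local marker density.
* The prioritization weights are a surrogate calibrated to an ordering, not
  a reimplementation of the original decision tree.
* The full published dataset (array genotypes and weekly weights) is an
  external download; reproducing its exact headline numbers (m_eff = 849,
  top LOD 11.84, the interval endpoints) requires those files, while every
  check shipped here runs on synthetic data.
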