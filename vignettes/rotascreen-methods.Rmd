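---
title: "Methods: simulating and analyzing an ENU rotarod screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing an ENU rotarod screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotascreen)
```

## The screen this package models

A forward-genetics motor screen induces random point mutations in male
mice with the chemical mutagen ENU, breeds the mutations to homozygosity
(a G1 male carrying ~60 heterozygous coding/splicing mutations is crossed
to C57BL/6J females; his G2 daughters are crossed back to him, so each G3
grandchild can be homozygous-variant, heterozygous or homozygous-reference
at every site), and phenotypes G3 mice on an accelerating rotarod — six
trials per mouse, hundreds of mice per week, concurrent untrained
wild-type controls every week. Genotyping all family members at all
mutation sites supports three analyses this package implements: detection
of recessive lethal alleles from distortion of Mendelian ratios, mapping
of rotarod phenotypes to individual mutations, and screen-level rate
arithmetic (how often does a homozygous mutation produce outlier motor
performance, and what does that imply for spontaneous mutation?).

Because the real screen data live in an external database, the package is
organized around a synthetic-data generator whose planted ground truth
(which mice are non-learners, which mutation is a superperformance allele,
which alleles are lethal) makes every downstream stage testable.

## Normalization

Fall latencies are only comparable within a testing week: equipment,
testers and animal batches drift. Two standardizations are provided, both
anchored to the week's untrained wild-type controls:

* **Normalized scores** (used for genetic mapping): each raw latency is
  multiplied by the week's scaling factor, `100 / mean(wild-type raw)`,
  so the weekly wild-type mean is exactly 100. The scaling factor is
  trial-matched by default; a single pooled weekly factor derived from
  trial-6 wild-type means is available (`scaling = "pooled"`) because the
  screen's description of "mean wild type performance" does not fix which
  trial feeds it.
* **T-scores** (used for behavioral analysis): `T = 50 + 10·Z`, with Z
  computed per week and per trial against the wild-type mean and SD, so
  wild-type T-scores have mean 50 and SD 10 by construction. A
  whole-cohort reference is available (`reference = "cohort"`); the
  wild-type anchor is the default because it makes the T-scale's meaning
  ("every 10 units is one wild-type SD") independent of the mutant mix.

Statistics are always computed on unsmoothed scores. The 2-trial median
filter (each value replaced by the median of itself and its left
neighbor, the median of two being their mean; the first trial keeps its
value, having no left neighbor) exists to display learning trajectories
and to stabilize the clustering features.

## The latency model

Simulated fall latency is linear in trial:

latency(i, t) = baseline_i · mult_i + slope_i · (t − 1) + load_i(t) +
tester(week, tester) + noise,  truncated at 0.

* `baseline_i ~ N(35, 6)` seconds and `slope_i ~ N(4, 0.45)` s/trial,
  correlated at −0.3 so poor starters learn faster (the inverse relation
  between initial performance and learning rate the screen reports). At
  these values a wild-type mouse's trial-6 latency (~55 s) corresponds to
  a maximum linear speed of ~1.0 m/min on a 3-cm rod accelerating at
  1 rpm per 8 s from 4 rpm — the control-level top speed. A linear form
  was chosen because it makes the average learning rate (the mean of
  successive differences, which telescopes to `(t6 − t1)/5`) recover the
  slope exactly.
* `mult_i` multiplies the baseline by `effect_size_performance` of every
  carried effect mutation whose inheritance mode is satisfied (recessive:
  homozygous only; dominant: any copy; additive: square-root multiplier
  per heterozygous copy). The default planted superperformance allele is
  recessive with multiplier 1.4, the scale of the strongest
  superperformance contrast observed on this apparatus (≈1.0 → 1.4 m/min).
* `load_i(t)` shifts trial t by `−0.05 / 10 · sd_wt(t)` seconds per
  homozygous mutation carried — i.e. a constant −0.05 displacement on the
  T-score scale per homozygous mutation, implementing the slight but
  systematic deterioration of performance with mutation load.
* Tester effects are additive constants per (week, tester) with SD 2 s,
  the batch structure the weekly normalization exists to remove; trial
  noise is i.i.d. N(0, 1.5²) seconds.

**Non-learners.** A fraction (8%) of G3 mice is drawn as a stereotyped
non-learning mode: slope ~ N(0, 0.15), baseline shifted +5 s with 0.3× the
usual baseline spread — higher first-trial performance, no gain across
trials, and low within-group variability. This idealization is
deliberate. The screen's PCA of 22,509 real mice shows two
*density-separated* clusters, and a density-based algorithm (DBSCAN) can
only reproduce that structure if the generator actually produces an empty
valley between the modes; with broadly overlapping Gaussian phenotypes no
radius separates them at any cohort size (the valley fills as n grows).
Passing the clustering-recovery tests therefore demonstrates that the
pipeline correctly recovers a density-separated subpopulation — it does
not certify performance on real data, where trial-to-trial variability is
larger and the group boundary may be genuinely fuzzy.

**Pedigree counts.** The 40–60 G3 mice per pedigree are the *observed
yield* of the cross, so the generator tops up litters until that many
conceptuses survive recessive lethality (penetrance 1 by default,
configurable for partial distortion). Lethality therefore distorts the
observed genotype ratios — the footprint the distortion test looks for —
without shrinking pedigrees. Post-weaning survival declines mildly with
homozygous load (`0.99 − 0.004 · n_VAR`, floored at 0.5). The X
chromosome is never mutagenized (G3 X chromosomes descend from wild-type
dams), matching the screen's design; an `x_mutation_rate` hook exists for
spontaneous X-linked mutations but defaults to 0.

## Clustering

Features per mouse: the six trial T-scores, five successive differences,
average learning rate, initial (mean of trials 1–2) and final (trial 6)
performance, early rise (t3 − t1), late rise (t6 − t4), and average
performance. For clustering, features are computed from median-smoothed
curves (statistics stay unsmoothed); each feature is min–max normalized
to [0, 1]; PCA (covariance, via `stats::prcomp`) reduces to two
components; DBSCAN with `min_pts = 10` clusters the scores. The larger
cluster is the learning group, the second the non-learning group;
anything else is noise and belongs to neither (the screen's own analysis
reports no noise class — ours reports it separately rather than forcing a
label).

`eps` is chosen from the k-distance curve in two stages: the classic
chord elbow, then geometric growth (steps of 1.15) to the largest radius
at which at least two clusters remain. The bare elbow sits at the dense
cluster's periphery and systematically under-covers the sparser second
cluster; growing until just before the density modes merge recovers its
border members while never crossing the inter-cluster valley. On planted
two-blob data this rule assigns >99% of points to exactly two clusters;
on simulated screens it recovers planted non-learners with mean recall
≈0.97 and precision ≈1 across seeds.

Group comparisons are the screen's: a one-sample t-test of the
non-learning group's average learning rate against zero, and Welch tests
between groups for learning rate, initial, final and average performance
(`stats::t.test`; zero-variance groups yield NA).

## Genetic mapping

The published screen maps phenotypes with a dedicated linkage tool whose
statistic is not specified in the source describing this screen; the
package substitutes a transparent per-mutation least-squares scan within
each pedigree, under three genotype codings (recessive VAR=1, additive
dose 0/1/2, dominant carrier=1), reporting effect, SE and two-sided p per
mutation × model, Bonferroni-corrected within pedigree by default. The
implementation is a closed-form simple regression (cross-checked against
`stats::lm` in the tests); the recessive model requires ≥3 homozygotes,
matching the screen's reporting threshold for homozygous testing.

The default mapping phenotype is the per-mouse **mean normalized score
over the six trials**. A single-trial phenotype (selectable trial, as the
screen's figures use for individual genes) is available, but a latency
multiplier acts on every trial, and at realistic effect sizes (multiplier
1.4, ~6 homozygotes per pedigree) the 6-trial mean roughly triples the
mapping signal-to-noise; with it, the end-to-end pipeline ranks a single
planted allele first in ≥8 of 10 seeded 20-pedigree screens, which the
single-trial phenotype cannot do.

Candidates are ranked by (p ascending, |effect| descending, homozygote
count descending) — a deliberately simple, auditable stand-in for the
screen's machine-learning candidate scorer, which is out of scope here.

**Lethality.** For each mutation, the expected homozygote fraction among
genotyped G3 offspring is computed from each mouse's dam genotype
(heterozygous dam → 1/4, reference dam → 0; only het-dam offspring are
informative). A one-sided exact binomial test (`stats::binom.test`,
lower tail) flags deficits below the Bonferroni threshold
`α / mutations-in-pedigree`. The test is one-sided because an excess of
homozygotes is not the phenotype sought. At typical pedigree sizes
(~25 informative offspring) a fully penetrant lethal sits near the
corrected threshold — single-pedigree lethality detection is genuinely
marginal at this scale, which is why the tests exercise the stated
40-informative-offspring case.

**Saturation.** The fraction of genes carrying a severely damaging
mutation (damage classes `probably_damaging` + `probably_null` by
default) brought to homozygosity in ≥5 G3 mice each tested 6 times,
against a 25,000-gene universe (24,000 autosomal). Both the autosomal and
all-chromosome fractions are reported; with an unmutagenized X the
autosomal fraction is necessarily the larger. Synthetic screens at desk
scale reach ~1% saturation, not the tens of percent of a multi-year
screen — the tests therefore verify the estimate against an independent
brute-force recount rather than any absolute level.

## Outliers, rates, evolution

Outlier performance is one-sided: values above mean + 3 SD of the scanned
cohort (the screen derives the 3-SD rule from wild-type data, in which no
mouse strays that far; both the cohort default and a wild-type reference
are supported, and a two-sided option exists). Rates are reported with
raw numerators and denominators — mice per outlier and homozygous
mutation calls per outlier — so rounding is always auditable.

The load analysis bins mice by homozygous mutation count, reports
per-bin means and the coefficient of variation, and fits performance,
initial score and learning rate against count restricted to counts ≤ 15,
the point beyond which performance variability changes drastically in the
screen's data (configurable). The survival fit is least squares of
survivors per count bin on `a + b·ln(count)`, counts ≥ 1 only.

The evolutionary calculator reproduces the screen's printed arithmetic
verbatim: for spontaneous rate r = 7.9×10⁻⁹ per bp per replication,
homozygous probability r² = 6.24×10⁻¹⁷; multiplied by the
behavior-modifying fraction *as printed* (0.15 for performance, 0.27 for
learning — the percentage figure used as a bare factor) gives
9.36×10⁻¹⁸, expressed as 1.19×10⁻⁷ % (performance) and 2.13×10⁻⁷ %
(learning) of mutations per replication. A `strict_percent` mode divides
the factor by 100 for users who want the literal percentage
interpretation. Five published rate presets are bundled
(`rate_table()`).

## Numerical and design notes

* All randomness flows from one seed expanded into independent per-stage
  streams; changing clustering settings never perturbs simulation draws,
  and identical configuration + seed reproduces every numeric field.
* Latencies are stored in seconds, speeds in m/min, trials are 1-based
  (trial 1..6), weeks are 1-based integers.
* The interchange format is four TSV tables (pedigree, mutations,
  genotype long-form, phenotype) with fixed column order and id-sorted
  rows, so repeated writes are byte-identical. The pedigree table carries
  a `dam_id` column: dam genotypes define which offspring are informative
  for the distortion test.
* Degenerate inputs are first-class: weeks without wild-type controls and
  zero-SD references are errors naming the week/trial; constant feature
  columns are dropped with a warning; constant genotype codings, single
  survival bins and zero-variance groups yield NA/flagged results rather
  than failures; zero outliers yield flagged infinite rates.
* Problem sizes in the test suite (6–40 pedigrees for most properties,
  400 pedigrees ≈ 20,000 G3 mice for load-slope recovery and scan
  calibration) were chosen as the smallest cohorts at which the checked
  contrasts are statistically decisive.

## Known limitations

* The latency model is linear with Gaussian noise; real learning curves
  saturate and real noise is heteroscedastic and occasionally censored at
  the trial cap.
* The non-learning mode is idealized as compact and well-separated (see
  above); recovery metrics on real data would be lower.
* Linkage uses marginal per-mutation regressions: co-segregating mutations
  in one pedigree produce tied signals that are reported, not
  disambiguated.
* Damage classes are simulated labels, not sequence-derived predictions;
  saturation fractions at desk scale are illustrative.
* The lethality test treats mutations independently; linked lethals on
  one chromosome would violate that assumption.
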