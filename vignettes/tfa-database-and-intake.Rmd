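---
title: "Building a trans fatty acid composition database and estimating dietary intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a trans fatty acid composition database and estimating dietary intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfaintake)
```

## The problem

National food composition tables often omit trans fatty acids (TFA), so
estimating a population's TFA intake requires first constructing a TFA
content value for every food a cohort might report eating. `tfaintake`
implements the complete workflow: a four-step hierarchical assignment that
attaches a TFA value *with provenance* to every food in a composition
table, an intake estimator that converts multi-day semi-weighed diet
records into per-subject mean intakes, stratified descriptive summaries,
and a synthetic-data generator that emulates every input with known ground
truth so the whole pipeline is testable without proprietary data.

## The assignment hierarchy

Every food receives exactly one TFA value, from the first rule that can
produce one:

* **Zero rule.** A food with at most a trace of fat (default 0.1 g/100 g,
  the resolution at which composition tables report fat), or containing
  neither partially hydrogenated oils nor ruminant-derived ingredients, is
  assigned exactly 0: those are the only two dietary TFA sources.
* **Step 1 — analytic literature.** Values measured by gas chromatography
  are converted to g/100 g of food by rescaling the reported
  TFA-per-total-fat ratio with the composition table's own fat content:
  `tfa_g_100g = (tfa / fat in reference) * fat_g_100g`. When the article
  omits the fat content of its samples, the table's fat is used on both
  sides of the ratio. One single-sample article contributes its value; one
  multi-sample article its mean; several articles a mean weighted by each
  article's sample count. An article that does not state its sample count
  can stand alone but is dropped from weighted pooling (the weight is
  unknown); two or more such articles with nothing else is an error that
  demands manual resolution.
* **Step 2 — similarity transfer.** A food without analytic data borrows
  the TFA share of total fat (`tfa_pct_fat`) of the most similar
  Step-1-resolved food, and the share is rescaled by the recipient's own
  fat content. Ordinary foods search first within the same category of the
  same food group, then within the whole group. Meat cuts (foods carrying
  a species label) instead run a five-level cascade: same species and same
  part regardless of composition; same species and a *similar* part with
  similar composition; a similar animal type of the same species; a
  different species with similar composition; finally any similar member
  of the same meat group. "Similar part" and "similar animal" are expert
  judgments, so they enter as part/species adjacency lists in the
  configuration — data, not code.
* **Step 3 — foreign product matching.** A product marketed by the same
  manufacturer abroad donates its analysed TFA value when the domestic and
  foreign nutrient declarations are similar.
* **Step 4 — recipe imputation.** A composed food's value is the
  gram-weighted sum of its ingredients' values. Recipes may nest and are
  resolved in topological order; cycles are an error, as is an ingredient
  with no value of its own.

The provenance table counts foods per group and step; its grand total
always equals the number of foods.

### Numerical choices

*Nutrient similarity* has to be made precise to be computable. The
package uses the maximum over the four components (energy, fat, protein,
carbohydrate per 100 g) of the relative deviation `|a - b| / max(b, 1)`,
with a similarity threshold of 0.25. The metric is scale-free (energy in
kcal and protein in grams carry equal weight), the floor of 1 unit keeps
near-zero components from dominating, and 0.25 is conservative: a donor
must agree within 25% in its *worst* component. Both constants are
configuration, not constants in code.

Whether the within-category and within-group searches of Step 2 should be
thresholded or pure nearest-neighbour was genuinely open. The package
defaults to thresholded-nearest, for a structural reason: provenance
tables of real databases show foods resolved at Steps 3 and 4 inside
groups that contain Step-1 donors, which is impossible if any group donor
is accepted unconditionally. A configuration switch
(`step2_thresholded = FALSE`) restores pure nearest-neighbour matching.

Ties among equidistant donors go to the lowest food id, so database
construction is deterministic; pooling and recipe sums iterate in sorted
order so results are independent of input row order to the last bit. A
Step-2 recipient with zero fat but a hydrogenation/ruminant flag receives
0.0 under its matched step label, because a share of zero fat is
undefined. All values are carried at full precision; rounding to one
decimal happens only in display.

## Intake estimation

Diet records list grams consumed per subject, day and food, with a venue.
Commercial products (fast foods, baked goods, confectionaries) are valued
as the products themselves — their TFA content reflects the oils actually
used — while a composed dish eaten at a restaurant, for which no product
declaration exists, is decomposed into its raw materials through its
recipe. Venue never matters for a simple food.

Daily energy, fat and TFA totals are averaged over the subject's recorded
days (16 in the emulated design: four days in each season). Percentages
of energy use the Atwater factor of 9 kcal per gram of fat, a
configuration constant; percent-of-energy is computed as the ratio of the
multi-day means rather than the mean of daily ratios, which matches the
"multi-day mean intake" framing and is robust to single low-energy days.
Subjects with fewer than the full complement of days are averaged over
available days with a warning rather than dropped.

Outlier exclusion removes subjects outside the sex-group mean ± 3 SD on
either the g/day or the %-of-energy scale, in a single pass with the mean
and SD taken from the full group. A group with zero spread keeps all its
subjects.

## Summaries

Food-group contributions divide each subject's group-specific TFA mass by
their total TFA mass (g/day, not %energy — the decomposition is of mass),
so per-subject shares sum to exactly 100%; rows report the mean and SD of
shares over subjects, and the industrial share is the sum of the mean
contributions of the industrially-sourced groups. Urban/rural
classification uses a population-density threshold of 1000 persons/km²,
which cleanly separates typical city densities (thousands) from
provincial ones (hundreds). Comparisons use the unpaired two-sided t-test
(pooled variance) between area types and one-way ANOVA over the four
10-year age groups followed by Tukey-Kramer pairwise contrasts, which
remain valid for unequal group sizes; the package emits explicit pairwise
p-values rather than letter codes. Distribution tables count subjects in
half-open `[lo, hi)` bins with open-ended, label-truncated extremes.

## The synthetic generator

No subject-level data from any real study are available, so the generator
is a first-class module. It emulates:

* a food table in the eleven TFA-carrying groups plus a TFA-free block,
  with internally consistent macronutrients (energy within 5% of
  9·fat + 4·protein + 4·carbohydrate) and per-group lognormal true TFA
  shares of fat;
* a literature corpus whose article means are the truth plus additive
  measurement noise (zero noise gives exact recovery, which the closure
  tests exploit), with bracketing minima/maxima and a configurable
  fraction of articles omitting their sample count;
* recipes for a fraction of foods, whose macronutrients and true TFA are
  redefined as the gram-weighted sums of their ingredients so that direct
  valuation and decomposition agree exactly;
* a stratified cohort of 119 women and 106 men across four areas (two
  urban, two rural) and four age decades, each with 16 recording days.

The consumption model is deliberately minimal: per subject, Dirichlet
weights over food groups; per day, a Poisson number of TFA foods whose
lognormal amounts are rescaled to hit the day's TFA target, then TFA-free
fillers rescaled to top energy up to the day's energy target. Because the
two targets are hit by construction, realized cohort means converge to
the configured stratum targets (1847 kcal/day and 1.7 g/day for women,
2372 kcal/day and 1.7 g/day for men) at the usual 1/sqrt(n) rate, and
total fat lands near the emulated conditions (about 57-61 g/day for
women) as a consequence of the generated food compositions. Urban/rural
and age gradients in TFA intake are multiplicative factors on the
subject-level target, renormalised so each sex's design-weighted mean
factor is 1.

What the generator does *not* emulate: real menus and food co-occurrence,
seasonal variation, correlated reporting errors, energy misreporting, and
anthropometric realism beyond plausible ranges. Passing tests therefore
demonstrate that the estimator is exact given exact inputs and that the
pipeline's aggregation logic is correct — not that any particular real
population's intake is reproduced.

A second, fully deterministic corpus generator
(`generate_provenance_corpus()`) routes a prescribed number of foods per
group through each step of the hierarchy by geometric placement of
nutrient vectors (donors in a tight band, similar recipients within the
threshold, fall-through recipients far outside it; one composition region
per meat species). Its default counts are the published per-step counts
of the 1995-food Japanese TFA database, which the provenance table then
reproduces cell by cell.

## Problem sizes and runtime

The default test suite uses 4 foods per group and a two-area cohort
(about 56 subjects) for exact-closure checks, the full 1995-food corpus
for provenance accounting, a 119-woman cohort for calibration, and 10^5
shuffles for the permutation oracle behind the ANOVA check; the whole
suite and the acceptance script each run in about a minute on one core.

## Known limitations

* The meat cascade's adjacency lists are inputs; the package ships no
  authoritative list of "similar" cuts or species.
* Published group-level means cannot identify subject-level joint
  distributions; the subject-level fixture reconstructed from published
  bin counts honours the printed area and age marginals per bin, which is
  sufficient for threshold frequencies but not unique.
* Stratum means, SDs and p-values of any real study are not reproducible
  without its raw records; those surfaces are verified by properties
  (conservation, monotonicity, oracle agreement) on synthetic cohorts.
* Usual-intake (measurement-error) modelling, energy adjustment, survey
  weighting and seasonal-variation testing are out of scope.
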