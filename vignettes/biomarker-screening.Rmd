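---
title: "Block-stratified biomarker screening in spent embryo culture medium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-stratified biomarker screening in spent embryo culture medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoscreen)
```

## The problem

A bovine in vitro produced (IVP) embryo spends its last 24 h before
transfer in a small volume of protein-free single-culture medium. The
metabolites it consumes from and releases into that medium carry
information about its developmental competence, and so about the
probability that the recipient becomes pregnant (diagnosed at Day-40 and
Day-62) and calves. Untargeted LC-MS of the spent medium produces a
feature table (samples by spectral features, each with a retention time
and m/z) whose analysis is complicated by strong, known sources of
metabolic variation: cryopreservation of the embryo, bull breed, culture
supplement (BSA alone or BSA + fetal calf serum), the embryonic stage at
the start (morula M, early blastocyst EB, blastocyst B) and end
(expanding ExB, fully expanded FEB blastocyst) of the single-culture
step, and embryo age (Day 7 or 8).

`embryoscreen` implements the complete downstream analysis: feature-table
post-processing, exhaustive *block* screening stratified on those fixed
factors, impact weighting of the resulting single biomarkers, and
combination of stage-disjoint blocks into predictive *series*. A
synthetic-cohort generator with planted effects makes every stage
testable without access to any cohort.

## Preprocessing

The pipeline order is fixed and logged:

1. **Replicate averaging.** Each sample is injected in duplicate; a cell
   becomes the mean of its non-missing replicates and stays missing only
   when both are.
2. **Consistency filter (threshold 0.8).** A feature is kept only if at
   least one outcome group measures it in at least 80% of its samples.
   The grouping defaults to the Day-40 pregnancy classes and is
   configurable.
3. **Random-forest imputation (missingness cap 0.25).** Features still
   missing in more than a quarter of samples are dropped; remaining holes
   are filled by an iterative random-forest regression of each incomplete
   feature on all others (feature means to start, sweeps in order of
   increasing missingness, stopping when the total change in imputed
   values stops decreasing). The 0.25 threshold is a per-feature
   missingness cap, not a forest hyperparameter. Imputed values are clipped to each feature's observed
   range to avoid extrapolation artifacts. The imputer is deterministic
   given the seed.
4. **Total-intensity normalization.** Every sample is scaled by (grand
   mean of sample totals) / (own total). Blanks are normalized alongside
   the samples to the same grand-mean target. Normalization precedes
   blank subtraction, so net values are expressed on the common,
   balanced intensity scale.
5. **Blank subtraction.** One blank (medium incubated without an embryo)
   is recorded per transfer-round-by-culture batch and subtracted feature
   by feature. Negative net values are preserved: they are consumption of
   a medium constituent. A blank cell below detection is treated as zero
   (nothing to subtract). Blanks are matched per batch rather than
   averaged across rounds, and the pairing key is stored explicitly.

## The two-level block screen

A *block* is a pregnancy endpoint (Day-40, Day-62, birth) crossed with a
constraint on each fixed factor: one level or "free" for
cryopreservation, breed, culture and age, and a whitelist of stage
subsets at 0 h ({M}, {EB}, {B}, {EB,B}, free) and 24 h ({ExB}, {FEB},
free) — the unions that occur in practice, which bounds the enumeration.
Blocks need at least `min_class = 3` samples in both outcome classes,
so very small pilot blocks remain admissible but degenerate contrasts
are excluded. Constraint tuples resolving to
identical pregnant/open sample sets are collapsed to the coarsest tuple.

Within a block, every feature passes two gates:

* **Level 1 (volcano).** Fold-change gate |log2 FCh| ≥ 1 (i.e. FCh
  beyond |2|) and min(parametric, non-parametric p) < 0.10, flagged
  *significant* below 0.05 and *tendency* in [0.05, 0.10). The
  parametric test is the two-sample equal-variance t test (one-way ANOVA
  with two groups); the non-parametric test is Kruskal–Wallis.
* **Level 2 (ROC).** Direction-free empirical rank AUC
  (`max(A, 1 - A)`, ties at half credit) above 0.700 with t-test
  p < 0.10. Blocks with fewer than 12 samples and AUC ≥ 0.850 are
  admitted with p up to 0.15 and flagged `small_n_exception`: such
  high-separation small blocks are kept as complementary information for
  larger blocks rather than discarded outright.

**Fold changes on net values.** Net intensities can be negative, so the
pregnant/open fold change follows sign rules: both means positive gives
`log2(mean_P/mean_O)`; both negative gives `log2(|mean_P|/|mean_O|)`;
opposite signs (or exactly one zero mean) are *qualitative* differences
reported as the sentinel ±99.000 with the sign of `mean_P − mean_O`.
Fold changes are on the log2 scale, which makes the FCh gate equal
|LogFCh| ≥ 1. Sentinel features satisfy the fold-change gate by
construction. The second reported p-value (`p2`) is standardized on the
Kruskal–Wallis test, the rank-based complement to the t-test of `p1`.

No multiple-testing correction is applied inside the screen; the
correction is reserved for the whole-dataset models, and the hit table
carries raw p-values plus the total number of tests so readers can apply
their own.

## Impact weighting and series

The value of a hit depends on how much of the embryo population its
stratum covers. An *impact table* gives, per culture condition, the
percentage of embryos in each 0 h-by-24 h stage cell (summing to 100
within a culture), plus each culture's population share. A block's
impact is the sum of the cells it covers; culture-free blocks combine
cultures weighted by the shares. Stage-free blocks therefore have impact
exactly 100 under any culture constraint, and culture-free stage impacts
still sum to 100 over a full stage partition; carrying explicit
per-culture shares is what makes the culture-free lookup well defined.

* **Single biomarkers:** predicted coverage = AUC × impact (percent);
  reported when ≥ 70.
* **Series:** blocks sharing endpoint, cryo, breed, culture and age
  whose stage strata are pairwise disjoint. Member sets are enumerated
  exhaustively (the stage lattice is small), each member block
  contributes its best metabolite, and the combined coverage is the sum
  of member AUC × impact. Series are reported above 80; ties go to fewer
  members, then lexicographic metabolite ids. Members must share a common
  age and endpoint so a series reads as one decision rule for one
  population.

## Whole-dataset reporting

For candidate metabolites from the block study, an ordinary
least-squares (Gaussian identity-link) model of net intensity on cryo, culture, breed, both
stages and age tests each endpoint term, including a three-group
miscarriage contrast (term / post-Day-40 loss / open). Bonferroni flags
at family levels 0.05 and 0.10 use the number of candidate metabolites
as the family size — the candidates identified by the screen, not all
features. Both the raw p and the passed family levels are reported, so
the flags are reproducible from the table alone. Tallies by taxonomy class, endpoint and cryo status, an
AUC-versus-sample-number summary (seven default bins, configurable
edges), and the descriptive
pregnancy-rate table (with per-endpoint exclusion of, e.g., a deceased
recipient) complete the reports.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: 84 transfers (28 fresh
Day-7, 48 frozen Day-7, 8 frozen Day-8), seven bulls, two breeds, two
culture conditions, stage records at 0 h and 24 h, and nested endpoint
indicators (birth ⟹ Day-62 ⟹ Day-40) with baseline rates 0.607 / 0.583 /
0.464, typical of Day-7 bovine transfer cohorts of this composition. Intensities are
log-normal on the log2 scale. A configurable fraction of features are
medium constituents carrying a blank level; embryos consume or release
them (net-negative or net-positive after blank subtraction), while
genuinely embryo-derived features are low-abundance. Bull random
intercepts (default SD 0.5 log2 units) act on a feature subset.
Missingness combines MNAR censoring below a global detection-limit
quantile with a small MCAR rate, both configurable. Duplicate
injections add a 2% CV, a typical analytical scale, exposed in the
configuration.

Planted effects make chosen features differential inside a stratum:
*shift* mode adds a log2 effect to the pregnant class's embryo
contribution; *qualitative* mode pins one class near blank level with a
small opposite-sign net so the ±99 sentinel fires downstream. Planted
biomarkers are drawn from released medium-constituent features: a
qualitative effect needs blank-level signal in its suppressed class to
remain detectable, and an amplified consumption would saturate at
complete depletion of the constituent — which is the qualitative regime,
not a fold change. Biological noise defaults to 1.0 log2 units, a
realistic single-embryo scale that leaves strong (≥ 4-fold) effects
clearly detectable at the block sizes of this design. The default of 120
features keeps a full cohort round-trip fast while leaving the large
majority of features null.

What the generator does *not* emulate: chromatographic drift and batch
effects beyond the blank pairing, correlated metabolite modules (beyond
a shared bull intercept), adduct/isotope redundancy among features, and
recipient-side physiology. Passing tests therefore demonstrate that the
pipeline recovers the statistical structure it assumes, not that any
specific real cohort satisfies those assumptions.

## Numerical choices and degenerate inputs

* Equal group means with zero variance in both groups give p = 1 (no
  evidence), unequal means with zero variance give p = 0.
* Both group means exactly zero make the fold change undefined (`NA`);
  the feature cannot pass the gate.
* The Kruskal–Wallis p uses the chi-square approximation with tie
  correction; a fully tied block yields p = 1.
* AUC ties get half credit; the direction-free fold `max(A, 1 - A)`
  keeps AUC in [0.5, 1] for both release and consumption markers.
* Imputed values are clipped to the feature's observed range.
* Coverage ties are broken deterministically (larger block, then feature
  id; series: fewer members, then lexicographic ids), so reruns are
  byte-identical.
* Tables are written with 17 significant digits, so TSV round-trips are
  bit-exact; the ±99 sentinel is written exactly as `-99.000`/`99.000`.

## Problem sizes used by the test suite

The stochastic suites run with cohorts of the default 84 samples:
level-1 calibration uses 200 planted-null cohorts of 40 features on
complete data (so the measured pass rate reflects the tests themselves
rather than the imputer) across a panel of named strata; recovery uses
six cohorts of 120 features with five planted 8-fold shift effects each
in strata holding at least 8 samples per class; determinism runs the
full pipeline twice on a 30-feature cohort. These sizes were chosen to
give stable Monte-Carlo estimates (MC-SE of the pass rate below 0.002)
at interactive runtimes.

## Known limitations

* The screen's hit list is intentionally uncorrected for multiplicity;
  with thousands of block-by-feature tests it must be read together with
  the test counts it reports, and downstream identification (library
  annotation) is the main false-positive filter, as in the original
  design.
* Impact weighting assumes the reference stage-abundance table applies
  to the cohort under study.
* The package standardizes on the empirical rank AUC throughout;
  smoothed or binormal AUC estimates from other software will disagree
  slightly on small blocks.
* Stage constraints written with 24 h labels (ExB, FEB) are always
  interpreted as 24 h constraints, whatever column they arrive in.
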