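---
title: "Two-stage mixed-model analysis of dye-swapped loop designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage mixed-model analysis of dye-swapped loop designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmaa)
```

## The experimental layout

Two-colour spotted microarrays hybridise two RNA samples per slide, one
labelled Cy3 and one Cy5, so every array is a direct comparison of two
samples.  In a **loop design** the treatments form a cycle -- A vs B, B vs C,
C vs A on successive arrays -- which gives balanced within-array comparisons
for every treatment pair without spending half of every slide on a common
reference.  A **dye swap** duplicates each loop with the label assignment
reversed so that dye-specific bias (Cy5 typically reads systematically
brighter or dimmer) cancels by symmetry.

`build_loop_design(treatments, n_replicates, dye_swap)` constructs this
layout as the canonical single cycle in treatment-list order.  Any single
cycle is statistically equivalent for balanced estimation, so the package
does not search over topologies; replicate loops reuse the same cycle, with
the replicate index carrying the biological identity.  For three treatments,
three biological replicates and a dye swap this yields 18 arrays and 36
channel-samples, i.e. 18 direct within-array comparisons:

```{r design}
design <- build_loop_design(c("control", "wcr_untreated", "wcr_treated"), 3)
summarize_design(design)
```

`validate_design()` checks the invariants (two channels per array with
distinct dyes, no self-comparisons, balanced `(treatment, replicate)` counts,
dye-orientation balance under the swap) and returns violations as data so
that externally supplied design tables can be triaged.

## The two-stage mixed linear model

Raw intensities are strictly positive and right-skewed, so the analysis
operates on logarithms.  `log_transform()` defaults to base 2 -- the
convention that makes differences read as log-fold changes -- and the base
is configurable; nothing downstream depends on the choice beyond the scale
of the effect estimates.

**Stage 1** (`fit_stage1()`) models every log intensity `y[g, c]` of probe
`g` in channel-sample `c = (array, dye)` as

    y[g,c] = mu + panel[p(g)] + dye[d(c)] + treatment[t(c)]
             + A[array(c)] + D[c] + e[g,c]

with fixed panel (print-tip block), dye and treatment effects under
sum-to-zero constraints, random array effects `A ~ N(0, sigma2_array)`,
random dye-within-array effects `D ~ N(0, sigma2_dye)` and residual noise
`e ~ N(0, sigma2_resid)`.  Treatment enters stage 1 as a *global* fixed
effect -- the average shift of a treatment across all probes -- even though
per-probe treatment effects are re-estimated in stage 2; this keeps the
stage-1 residuals centred per treatment and costs two degrees of freedom.
Panel is modelled as a crossed fixed effect (one level set shared across
arrays): every panel appears in every channel, so panel contrasts are
orthogonal to the channel-level terms.

Because designs built by this package are exactly balanced, the fixed
effects reduce to contrasts of cell means and the variance components have
closed-form method-of-moments estimators (Henderson III applied to the
channel-sample means): the within-array channel mean square estimates
`sigma2_dye + sigma2_resid/G` (with `G` probes per channel), and the
array-adjusted sum of squares estimates `sigma2_array` after subtracting its
expected noise contribution, with the trace coefficients computed
numerically from the actual design matrices so mild imbalance degrades
gracefully.  Negative moment estimates are clamped to zero.
`method = "reml"` refits the channel-level components by restricted maximum
likelihood (delegated to `lme4`), the recommended route when arrays have
been dropped and balance is lost; on balanced data the two estimators
coincide to optimizer tolerance, which the test suite asserts.

### Residuals and BLUP shrinkage

The residuals handed to stage 2 subtract the fixed effects and the
*predicted* random effects.  Two switches control the prediction:

* `subtract_blups = FALSE` skips random-effect subtraction entirely, leaving
  array and channel variation in the residuals;
* `shrink_blups` (default `TRUE`) toggles between proper BLUPs -- the
  channel deviations shrunken by `sigma2 / (sigma2 + noise)` factors -- and
  the unshrunken least-squares channel effects.

With unshrunken effects the residuals are an exact orthogonal projection:
they sum to zero within every array, dye, treatment and panel to machine
precision.  With shrunken BLUPs (the standard two-stage practice, and the
default) the within-channel sums are instead of order `(1 - k)` times the
channel deviation -- negligible whenever thousands of probes inform each
channel mean, but not literally zero.  Both behaviours are tested; users who
need exact orthogonality (e.g. for downstream projections) should set
`shrink_blups = FALSE`.

## Stage 2: per-probe inference

`run_probe_inference()` refits, for every probe, the fixed-effect model
`residual = mean + dye + treatment + error` (error df
`n - 1 - (n_dyes - 1) - (n_treatments - 1)`; 32 in the 36-channel layout)
and computes:

* the treatment **F test**, `F = (SS_trt / (t-1)) / MSE`;
* all pairwise **t tests** on the dye-adjusted LS means,
  `t = (lsm_i - lsm_j) / sqrt(MSE (1/n_i + 1/n_j))`;
* optionally, pairwise **Wilcoxon rank-sum** tests on the residuals grouped
  by treatment with dyes pooled (12 vs 12 in the study layout), as a
  distribution-free confirmation.

All probes share one design matrix, so the battery is evaluated in a few
matrix operations rather than a per-probe loop.  The Wilcoxon p-value is
exact -- by enumeration of the rank-sum null distribution -- whenever the
combined sample is at most 14 with no ties, and otherwise uses the Normal
approximation with tie and continuity corrections; the exact path is
property-tested against brute-force enumeration of every rank assignment.

**Ranking.** Probes are ordered by their smallest pairwise t p-value
(ties broken lexicographically by probe id) and assigned ranks `1..n`.
With three treatments there are three pairwise tests per probe and no single
"the t-test p-value", so the minimum is the documented default;
`order_by = "f"` switches the ranking to the F p-value.  The significance
flag compares the minimum pairwise p-value against `alpha` (default 0.05).
A literal threshold of 0.5 -- which excludes almost nothing -- can be
requested explicitly via `alpha = 0.5`; the package treats the threshold as
a free parameter rather than guessing an intended value.  No
multiple-testing correction is applied by default because the workflow
*ranks* probes for profiling rather than controlling an error rate;
`p.adjust()` composes naturally with the returned table if FDR control is
wanted.

## Profiling the top-k set

`select_top_k()` takes the `k` best-ranked probes (contiguous ranks
`1..k`).  Downstream summaries:

* `direction_calls()` labels each treatment UP/DOWN/UNCHANGED against a
  control column, with a dead-band `tolerance` (default 0: any non-zero
  difference is a call, appropriate for printed summary tables; use a small
  epsilon for noisy means).
* `similarity_partition()` operationalises "statistically similar
  expression" for a treatment pair as *failure to reject*: pairwise
  `p > alpha`.  This is a deliberate, documented choice -- absence of
  evidence for a difference, not evidence of equivalence -- and the Venn
  cell counts always sum to `k` by construction.
* `category_summary()` tallies annotation categories (missing ids fall into
  `"unknown"`); the gene-by-gene classification itself is consumed as an
  annotation map, never computed.
* `export_heatmap_matrix()` writes the probe x treatment matrix behind an
  expression heat map in a deterministic row order; rendering is left to
  dedicated tools.
* `direction_concordance()` compares the *sign* of each
  treatment-vs-control difference between two expression tables (e.g.
  array LS means vs QRT-PCR ng-RNA quantities); signs rather than
  magnitudes, because the platforms' scales are incommensurable.

The packaged fixtures `table1.tsv` (36 defense-related probes with
per-treatment mean relative expression) and `table2.tsv` (6 QRT-PCR
quantified genes) are transcriptions of published summary tables, Unicode
minus signs included -- the reader normalises U+2212 on input.  On these,
31 of 36 probes call DOWN in the untreated-herbivore column relative to
control, and the three probes shared between the tables are sign-concordant
in all treatment directions.

## The synthetic-data generator

`simulate_experiment()` is the generative mirror of stage 1: log-scale
intensities are composed of exactly the effect classes the model fits
(baseline, fixed panel draws, a CY5-CY3 dye offset, per-probe treatment
shifts, Normal array and dye-within-array effects, Normal residual noise),
then exponentiated so the emitted raw table is strictly positive.  Ground
truth (which probes are DE, where, and by how much) is returned alongside
for recovery testing.

Defaults are package choices on the log2 scale, documented here because the
source analysis reports no variance magnitudes: `array_sd = 0.3`,
`dye_in_array_sd = 0.2`, `residual_sd = 0.4`, `dye_effect = 0.1`,
`panel_sd = 0.25`, 48 panels.  The DE defaults -- 5% of probes shifted by
two residual SDs, 74% of them downward in the second treatment -- emulate
the headline biology of a treatment that suppresses most of the genes it
touches.  `n_probes` defaults to 2000: large enough that channel means are
estimated to ~1% and small enough that a full pipeline run takes about a
second, which is the problem size used throughout the tests and the
acceptance script; the full 57,452-probe array is a `sim_config` call away.

What the generator does *not* emulate: spot-level image artefacts,
background, spatial/print-tip trends within a panel, intensity-dependent
(banana-shaped) dye bias, heavy-tailed or probe-specific variances, and
correlated probe sets.  Passing recovery and calibration tests on this
generator therefore demonstrates that the estimators are correct *under the
model's own assumptions* -- not that the model is adequate for any
particular real slide set.

### What the simulation studies show

Run under the null generator (`de_fraction = 0`, so that true per-probe
shifts are not absorbed into the residual component):

* **Variance-component recovery.**  With 18 arrays the between-array mean
  square carries only 17 degrees of freedom, so a *single* estimate of the
  array component has ~40% coefficient of variation -- an information limit
  of the design, not an estimator defect.  Recovery is therefore assessed
  on the median estimate across 64 seeds, which lands within a few percent
  of truth for all three components (and the residual component, informed
  by ~70k observations, is tight per seed).
* **Type-I calibration.**  Pairwise t-test rejection rates at
  `alpha = 0.05` fall within [0.03, 0.07] over 12,000 probe-tests.
* **Power / recovery.**  With a 2-sigma effect in 5% of 2000 probes,
  >= 90% (typically ~99%) of truly DE probes land in the top 500, and
  detection is monotone in effect size.

## Fitness assays

The companion assay module mirrors the organismal experiments that ask
whether curing the insect of its symbiont costs it fitness: an egg-hatch
assay (10 dishes x 100 eggs, daily counts, stop rule of seven hatch-free
days applied as a reporting truncation that never alters totals) and a
host-location assay (10 dishes x 10 neonate larvae, 5-minute counts over an
hour, non-locators censored).  `percent_hatch()`, `hatch_curve()`,
`location_fraction_within()` produce the per-replicate summaries and
`two_sample_t()` compares them between colonies with the pooled-variance
Student's t on `n_a + n_b - 2` df -- per-replicate percentages, the only
unit under which the assays' replication structure gives a sensible t test.
Simulator defaults (hatch probability 0.885, bell-shaped hatch day
N(6, 1.5^2) truncated at day 1; location probability 0.95 with geometric
5-minute bins of median 20 minutes) reproduce the reported ~88-89% hatch
and ~80-85% located-within-the-hour figures.

## Numerical and degenerate-input policy

* Sum-to-zero (effects) coding everywhere, so treatment effects read as
  deviations from the grand mean; for unequal panel fills the panel family
  is weighted-sum-to-zero.
* Exact-fit probes (`MSE = 0`): F and t p-values are 0 when the effect sum
  of squares is non-zero and 1 when it is zero, flagged as exact fits.
* Negative variance-component moments clamp to zero; BLUP shrinkage factors
  fall back to 0 when their denominators vanish (all-constant input).
* Rank ties are broken lexicographically by probe id, making every ranking
  deterministic and permutation-invariant.
* Wilcoxon two-sided exact p sums both tails at least as extreme as the
  observed rank sum and its reflection about the null mean, capped at 1.
* All simulators consume a single integer seed and are bit-reproducible.

## Known limitations

* Stage 1 assumes a complete, balanced probe x channel table; missing spots
  must be imputed or dropped upstream (the method-of-moments traces are
  computed numerically, so mild channel-level imbalance degrades gracefully,
  but probe-level holes are rejected).
* No spatial/loess or quantile normalisation, background subtraction, or
  empirical-Bayes variance moderation; the stage-2 t tests use the honest
  per-probe MSE on 32 df.
* "Statistically similar" in the Venn partition is failure-to-reject, not
  an equivalence test; its counts depend on power.
* Genome-wide percentages from the original slide sets depend on scanner
  spot-calling upstream of this pipeline's inputs and are out of scope.
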