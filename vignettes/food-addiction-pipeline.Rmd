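---
title: "From operant event logs to miRNA signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From operant event logs to miRNA signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addictomir)
```

addictomir implements, as one tested pipeline, the analysis chain of a
rodent food-addiction study and its human translation: operant
event-log scoring of the three addiction-like criteria, 75th-percentile
classification with the 2-of-3 rule, selection of extreme vulnerable and
resilient subgroups on a gradual severity scale, negative-binomial
differential expression of miRNA/mRNA count matrices with
discovery/replica replication and target-set enrichment, and YFAS 2.0
questionnaire scoring with sex-stratified correlations against circulating
miRNAs. Because the per-animal raw data of such studies are not released,
the package ships a first-class synthetic-data generator that emulates the
study conditions; everything downstream operates identically on real
tables with the same layouts.

## The behavioral model

Each simulated mouse is an agent emitting lever responses as a thinned
Poisson process per lever (`agent_params()`): the simplest count-valued
process whose rate can be modulated by schedule context. The schedule state
machine (`simulate_session()`) encodes the operant-box contingencies:

* **FR5** — one pellet plus cue light per 5 active responses, followed by a
  10-s time-out during which responses never count toward the next ratio.
* **FR5 with a pellet-free period** — a signalled 10-minute window (by
  default minutes 20–30 of a 1-h session) in which responses are tagged
  `pellet_free` and never reinforced. The *persistence of response*
  criterion is the mean pellet-free active count over the three FR5
  sessions that carry the window; the arithmetic mean is used because the
  design aggregates three consecutive sessions without naming an aggregate,
  and the mean is scale-stable.
* **Progressive ratio** — the requirement escalates through the 35-step
  ladder `pr_ladder()` (1, 5, 12, … 5500); the *breaking point* is the
  ladder value of the last fully completed requirement. Sessions end by
  ladder exhaustion, a 5-h cap, or one hour without a response on either
  lever — and by nothing else (a property the tests assert). An agent
  disengages when the next requirement exceeds its `motivation_cap`.
* **Shock test** — a 50-min FR5 variant: the 4th active response of a cycle
  yields a footshock only, the 5th a footshock plus pellet; a cycle parked
  past its 4th response for more than one minute restarts. The *compulsion*
  criterion is the total shock count. Shock intensity (0.18 mA, 2 s) is
  recorded as log metadata only; in the simulator punishment acts through
  `punishment_sensitivity`, a per-shock multiplicative rate decrement.
* **Probe sessions** — a cue probe (non-contingent cue light at
  mid-session; appetitive reactivity is the post-cue minus pre-cue active
  count over equal windows), a grid-extinction session (aversive
  reactivity), and a lever-reversal session (perseverative responses on
  the previously active lever). The reversal schedule is part of the
  simulator because the cognitive-flexibility trait requires it.

Two operationalizations are deliberate stand-ins, flagged as such:
impulsivity is counted as active responses during FR5 time-out windows, and
flexibility errors as perseveration in a single reversal probe; the
underlying tests of the original behavioral battery are described only at
the construct level in the literature available to us.

One direction question is worth recording: "lower aversive cue reactivity
in addicted animals" can mean either a lower response *count* in the
grid-extinction session or weaker *control* of behavior by the aversive
context (hence a higher count). We adopt the control reading — vulnerable
agents get weaker aversive suppression and therefore respond more — because
it coheres with the compulsion phenotype. Classification never uses the
traits, so no headline quantity depends on this choice.

## Classification, severity, extremes

A criterion is positive when the mouse's score is *strictly above* the
cohort's 75th percentile (linear-interpolation quantile, the common
statistical default); a mouse achieving 2 or 3 of the 3 criteria is
addicted. The analogy to the DSM-5 is deliberate: severe substance use
disorder requires 6 of 11 criteria (55%), the mouse rule 2 of 3 (66%).
Thresholds are computed on the palatable-food-trained cohort; experimental
arms should pass thresholds from their own control arm explicitly.

The gradual severity scale orders mice along the inverted-U: we use the
mean of the three within-cohort fractional ranks, the simplest composite
that is monotone in every criterion, lies in [0, 1], and puts the median
mouse at 0.5. The original scale is not defined publicly, so the choice is
isolated in `severity_and_extremes()` and easy to swap. Extreme subgroups
take the `k = 6` highest-severity addicted and `k` lowest-severity
nonaddicted mice as the discovery sample and the next `k` per side as the
replica; whether the original split was symmetric on both tails is
ambiguous, and this is one defensible reading. Ties break by persistence,
breaking point, shocks, then mouse id, making selection deterministic.

PCA of the 3 criteria + 4 traits runs on standardized variables (the units
are incommensurate), reports variance explained in percent, and flags
loadings above 0.7 in absolute value.

## The phenotype effect sizes

The study reports phenotype differences only as significance stars, so the
vulnerable-vs-resilient parameter separations cannot be calibrated to data.
They are frozen constants (`default_phenotype_params()`), chosen once so
that default 51-mouse cohorts yield roughly a quarter classified-addicted
(the reported 25.5%) and the classifier recovers latent labels with
balanced accuracy above 0.8; across seeds the classified fraction stays
within 0.15–0.35. They are not per-analysis tuning knobs.

## Differential expression

The NB engine is the package's own (it is the computation this module
exists for): median-of-ratios size factors, per-feature method-of-moments
dispersion floored at 1e-4 (no empirical-Bayes shrinkage — a documented
divergence from heavyweight DE tools, kept simple deliberately), a
group-mean NB fit by Newton scoring with size-factor offsets, and a Wald
test on the group contrast. Two numerical choices matter:

* **p-value reference.** The Wald statistic is referred to a t
  distribution with `n - 2` degrees of freedom, not a normal. At n = 6 vs 6
  the empirical null of the statistic under the method-of-moments
  dispersion matches t(10) across the whole tail (measured at |z| = 2…5),
  while the normal reference is anticonservative (≈0.076 at nominal 0.05).
  The all-null suite asserts calibration within 0.05 ± 0.01.
* **Degenerate groups.** Group means are floored at half a normalized
  count so an all-zero group keeps a finite estimate and a usable Wald
  interval; estimates are clamped at |η| ≤ 30 and Newton steps at ±5.

A label-permutation mode provides a distribution-free alternative; its
p-values are rank-concordant with the Wald ones (Spearman > 0.9 on default
simulations) and it is the slow path, so Wald is the default. An
established NB tool (DESeq2) serves as an independent cross-check in the
test suite — never as the implementation.

Replication between discovery and replica samples is direction-consistent
by design: a miRNA is replicated when significant (BH q < 0.05) in both
samples with the same sign, and the per-direction overlap is tested
hypergeometrically, conditioning on the features tested in both samples
after the `min_total = 10` count filter (overlap probability must condition
on testability). Target enrichment tests each miRNA's annotated target set
(GMT dialect, `read_gmt()`) among the differentially expressed genes with
the one-sided hypergeometric tail, BH-corrected across miRNAs; empty
intersected sets are reported, never dropped.

## The omics generator

Counts are drawn directly as NB integers (no post-rounding) with
`NB(mean = baseline × library factor × 2^(lfc·group), dispersion)`. The
planted defaults mirror the reported signature: 9 down- and 2 up-regulated
miRNAs at |log2FC| = 1 in 6 vs 6 extreme samples. Planted miRNAs take
baselines in 200–1000 counts (detectable signatures come from expressed
miRNAs); background features follow a log-normal. Each planted miRNA's
target genes receive an mRNA shift of `-coupling × lfc` — the opposite
sign, as expected under repressive regulation — with `coupling = 0.8` by
default; `coupling = 0` is the null control and the tests assert both
directions of that switch.

The default dispersion is 0.025 (biological CV ≈ 16%), appropriate for an
isogenic inbred cohort, and was fixed once, together with the planted
baseline range, so that the default configuration reproduces the design's
qualitative outcome — the planted down-regulated miRNAs replicate across
discovery and replica (median 9 of 9 over 12 seeds, minimum 7). It is
worth being explicit about the power arithmetic behind this choice: the
Fisher information bound for a 6 vs 6 NB contrast caps the expected Wald
statistic at `ln 2 / sqrt(α/3)` for |log2FC| = 1 — about 3.8 at α = 0.1 —
so at α = 0.1 no calibrated test can push 2-fold changes through BH q <
0.05 over a transcriptome-scale universe in both samples; at α = 0.025 the
bound is ≈ 7.6 and replication is comfortable. The acceptance suite
reports the α = 0.1 configuration faithfully and documents its failure to
replicate as a property of those conditions, not of the implementation.

## YFAS 2.0 scoring

The 35 ordinal items (codes 0–7) map to 11 diagnostic symptom criteria plus
a clinical-significance criterion via an editable CSV map; an item meets
its criterion at or above its threshold code, a criterion is positive when
any of its items meets it, and diagnosis requires at least 2 symptoms plus
impairment, with severity bands 2–3 mild, 4–5 moderate, 6–11 severe. The
shipped map (`yfas2_item_map_synthetic.csv`) is a *synthetic
reconstruction* of the instrument's structure — 3 items per symptom
criterion plus 2 impairment items — not the copyrighted scoring key;
studies with real data must supply their own. The three hallmark
composites (persistence, motivation, compulsion) are raw item-code sums
over the items of the criteria assigned to each hallmark; the assignment
of criteria to hallmarks is likewise a configurable reconstruction, since
only the grouping's existence is documented. Group comparisons use the
Mann–Whitney U test (normal approximation with tie correction), and
miRNA–score associations use Pearson correlations; sex stratification is a
first-class flag because the motivating findings are sex-specific. The
human generator assigns 12 of 51 subjects to the addicted group, generates
items so the implied symptom count matches the assignment exactly (a
round-trip the tests assert), and plants per-sex correlations by mixing
the standardized composite into the miRNA level, so sample correlations
converge to the planted values as the cohort grows.

## Pipelines, determinism, problem sizes

`run_mouse_pipeline()` and `run_human_pipeline()` chain the stages from one
`run_config()`. Per-stage seeds derive from the global seed by a stable
hash of the stage *name*, so adding a stage never shifts earlier stages'
randomness. Every tabular output is written under the run directory and
listed with an MD5 content hash in `manifest.json`; identical configs give
byte-identical manifests (the run log keeps timings and is diagnostic
output, outside the manifest). A cohort with too few mice on one side
completes with smaller or empty extreme sets and skips the omics stages
with a warning rather than failing.

The test and acceptance suites run at desk scale by design: 51-mouse
cohorts, 600 miRNA / 2000 mRNA features, 2000-subject human cohorts for
parameter recovery, 10–20 seeds for medians, 1000 random cases per oracle
check. These sizes were chosen to exercise every property at comfortable
statistical resolution while keeping a full run in minutes on one core.

## What the generator does and does not show

The simulator reproduces the *structure* of the study — schedule
contingencies, a latently bimodal cohort, NB counts with planted
signatures, anticorrelated targets, sex-specific human correlations — but
not the messiness of real data: no session-to-session drift or learning
curves, no batch or library-preparation effects, no dispersion trends over
expression, no correlated miRNA co-regulation beyond the planted sets, no
item-level response styles in the questionnaire. Passing tests therefore
demonstrate that the analysis chain is correct and calibrated under its
stated model, not that the biological conclusions of any particular study
are reproduced; the headline biological numbers (which specific miRNAs,
their fold changes, human correlation coefficients) depend on unreleased
per-animal data and are out of computational reach here.
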