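---
title: "Methods: markers, rules and the deterministic diagnosis engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markers, rules and the deterministic diagnosis engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cogdx` implements a complete desk-scale harness for rule-based cognitive
diagnosis from digital phenotyping streams: a seeded synthetic cohort, a
marker layer, decision-tree rule induction, a deterministic inference
engine behind a prompt/response contract, and a split/selection/evaluation
protocol. This vignette records the model assumptions, the tunable
parameters and their defaults, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The diagnostic model and its assumptions

The classifier is a weighted vote over conjunctive if–then rules evaluated
on a participant's markers. The substantive assumptions are:

- *Axis-aligned, shallow structure.* Rules come from a CART-style tree with
  Gini splits and `max_depth = 2`, so every learned rule has one or two
  conditions. The depth default reflects the shipped rule inventory, which
  contains only 1- and 2-condition rules; it is configurable.
- *Cohort-relative scaling.* All real-valued markers except age and
  education are min–max scaled to 0–10 integers using bounds fitted on the
  reference set. Rule thresholds (e.g. `EMA_compliance <= 9.5`) live on
  this scaled axis. Age is deliberately left in raw years: the shipped
  inventory contains `age <= 79.5`, which is only meaningful unscaled,
  while compliance and sharpness thresholds above 5 are only meaningful
  scaled. Education follows age as a natural-unit demographic.
- *Independence of evidence.* Confidence-weighted voting sums rule
  confidences per class as if fired rules were independent witnesses. This
  is the usual rule-ensemble simplification; correlated rules (a stump and
  its refinement) double-count.
- *Missingness is ignorable.* A condition on a missing marker silently
  un-fires its rule (flagged in the output) rather than erroring, mirroring
  the upstream convention that missing entries are excluded from
  calculations.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_support_frac` | 0.10 | fraction of training set | support floor `ceiling(0.10 n)`; rules below it are anecdotes |
| `min_confidence_pct` | 70 | percent | strict `>`; the boundary value 70.00 is excluded |
| `max_depth` | 2 | levels | matches the 1–2 condition rule inventory |
| `text_confidence` | 75 | percent | pseudo-confidence of text rules, which carry no measured `Pr`; set between the filter floor and the strongest numeric rules |
| aggregation policy | `confidence_weighted` | — | pluggable (`majority`, `first_match`); ties and the no-fire case default to healthy, the majority class |
| scale target | 0–10 integers | — | `round_half_up(10 (x−min)/(max−min))`, clamped |
| split sizes | 24+24 test, 25+25 training | participants | the evaluation protocol's class-balanced counts |
| `n_runs` | 30 | runs | repeated-run mean ± SD reporting |

Inversion rules are exempt from the confidence filter (they document the
complement of a retained stump, and complements of >70 % rules are usually
below 70 %) but still require the support floor.

## What the synthetic generator emulates

`generate_cohort()` emits 124 participants by default — 75 healthy, 49 MCI,
89 female, ages from a normal (mean 70.48, SD 8.72 years) truncated at the
50-year inclusion floor, at least 14 sensor days per participant and a 14 %
missing-day rate. Two calibration choices deserve note:

- *Truncation without bias.* Naively truncating N(70.48, 8.72²) at 50
  raises the mean by ≈ 0.22 years. The generator instead solves for the
  location parameter whose *truncated* mean equals the configured
  `age_mean`, so both the floor and the mean hold simultaneously.
- *Exact counts.* Label and sex counts are assigned exactly (not by
  Bernoulli draws) so count assertions are sharp for every seed.

Class-conditional effects are planted in the directions the rule inventory
encodes: the MCI class has lower daily activity, rarer and shorter
excursions from home, lower EMA compliance, lower and more variable
mental-sharpness responses, a lower n-back start and plateau with a steeper
learning ramp and noisier daily scores, sparser (possibly empty) journals
drawn from a short negative-word pool, and more interview ratings ≤ 3.
Because no class-conditional distributions of raw markers are published,
all effect magnitudes are free parameters of the stated world, chosen once
to be strong: a green recovery test establishes that the pipeline can find
planted structure, *not* that real cohorts are this separable (real marker
distributions overlap heavily and published accuracies sit near 0.77, far
below what these synthetic effects allow).

Raw 10 Hz streams are not emulated. The generator emits what the marker
layer consumes: per-day acceleration totals and 300 location readings per
non-missing day, as a two-cluster mixture (a tight home cluster holding at
least 55 % of the day's readings — so the home cell wins the plurality by
construction — plus an excursion cluster at a class-dependent radius).
n-back scores follow a linear ramp over the first 6 days to a plateau,
with class-dependent noise, clamped to [0, 1]. It does not model GPS noise
pathologies, time zones, circadian structure within days, or audio.

## Numerical and procedural choices

- *Home detection.* "Most frequently visited location" is made precise as
  the most populous cell after snapping the first `min(300, n)` readings to
  a 10 m grid, ties broken by the earliest-visited cell. The participant
  home used for distances is the modal daily home over the wear period.
- *Daily distance.* The mean (not maximum) per-reading distance from home;
  configurable in principle, mean chosen as the stabler aggregate.
- *Variance convention.* Population variance (divisor *n*) throughout the
  marker layer; `shape_score_sd` is the population SD.
- *Rounding.* `round_half_up` (half away from zero), not banker's
  rounding, so scaled values are platform-stable.
- *Tie-breaks in the tree.* Lowest-index marker, then lowest threshold;
  leaf majorities tie toward healthy. The tree is therefore fully
  deterministic without a seed; seeds only enter through bootstrap
  resampling when `n_trees > 1`.
- *`Pr` semantics.* Confidence is the antecedent-conditional class fraction
  measured by a linear scan of the training set — the only reading
  consistent with pairs like (100.00, 6) in the shipped inventory — and is
  always re-measured, never read off tree node counts.
- *Multiple trees.* The shipped inventory contains mutually inconsistent
  thresholds on the same marker (2.5 vs 5.5 on `mental_sharpness_mean`),
  which a single tree cannot produce; an `n_trees` option fits seed-varied
  bootstrap trees and de-duplicates the pooled rules, but defaults to 1.
- *Sentence complexity.* Undefined upstream; implemented as a clause-count
  proxy (1 + commas + subordinating/relative markers per sentence) so that
  it is not simply a duplicate of mean sentence length. The rich/sparse
  journal predicates fire when at least 2 of the 3 features (vocabulary,
  sentence length, complexity) are strictly above/below the reference
  medians, making them mutually exclusive and threshold-symmetric.
- *"Some" / "most".* "Some" is ≥ 1; "most" is strictly more than half of
  the present ratings. "Confidently answered" is surrogated as no present
  rating below 4, "struggled" as a mean rating below 3; both are
  deterministic stand-ins for judgments an LLM would make from transcripts.
- *Prompt contract.* The deterministic backend receives only the rendered
  prompt and reconstructs rules, markers, journal text and ratings from it,
  so the prompt→response→parse loop is closed and testable. Numeric rule
  lines carry their `# pr=.. pa=..` stats precisely so the response is
  computable from the prompt alone.
- *Wrapper scoring.* What data the greedy search should score on is
  unspecified upstream; stratified 5-fold cross-validation of the training
  set is used to avoid test leakage, since held-out test results are
  reported separately. Ties prefer fewer rules, then the fixed group order.
- *Run-to-run variability.* Published SDs stem from LLM nondeterminism,
  which has no analogue here; the configurable analogue is split
  resampling (`mode = "resample_split"`). With a fixed split the engine's
  SD is exactly 0, and the determinism test asserts exactly that.
- *MCC convention.* 0 when any denominator factor is 0; precision/recall
  likewise 0 on empty denominators.

## Limitations

- Generator effect sizes are stipulations, not estimates; absolute metric
  values on synthetic cohorts do not transfer to real populations.
- The text layer is lexicon- and threshold-based; it deliberately does not
  model transcription error, disfluencies, or semantic content, and the
  interview-explanation predicates are rating-based surrogates.
- The external-backend adapter is exercised only through injected mocks;
  no network client ships with the package.
- The wrapper search is greedy forward-only; it will not find
  complementary pairs whose singletons are individually useless.
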