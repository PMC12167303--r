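---
title: "Benchmarking surgical phase recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking surgical phase recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprbench)
```

## The problem

Surgical phase recognition (SPR) segments a surgical video into its workflow
phases. Benchmarking *who* recognises phases better — clinicians of varying
expertise, or frame-level computer-vision models, with or without temporal
context — requires a carefully controlled question-sampling design, shared
metrics, and a paired statistical protocol. `sprbench` implements that
machinery for two phase schemas: the 15-phase robot-assisted partial
nephrectomy (RAPN) workflow, a long and highly nonlinear procedure, and the
7-phase laparoscopic cholecystectomy workflow. Because the underlying
surgical videos are private, the package ships a synthetic-data layer that
emulates every data source the benchmark needs — procedure timelines,
survey respondents, frame-level predictors — so the whole pipeline runs,
and is tested, end-to-end on any machine.

## Timelines

A procedure is an ordered list of half-open segments `[start_s, end_s)`
labelled with schema phases. Three representation choices matter:

* **Half-open intervals, 0-based seconds.** The start instant belongs to a
  segment, the end does not, so adjacent segments tile time without
  ambiguity and per-frame label tables (frame `i` covering
  `[i/fps, (i+1)/fps)`) convert exactly.
* **Recurring phases.** RAPN workflow is nonlinear; nothing forces a phase
  to be contiguous. A phase may own several segments and its duration is
  the sum over them. The timestamp sampler works in *phase-relative* time
  (seconds of elapsed phase time) and walks the segments to map back to
  absolute time.
* **Gaps are legal** and mean discarded footage (out-of-body sequences,
  ambiguous transitions). Samplers never place a timestamp, or a snippet
  window, across a gap.

## The survey sampler

For each procedure the sampler emits `n_samples = 17` timestamps, each
yielding two question items: the single frame at the timestamp and the
video snippet of the 10 s preceding it.

* **Allocation.** Every phase present gets one timestamp; the
  `17 - 15 = 2` extras go one each to the phases longer than 10 min, in
  descending duration order (schema order breaks ties), falling back to the
  longest remaining phases when fewer than two exceed the threshold.
* **Within-phase draws.** Phase-relative positions are drawn from
  `Normal(0.5 D, 0.1 D)` for a phase of duration `D` and accepted only
  inside the trimmed band `[0.05 D, 0.95 D]`. Truncation is by rejection,
  not clipping: clipping would pile probability mass on the band edges and
  break the draw-scale property `sd ≈ 0.1 D` that the tests verify. The
  trim fractions are read as fractions of elapsed phase *time* — the only
  reading that is independent of any sampling resolution.
* **Spacing.** Timestamps closer than 30 s are redundant; draws violating
  the spacing against already-accepted timestamps are rejected and redrawn
  (up to `max_retries`). If a draw cannot be placed, the most crowded
  phase's draws are discarded and resampled once; if spacing still cannot
  be satisfied the sampler raises an error naming the phase.
* **Snippet feasibility.** By default a snippet may not reach back across
  the phase boundary, enforced by requiring the phase-relative position to
  be at least the snippet length — but only when that constraint is
  *feasible*, which the package defines as the snippet length not exceeding
  the phase midpoint `0.5 D`. For phases barely longer than the snippet,
  enforcing the bound would push draws 3–5 sigma into the tail of the
  midpoint-centered normal; such snippets are instead allowed to cross into
  the preceding (contiguous) footage. Snippets must always lie entirely
  inside annotated footage, so they never span a gap.

Long-tailed duration distributions occasionally produce procedures whose
geometry admits no valid draw set at all — two adjacent phases jointly
shorter than about a minute cannot hold two midpoint-concentrated draws
30 s apart, and an opening phase shorter than 10 s can hold no snippet
window. The sampler reports these as errors; the survey simulator responds
the way the original study design could, by assigning the participant the
next unused procedure from a pool larger than the participant count, and
logs the skip.

## Metrics

Raters and predictors are scored against a k×k confusion matrix (rows =
true phase, columns = answer) with three statistics:

* **Accuracy**: trace over total.
* **Weighted F1**: per-class F1 (0 when precision + recall is 0), weighted
  by true-class support; zero-support classes are excluded.
* **Normalized L½ spread**: for each positive-support row, normalized to
  probabilities `p`, the statistic `(Σ√p_i)²` — 1 for a one-hot row, `k`
  for a uniform row. This is the unique power-mean reading consistent with
  those two endpoints. Row scores are averaged and rescaled to `[0, 1]` by
  `(mean − 1)/(k − 1)`. It measures *answer dispersion* — a rater can be
  concentrated (spread 0) and still always wrong. Zero-support rows are
  excluded from the average rather than imputed: imputing one-hot or
  uniform rows would bias the spread in opposite directions.

Group reports average the per-participant metrics by default (`"Average
accuracy"` semantics); pooled-matrix mode is available via
`mode = "pooled"`. The distinction matters enormously for the spread
statistic: a participant answers only 17 questions over 15 phases, so
per-participant confusion rows have support 1–2 and are nearly one-hot,
giving spreads near 0 regardless of competence. Group-level answer
dispersion on the scale published for this benchmark (0.2–0.6) only emerges
from pooled matrices; users comparing against published group tables
should use pooled mode for the L½ column.

## The inferential layer

* **Wilcoxon signed-rank** on within-participant accuracy differences
  (snippets minus frames). Zero differences are discarded (the classical
  rule), ties in |d| get average ranks, and the statistic is
  `W = min(W+, W−)`. With ≤ 25 tie-free differences the two-sided p-value
  is exact (the signed-rank null distribution); otherwise a normal
  approximation with tie correction and continuity correction is used. The
  switch point keeps the group-size regime of a survey (tens of
  participants) bit-for-bit reproducible wherever exactness is feasible.
* **Bonferroni**: the family-wise α = 0.05 is divided by the number of
  groups compared; rejection requires `p` *strictly* below the corrected
  threshold, so boundary ties fail conservatively. The number of
  comparisons is always taken from the data, never hard-coded.
* **Spearman rank correlation** (tie-aware, average ranks) with a
  two-sided t-approximation p-value on `n − 2` degrees of freedom, used for
  accuracy-vs-confidence and accuracy-vs-difficulty analyses.

## The synthetic-data layer

### Timelines

Per-phase durations are drawn from a family moment-matched to the published
duration table (mean ± SD in minutes, converted to seconds at the config
boundary):

* **lognormal** (default) — matches any (mean, sd) exactly via
  `sdlog² = log(1 + cv²)`. Chosen as default because several RAPN phases
  have sd ≥ mean (hilar clamping 2.0 ± 4.7 min), i.e. coefficients of
  variation above 1, which no positive-support (truncated) normal can
  reach.
* **truncated-normal** — the parent (μ, σ) is solved numerically so the
  truncated moments match; for cv ≥ 0.99 no solution exists and the
  generator warns and falls back to lognormal for that phase.
* **degenerate** — every phase takes exactly its mean; used for exact
  bookkeeping checks (the 15 RAPN means sum to 147.9 min).

The published RAPN mean *total* duration (122.3 min) is smaller than the
sum of the per-phase means (147.9 min) — presumably because not every phase
occurs in every recording. The generator deliberately does **not** rescale
to reconcile the two; it reproduces the per-phase table, which is what the
sampler consumes. Phases are laid out as single segments in schema order by
default; `split_prob` optionally splits phases into recurring segments to
exercise the nonlinear representation, but no recurrence statistics were
published, so it is off by default.

### Respondents

A respondent of a group answers the true phase with probability
`p_correct_frame`, plus `snippet_boost` for snippet questions. Wrong
answers fall on other phases with probability proportional to
`adjacency_spread^distance` in schema order — a stand-in for temporal
confusion between neighbouring workflow steps; no confusion kernel was
published, and this one-parameter geometric kernel is the simplest that
concentrates errors on adjacent phases.

Correctness on the *same timestamp* is coupled across modalities: both
draws share a per-item difficulty latent with probit-scale correlation
`item_coupling` (default 0.8). This reflects the survey design — the
snippet physically contains the sampled frame, so an item that is
unrecognisable as a frame (blur, bleeding, an uninformative view) tends to
stay hard with 10 s of context, while the boost captures the cases the
added context resolves. The coupling is what makes the within-participant
paired design efficient; with independent draws the paired test would be
far weaker than the study's design intends. Group defaults emulate the
published group performance: frame accuracies 0.303 / 0.415 / 0.412 and
snippet gains 0.133 / 0.114 / 0.120 for medical students, surgical
trainees and consultants respectively.

Confidence ratings (1–5) come from an ordinal probit-style model whose
latent is correlated with correctness at `confidence_correlation`
(default 0: the study found no significant accuracy–confidence
correlation, and the default reproduces that null). Response times are
lognormal with a 10-s median. Anchoring, learning and fatigue across the
34 questions are *not* modelled; the respondent model is statistical
plumbing, not a cognitive claim — so passing tests certify the pipeline's
arithmetic and operating characteristics, not human behaviour.

### Predictors

`simulate_ai_predictions()` is a desk-scale stand-in for frame-level
models: at each annotated second (1-Hz cadence, each second scored at its
midpoint) it emits the true phase with a configurable per-phase
probability, else a uniform wrong phase, then applies a trailing
majority-vote window (`smoothing_window_s`) that emulates temporal
context; the window never crosses footage gaps, and ties keep the raw
prediction. Scoring external prediction files uses the same three metrics
as the survey; predictions falling in gaps are dropped with a warning.

## Operating characteristics

The test suite verifies, at the study's stated conditions (30 participants
per group, 17 items per modality, α = 0.05 Bonferroni-corrected across 3
groups):

* **Size**: with `snippet_boost = 0`, per-group rejection stays within two
  standard errors of α/3 over 200 simulated surveys.
* **Power**: with `snippet_boost = 0.10`, the pipeline rejects the no-gain
  hypothesis for *all three* groups in at least 90% of 200 simulated
  surveys.
* **Recovery**: configured respondent and predictor accuracies are
  recovered within two binomial standard errors; simulated per-phase
  durations recover the published means within three standard errors over
  1,000 procedures; 10,000 within-phase draws recover the midpoint mean
  and the 0.1-duration sigma.

Problem sizes used throughout the suite (10,000 draws for distributional
checks, 1,000 procedures for moment recovery, 200 surveys of 90
participants for size/power) are the package's chosen balance between
Monte-Carlo error and a test suite that runs in minutes on one CPU.

## Numerical conventions and edge cases

* Probability-vector validation in `lhalf_row()` tolerates 1e-9 deviation
  from unit sum; anything larger is a user error, not noise.
* `wilcoxon_signed_rank()` refuses all-zero difference vectors ("test
  undefined"); the pipeline maps that case to an explicit `NA` p-value and
  a non-rejection rather than dropping the group silently.
* `spearman_rho()` refuses constant inputs; |rho| = 1 reports the smallest
  representable p-value rather than 0 so p-values stay in (0, 1].
* All randomness flows through R's RNG: a single integer seed at the
  survey/cohort/benchmark level reproduces every downstream artifact
  bit-for-bit. Item-level draws consume the stream in a fixed order
  (participants in assignment order; frames before snippets).
* Reports print percentages to one decimal; underlying data frames and
  CSVs keep full precision.

## Limitations

* The generator emulates the published duration table and group accuracy
  levels, not real visual content: no blur/bleeding/fog quality model, no
  landmark semantics, no per-phase difficulty differences unless configured
  per phase.
* The adjacency-confusion kernel and item-difficulty coupling are
  parsimonious stand-ins for unpublished structure; conclusions about
  *which* phases confuse raters should come from real response data scored
  with this package, not from its simulator.
* The exact oversampling arithmetic beyond "one extra per long phase" and
  the original study's resolution of infeasible spacing geometries are not
  published; the package's rules (documented above) are its own fixed
  choices.
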