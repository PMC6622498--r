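---
title: "Measuring lexico-semantic structure and its effect on toddler word recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lexico-semantic structure and its effect on toddler word recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexigaze)
```

## The scientific problem

Around 18 months of age, toddlers differ enormously in how many words they
produce (roughly 10 to 374 words on a parent-report checklist) and in how
those words relate to one another.  `lexigaze` implements an individual-level
analysis of how the *structure* of a child's productive vocabulary — not just
its size — relates to real-time word recognition measured with eye tracking.
Structure is quantified at three granularities:

* **Word level — degree.**  Each child's lexicon is turned into an undirected
  semantic network: nodes are the nouns the child produces, and two nouns are
  linked when they share at least two perceptual and/or functional features
  in an adult feature-norm database (taxonomic and encyclopedic features are
  excluded, keeping the edges grounded in properties a toddler can
  experience directly).  A target word's degree is its number of neighbours.
* **Category level — semantic density.**  For six early-acquired categories
  (ANIMALS, CLOTHING, VEHICLES, BODY-PARTS, FRUIT, DRINKS, with 43, 28, 14,
  27, 7 and 7 checklist items respectively), the proportion of each category
  the child produces is rank-ordered; the child's top three categories are
  labelled High density and the bottom three Low.  If ranks 3 and 4 are
  tied, every category tied at that value goes High, so the High set can
  exceed three.  Because the split is within-child, density is controlled
  for overall vocabulary size.
* **Lexicon level — global clustering coefficient (GCC).**  The transitivity
  of the child's network: `3 * triangles / connected triples`, where a
  connected triple is a path of length two.  The factor of three is forced
  by the convention that a fully connected lexicon — where *all* triples are
  closed — scores 1; a literal triangles/triples quotient would give a
  complete triad 1/3.

Recognition is measured in a looking-while-listening task: on each trial two
images appear, one is named, and gaze is sampled at 500 Hz.  Trial-level
accuracy is the log-gaze proportion ratio
`log(P_target / P_distractor)` over a 300–2000 ms window after label onset:
zero means equivalent looking, positive values a target preference.

## Normalising category proportions

Two readings of "the proportion of words said in each category" are
possible: dividing by the category's checklist size, or by the child's total
productive vocabulary.  The package defaults to **per-category-size**
(produced-in-category / category size) because observed assignment rates
pattern with it: a small category such as FRUIT (7 items) is frequently a
child's densest category while a large one such as CLOTHING (28 items)
rarely is, which a share-of-total metric would invert by rewarding sheer
category size.  The share-of-total normalisation remains available as
`mode = "per-total-produced"` in `category_proportions()`.

## Gaze preprocessing choices

* **Windows and bins are half-open.**  The analysis window `[300, 2000)` at
  2 ms spacing contains exactly 850 samples; 50 ms bins tile `[0, end)`.
  Area-of-interest rectangles are half-open in both axes, so a sample
  exactly on the right edge of a 400-pixel AOI falls outside it.
* **Smoothing.**  The ratio is undefined when either count is zero, so both
  counts receive an additive constant `c = 0.5` by default.  This keeps the
  statistic antisymmetric under swapping target and distractor and always
  finite; `c = 0` is available, in which case zero-count trials are flagged
  `undefined_ratio` and removed by a third filter stage.
* **Filters run sequentially** in the order used for the study bookkeeping:
  comprehension first (target rated below 2 on the 1–4 parental scale),
  then track loss (less than 20% of the window on screen) among the
  survivors.  "On screen" counts target, distractor *and* other on-screen
  samples, consistent with the timecourse denominators, which include
  off-AOI looks.  Every stage writes a ledger row with input, excluded and
  retained counts so that exclusions are conserved and auditable.

## The models

For each condition (semantically related vs unrelated picture pairs, always
modelled separately) the package fits, by REML via `lme4`:

```
log_gaze ~ (gcc_z + degree_z + density_code) * group_code + (1 | item)
```

with follow-up per-vocabulary-group fits of
`log_gaze ~ gcc_z + degree_z + density_code + (1 | item)`.  Categorical
predictors are sum coded (High = −0.5, Low = +0.5); continuous predictors
are centred and standardized with the sample (n−1) SD *within the modelled
subset*, so each per-condition or per-group model is standardized over its
own trials.  Vocabulary groups come from a median split of total productive
vocabulary, with scores equal to the median going High (with 79 children
this yields a 40/39 split).  Participants are deliberately not a random
effect — with roughly 22 retained trials per child spread over 12 items,
child intercepts are weakly identified and routinely prevent convergence —
so a single item intercept is the only grouping factor.  P-values default
to the normal approximation on t; a Satterthwaite mode is available through
`lmerTest` and is recorded in every report footer.

## What the synthetic cohort emulates

`simulate_cohort()` generates a full study from a seed, and doubles as the
package's fixture factory (`write_cohort()` emits every table in the exact
input formats the readers expect).  Its defaults are the study conditions:

* **Vocabulary sizes**: a log-normal (meanlog 4.1088, sdlog 1.4244)
  truncated to [10, 374], calibrated so the truncated distribution has mean
  92.1 and median 61 words; sizes are drawn i.i.d. per child.  The
  synthetic checklist has 680 words: the six experimental categories at
  their canonical sizes plus filler sections.  The norms cover all
  checklist nouns — the six categories and a 200-word general-noun section
  — while non-noun fillers (actions, descriptives, and so on) count toward
  vocabulary size but never become network nodes.
* **Category composition**: each child samples words under Dirichlet
  category weights (concentration 12 around checklist base rates), so
  density rankings genuinely vary across children.
* **Feature norms**: each concept carries private features of all four
  classes plus a taxonomic category marker (which the class filter must
  ignore); each concept pair within one experimental category
  independently receives a dedicated perceptual + functional
  shared-feature pair with probability 0.35; every other noun pair —
  across categories, or within the unstructured general-noun section —
  shares with probability 0.03.  An edge at the default threshold of 2 is
  therefore an independent coin flip with exactly these probabilities,
  which makes the generator's edge statistics directly testable.
* **Design**: the counterbalanced 24-trial layout over the twelve
  experimental items — 12 related and 12 unrelated trials; every image
  appears four times (twice as target, twice as distractor, once per role
  in each condition) and equally often left and right.  One pairing label
  in the published materials ("Teeth") does not occur in the stimulus list;
  the generator treats it as a typo for "Mouth" and uses the twelve listed
  items.
* **Gaze streams**: a four-state Markov chain (target, distractor, other
  on-screen, off-screen) at 2 ms steps over [0, 4000) ms.  Before a 500 ms
  latency — matching the observed onset of target preference — the chain's
  stationary distribution is uniform over on-screen states; afterwards the
  target/distractor odds are `exp(eta)` with

  `eta = beta0 + beta_cond * related + sum_k beta_k * x_k * (1 + gamma_k * group_code) + item intercept`.

  The stay-probability default (0.97 per 2 ms step, mean state run ≈ 67 ms)
  was chosen so that the trial statistic reads out `eta` approximately
  unbiased: with much longer runs the window holds so few independent
  fixation runs that the log-count ratio systematically overshoots the
  stationary log-odds.  Run lengths on this order are shorter than typical
  toddler fixations; the generator aims for statistical transparency of the
  injected effects, not oculomotor realism (saccade dynamics are out of
  scope).
* **Default effect structure** mirrors the directions reported for this
  paradigm: lexicon-level connectivity hurts recognition
  (`beta_gcc = −0.3`) with the interference concentrated in the
  high-vocabulary group (`gamma_gcc = −1`), and category density helps
  (`beta_density = +0.3` on the −0.5/+0.5 code) with the effect
  concentrated in the low-vocabulary group (`gamma_density = +1`, giving a
  low-group effect of 0.45 — the magnitude reported for that group).  A
  word-degree effect of 0.15 is included so all three predictors carry
  signal.  Item intercepts have SD 0.15.
* **Filter traffic**: each child × item comprehension rating falls below 2
  with probability 0.048 (the reported comprehension-exclusion rate), and
  5% of trials are "fussy" with a 0.9 off-screen stationary probability,
  producing a track-loss exclusion rate near the reported 4.3%.

Every trial draws from its own seed sub-stream keyed by trial id
(`substream_seed()`), so reordering trials never changes the numbers drawn,
and the realized coefficients and item intercepts are serialized as
`sim_truth.json` — the oracle for recovery tests.

### What passing tests do and do not show

The generator exercises every pipeline stage — AOI labelling, binning,
filtering, the statistic, coding and the mixed models — under known truth,
and the test suite verifies sign recovery of injected effects in ≥90% of
replicated cohorts and near-nominal (2–10%) false-positive rates for null
structure terms.  That validates the *machinery*.  It does not show that
real toddler data satisfy the generator's assumptions: real gaze has
saccade dynamics, drift and calibration error; real vocabularies have
richer category structure than a Dirichlet mixture; real feature norms
have correlated, non-dedicated feature overlap; and real children
contribute child-level variance that the item-only random-effect structure
absorbs into the residual.  Reproducing the published coefficient values
requires the original dataset (available from the study's public archive)
through the file-input path of `run_pipeline()`.

## Numerical and degenerate-input conventions

* Ranking ties (other than the 3/4 rule) break by category name, so runs
  are deterministic; a child producing nothing has all-zero proportions and
  falls into the all-High degenerate path with a warning, never silently.
* `global_clustering()` is 0 when a network has no connected triples.
* Triangle counts use the adjacency identity `trace(A^3)/6`; triple counts
  `sum(choose(degree, 2))`.  Both are validated exactly against exhaustive
  triple enumeration on ≥1000 random graphs.
* A constant model response (zero variance) cannot inform REML; the fit
  falls back to the exact fixed-effects least-squares solution and is
  flagged.  Degenerate predictors (zero variance in a modelled subset) are
  rejected with an explicit error — at very small cohort sizes the
  low-vocabulary group can have uniformly zero GCC, which aborts the run
  rather than fitting an unidentified model.
* Boundary (singular) variance estimates are reported via the `singular`
  flag and are not treated as convergence failures.

## Problem sizes used in the shipped studies

The packaged recovery study uses 100 replicated cohorts of 79 children ×
24 trials, and the null-calibration study 200 cohorts, both at the default
generator settings; unit tests use cohorts of 4–20 children.  These sizes
give binomial standard errors of ~3% on a 90% sign-recovery rate and
~1.5% on a 5% rejection rate, which is adequate to detect the failures the
tests guard against.

## Known limitations

* Degree for targets the child does not produce defaults to the augmented
  network (the target node plus its qualifying edges into the produced
  lexicon); `target_mode = "zero"` scores them 0 instead.  Which behaviour
  the original analysis used is not documented, so both are exposed.
* The pipeline models conditions separately by design; pooled three-way
  interaction models are intentionally not provided.
* Saccade/fixation event parsing, drift correction and calibration are
  upstream of this package and out of scope.
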