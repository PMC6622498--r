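# lexigaze

Individual differences in *what* toddlers know shape *how fast* they
recognise words.  `lexigaze` is an R package for relating the structure of
an 18-month-old's productive vocabulary to real-time word recognition in a
looking-while-listening eye-tracking task.  It is written for developmental
psycholinguists who have (a) parent-report vocabulary checklists, (b) a
feature-norm database, and (c) per-trial gaze streams, and who want the
whole analysis — network construction, gaze preprocessing, mixed-effects
inference — as one reproducible, audited pipeline.

## What it computes

**Structure metrics.**  Each child's produced nouns become an undirected
semantic network: an edge links two nouns that share at least two
perceptual and/or functional features in the norms.  From this network the
package computes

* *word degree* — the number of semantic neighbours of each target word,
  `deg(w)`;
* *global clustering coefficient* — the network transitivity
  `C = 3T / P`, where `T` is the number of closed triangles and
  `P = Σ_v C(deg(v), 2)` the number of connected triples, so `C ∈ [0, 1]`
  with 1 meaning every triple is closed;
* *category density* — within each child, the six experimental categories
  (ANIMALS, CLOTHING, VEHICLES, BODY-PARTS, FRUIT, DRINKS) are ranked by
  the proportion produced; the top three are High density, the rest Low,
  with rank-3/4 ties going High.

**Gaze statistic.**  Trials are binned into 50 ms intervals and scored with
the log-gaze proportion ratio over the 300–2000 ms post-label window:

```
log_gaze = log((n_target + c) / (n_distractor + c)),   c = 0.5
```

Zero means equivalent target/distractor looking; positive values a target
preference.  Trials are filtered sequentially — comprehension rating < 2,
then < 20% on-screen looking — with a conserving exclusion ledger.

**Inference.**  Per condition (semantically related vs unrelated picture
pairs), REML linear mixed models via `lme4`:

```
log_gaze ~ (gcc_z + degree_z + density_code) * group_code + (1 | item)
```

with sum-coded factors (High = −0.5, Low = +0.5), within-subset
standardized continuous predictors, item-only random intercepts, and
follow-up structure-only fits per median-split vocabulary group.

**Synthetic cohorts.**  Because child data cannot be shipped,
`simulate_cohort()` generates a complete study — checklist, feature norms,
vocabularies calibrated to the published size distribution (mean 92.1,
median 61, range 10–374), the counterbalanced 24-trial design, ratings and
500 Hz four-state Markov gaze streams with a known effect structure — and
records the generative truth for recovery testing.  See the methods
vignette (`vignettes/lexigaze-methods.Rmd`) for every assumption and
default.

## Worked example

```r
library(lexigaze)

cfg <- sim_config(seed = 1)          # 79 children, study-scale defaults
res <- run_pipeline(cfg, "run1")     # writes tables, reports, figures

res$filtered$ledger
#>             stage n_in n_excluded n_retained pct_excluded
#> 1      low_rating 1896        102       1794     5.379747
#> 2      track_loss 1794         84       1710     4.682274
#> 3 undefined_ratio 1710          0       1710     0.000000

print(res$models$related_all)
#> <mixed model> log_gaze ~ (gcc_z + degree_z + density_code) * group_code + (1 | item)
#>   853 trials, 12 items; converged
#>                     term estimate     se      t        p
#>              (Intercept)   0.8830 0.0678 13.000 9.33e-39
#>                    gcc_z  -0.3340 0.0590 -5.670 1.45e-08
#>                 degree_z   0.1450 0.0695  2.080 3.75e-02
#>             density_code   0.3100 0.0695  4.460 8.21e-06
#>               group_code  -0.0766 0.1040 -0.735 4.63e-01
#>         gcc_z:group_code   0.4090 0.1180  3.470 5.19e-04
#>      degree_z:group_code  -0.0187 0.1320 -0.142 8.87e-01
#>  density_code:group_code   0.2020 0.1380  1.470 1.43e-01
```

Reading this output: of the 1896 simulated trials, 102 fail the
comprehension filter and 84 of the survivors fail track loss, leaving 1710
for analysis — bookkeeping on the same scale as the study the defaults
emulate.  In the related condition the positive intercept (0.88) is the
overall target preference; the negative standardized
clustering-coefficient effect (−0.33, generated as −0.3) is the injected
lexicon-level interference, and the positive `gcc_z:group_code`
interaction (0.41, generated as +0.3 on this coding) places that
interference mostly in the high-vocabulary group.  `run1/` then contains
the metric tables, the trial accuracy table and exclusion ledger, the
binned timecourse table, `model_report.txt` with all six model panels and
fixed-effect correlations, figures, and a `manifest.json` recording
configuration, seeds and stage counts.

A thin command-line wrapper is installed at `inst/cli/lexigaze`:

```sh
Rscript inst/cli/lexigaze --seed 1 --outdir run1
```

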