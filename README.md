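# behavephen

Behavioural phenotyping pipelines for mouse motor and learning tasks.

Slowly progressing mouse models of Huntington disease — heterozygous CAG
knock-in lines compared with wild-type littermates — show behavioural
deficits that are subtle, sex-dependent, and badly confounded by body
weight: manifest mutants are ~10 g lighter than littermates, and weight
itself changes rotarod and water-maze performance. `behavephen` implements
the full analysis stack for four assays used to phenotype such cohorts, for
researchers who have keypoint-tracking tables and operant event logs and
need reproducible, weight-corrected readouts:

* **Open field** — distance per 5-min bin, habituation as percent change
  versus the first bin (`100·(dᵢ−d₁)/d₁`, with decay rate from the
  log-linear fit `log dᵢ = log d₁ − λ(i−1)`), centre-zone time, and
  bout statistics of behaviour-classifier labels, with rearing scored away
  from the wall.
* **Accelerating rotarod** (5→40 rpm over 300 s) — both protocol
  semantics (one-rotation-equals-fall vs three consecutive rotations),
  hind-paw slip detection (paw below the rod bottom), slips/min with the
  20-s exclusion, and weight-normalized latency
  `latency × weight / mean(mutant weight)`.
* **Water T-maze** — time to platform (30-s guide cap), weight-normalized
  time (`time ÷ weight-factor`), arm entries with hysteresis,
  decision-point dwell, stop/start acceleration counts, probe-trial
  strategy (egocentric vs allocentric), reversal eligibility, swim speed.
* **Home-cage lever task** — log refinement, the three-phase state machine
  (100 rewarded nose-pokes → pulls beyond 8° → the 12–21° goal band of the
  25° lever range), 24-h performance bins, the 16 ± 2-day / 60-day stopping
  rule, and logistic learning-curve fits.
* **Statistics** — two-way (optionally repeated-measures) ANOVA, Sidak
  correction `1−(1−p)^m`, pooled t tests, Pearson r, and Fisher's z test
  `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3)+1/(n₂−3))` for comparing
  correlations.

Because the underlying animal recordings are not distributable, the package
ships a seeded synthetic-data generator that emulates all four input kinds
with planted ground truth (weight offsets, habituation decay, Poisson slip
events, junction dwell, logistic learning curves), so every detector is
verifiable exactly. See `vignette("behavephen-methods")` for the models,
parameter defaults, and the generator's scope and limits.

## Worked example

```r
library(behavephen)

coh <- gen_cohort(c(mutant = 12, wildtype = 15), seed = 1)
coh
#> <cohort> 27 animals (12 mutant / 15 wildtype)
#>    animal_id genotype sex age_group strain weight_g
#> 1     mutM01   mutant   M  manifest     B6 34.62144
#> ...

ctx <- normalization_context(coh)
ctx
#> <normalization_context> reference weight 31.63 g (n = 12)

# one wild-type open-field hour: binned distance and habituation
a <- coh[coh$animal_id == "wtM01", ]
sess <- gen_open_field(a, duration_s = 3600, seed = 1)
b <- bin_distance(distance_series(sess$track), 30)
b
#> <binned_distance> 12 bins of 300 s, total 16878.2 cm
round(habituation_percent_change(b)[c(1, 6, 12)], 1)
#> [1]   0.0 -38.6 -57.6
fit_habituation(b)$lambda        # planted decay was 0.08 per bin
#> [1] 0.0799

# one rotarod trial: endpoint, slip detection, weight normalization
tr <- gen_rotarod_trial(a, day = 1, seed = 1)
trial_endpoint(tr, "standard")   # 51.9 s
nrow(detect_slips(tr))           # 6 (6 were planted)
normalize_latency(trial_endpoint(tr, "standard"), a$weight_g, ctx)
#> [1] 73.3
```

The animal habituates (distance falls 57.6% by the final bin) at the
planted decay rate; the slip detector recovers exactly the planted slip
events; and the heavy wild-type's 51.9-s latency normalizes to 73.3 s
against the 31.63-g mutant-mean reference.

`run_study(seed, out_dir = ...)` runs the whole pipeline — cohort, all four
tasks, ANOVA/correlation layer — and writes tidy per-table CSVs; a fixed
seed reproduces every file byte for byte.

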