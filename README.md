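# ecgmatch

Closed-set human identification from personalized 12-lead ECG beat
patterns.

The heart's electrical signature is a usable biometric: the relative
timing and geometry of the P, QRS and T waves differ between people and
are stable within a person over years. `ecgmatch` implements an
identification pipeline that works on *personalized beat patterns* — 500 ms
averaged PQRST templates per lead on a 1 ms grid — rather than raw ECG. A
probe recording (session T2) is compared against a gallery of enrolled
templates (session T1) and assigned the identity of the best-matching
gallery subject.

## Method

Each probe-reference pair is scored with seven features per lead, all on a
common [0, 100]% similarity scale:

* **COR-PQRST / COR-QRS** — cross-correlation of the 500 ms PQRST pattern
  and the 100 ms QRS pattern (30 ms before to 70 ms after the R-peak
  fiducial), with a fixed full-pattern-norm denominator:

  $$r(k) = \frac{\sum_i a(i)\,b(i+k)}{\sqrt{\textstyle\sum_i a(i)^2}\,\sqrt{\textstyle\sum_i b(i)^2}},$$

  summarized as the maximum over all lags, $r_{max}$, and the zero-lag
  value, $r_{lag0}$, each × 100 and clamped at 0.
* **AMP-QRS** — 100 × smaller/larger peak-to-peak QRS amplitude.
* **MATCH-QRS** — each pairwise-normalized QRS is approximated by a
  100 × 80 binary matrix over a 1 ms × 0.025 time-amplitude grid (±1 ms,
  ±0.05 tolerances); *EQUT* is the percentage of time columns where the
  two matrices overlap, and *EQUA* = 100 − *DIFA*, where *DIFA* is the
  normalized area between the non-overlapping parts of the two bands.

The similarity index of a pair is the mean of the feature × lead entries
enabled by an identification model (a binary 7 × 12 mask); identification
is the argmax of this index over the gallery, and accuracy (*AccID*) is the
percentage of probes assigned their true identity. Models are trained by
forward stepwise selection of feature-lead entries until training accuracy
stops improving, and evaluated as a function of gallery size by seeded
subset resampling with confidence intervals.

Because clinical two-session ECG databases are proprietary, the package
ships a seeded synthetic cohort generator (Gaussian-wave morphologies,
exact Einthoven/Goldberger limb-lead relations, chest-lead
electrode-misplacement noise between sessions) that reproduces the
statistical structure the method assumes. See the methods vignette
(`vignettes/ecg-identification.Rmd`) for the model, parameter defaults and
their rationale, and known limitations.

## Worked example

Train a model on one synthetic cohort, validate on an independent one, and
sweep the gallery size for three models:

```r
library(ecgmatch)
library(dplyr)

train_cohort <- prepare_cohort(
  generate_cohort(cohort_config(n_subjects = 50, seed = 42)),
  synth_reference())
valid_cohort <- prepare_cohort(
  generate_cohort(cohort_config(n_subjects = 50, seed = 99)),
  synth_reference())

model <- train_id_model(train_cohort)
model$trace
#> # A tibble: 3 × 4
#>    step feature     lead  acc_id
#>   <int> <chr>       <chr>  <dbl>
#> 1     1 r_max_pqrst I         92
#> 2     2 r_max_pqrst aVF       98
#> 3     3 r_max_pqrst V5       100

sweep <- function(m) {
  evaluate_size_sweep(valid_cohort, m, sizes = c(10, 30, 50),
                      n_resamples = 200, seed = 1)
}
bind_rows(trained = sweep(model), full = sweep(id_model()),
          `lead II` = sweep(id_model(lead_mask("II"))), .id = "model") |>
  select(model, n_subjects, mean_accid, ci_halfwidth)
#> # A tibble: 9 × 4
#>   model   n_subjects mean_accid ci_halfwidth
#>   <chr>        <int>      <dbl>        <dbl>
#> 1 trained         10      100          0
#> 2 trained         30      100          0
#> 3 trained         50      100          3.57
#> 4 full            10       99.1        0.444
#> 5 full            30       96.4        0.414
#> 6 full            50       94          7.08
#> 7 lead II         10       71.6        1.65
#> 8 lead II         30       50.5        0.927
#> 9 lead II         50       42         13.2
```

Reading the output: the stepwise-trained three-entry model generalizes
perfectly on this synthetic validation cohort; the full 84-entry model
dilutes strong correlation features with weaker amplitude and chest-lead
entries and declines from 99.1% to 94% as the gallery grows from 10 to 50;
a single-lead model degrades much faster (71.6% to 42%). The half-width
column is the 95% confidence interval across resampled subsets (Wilson
binomial for the single exhaustive full-gallery subset). `autoplot(sweep(model))`
draws the accuracy-versus-gallery-size curve.

A thin command-line wrapper over the same functions lives at
`inst/cli/ecgmatch.R` (subcommands `synth`, `train`, `identify`,
`evaluate`, `pipeline`), and `run_pipeline()` orchestrates
synth → train → evaluate → report from a single seed or YAML config.

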