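# binocsync

Analysis of small temporal asynchronies between the two eyes' fixations in
binocular reading eye-tracking.

When the two eyes read the same line of text, their fixations are yoked
only approximately: one eye often *starts* a fixation a few milliseconds
before the other, or *ends* it a few milliseconds later. These asynchronies
are systematic across the screen — left-eye advantages accumulate toward
the left of lines, right-eye advantages toward the right — and are a
candidate cue for *ocular prevalence*, the prioritisation of one eye's
input in the fused percept. `binocsync` is a pipeline for quantifying that
pattern, aimed at eye-movement researchers with per-eye fixation event
data (canonical CSV or EyeLink ASC fixation reports).

## What it computes

With start/end offsets defined as right-eye time minus left-eye time, and
offsets within ±2 ms (one 500 Hz sample, inclusive) counted as
simultaneous, each binocular fixation falls into a 3 × 3 typology:

|                 | end sync | left eye ends later | right eye ends later |
|-----------------|----------|---------------------|----------------------|
| **start sync**          | Syn | T1 | T2 |
| **right eye starts first** | T3 | T4 | T5 |
| **left eye starts first**  | T6 | T7 | T8 |

T1/T6/T7 are left-priority types, T2/T3/T5 right-priority; T4/T8 are
ambiguous and excluded from modelling by default.

The pipeline stages are:

1. **Pairing** — left/right fixation streams are matched one-to-one into
   temporally overlapping pairs by an exact dynamic program that maximises
   total overlap under a non-crossing constraint (C++ kernel, enumeration-
   validated).
2. **Typology** — offsets and the Syn/T1–T8 classification, with
   distribution summaries (share starting/ending synchronously,
   left/right-priority shares).
3. **Spatial** — pair position (right eye's mean coordinates), left/
   middle/right screen regions (default: thirds of a 1024 × 768 display),
   hexbin density grids.
4. **Count models** — per-cell fixation-pair counts modelled with Poisson
   GLMs and `lme4` GLMMs (`count ~ region + (1|participant) + (1|article)
   + (1|page)`, middle as reference, Laplace ML), nested models compared
   by likelihood-ratio test, reported in the conventional two-column
   null/region table with AIC/BIC (`k` = fixed coefficients + variance
   components).

Because raw binocular reading corpora are generally unavailable, the
package includes a synthetic generator (`simulate_reading_session()`) that
emulates 2 ms-quantized binocular streams over multi-line pages with
planted, Laplace-distributed start/end lags whose location drifts with
horizontal position — plus a count-table shortcut
(`simulate_count_table()`) with planted region effects for validating the
model layer.

## Worked example

```r
library(binocsync)

cfg <- sim_config(n_participants = 12, n_articles = 5,
                  pages_per_article = 4, seed = 1)
session <- simulate_reading_session(cfg)
pairs <- classify_pairs(pair_fixations(session$left, session$right))
pairs$region <- assign_region(pairs$x_px, cfg$screen)
type_distribution(pairs)
#> Asynchrony type distribution (n = 11305 binocular fixations)
#>   Syn    T1    T2    T3    T4    T5    T6    T7    T8
#> 52.22  8.17  6.42 14.94  0.93  4.07  8.45  4.44  0.36
#> aggregates (%):
#> start_synchronous   end_synchronous     left_priority    right_priority
#>             66.81             75.60             21.06             25.43
```

About half the simulated pairs are fully synchronous and three quarters
end synchronously; right-priority types outnumber left-priority ones.
Fitting the T6 (left-eye-priority) counts by screen region:

```r
t6 <- count_table(pairs[pairs$type == "T6", ], complete_zeros = TRUE,
                  types = "T6")
null_fit <- fit_poisson_glmm(t6, model_spec(region = FALSE))
full_fit <- fit_poisson_glmm(t6, model_spec(region = TRUE))
lrt_compare(null_fit, full_fit)
#> LRT: chisq = 1029.500, df = 2, p = 2.799e-224
```

The region model's `left` coefficient (+1.73 log units vs the middle
region) and negative `right` coefficient (−1.44) recover the planted
left-of-screen concentration of left-eye-priority fixations; the LRT says
region adds enormous explanatory power over the null model.

The same flow with artifact files and a run manifest:

```r
run_pipeline(pipeline_config(sim = cfg, out_dir = "out", seed = 1))
```

or from a shell, `Rscript inst/scripts/binocsync-run.R --config cfg.yaml
--seed 1 --out out`.

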