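# habslope

Neural habituation — the decline in response to a repeated stimulus — is a
basic sensory-filtering mechanism that is blunted in schizophrenia-spectrum
disorders, in regions spanning the anterior hippocampus and the ventral
visual stream. `habslope` measures habituation from repetition-task fMRI
ROI time-series and tests whether it differs between groups and changes
over a longitudinal follow-up.

The core quantity is the **novelty-normalized habituation slope**. For a
residual BOLD series *y(t)* in a region of interest, a habituation window
*[t_peak, t_return]* is defined on the baseline-visit control group as the
interval from the novelty peak to the first return to baseline. Within that
window,

- the novelty response *a* = *y(t_peak)*, the amplitude at window start;
- the raw slope *b* = OLS slope of *y* on time (signal units / s);
- the normalized slope **b′ = b / a** (per second), which is invariant to
  rescaling of the residual signal, so that groups can be compared on
  habituation *rate* independently of differences in novelty-response
  magnitude. More negative b′ = faster habituation.

Group inference uses a linear mixed model `b′ ~ group + time +
(1 | participant)` per region (group between-subject, time repeated,
participant random intercept), one-sided one-sample t-tests of b′ < 0
within group × visit × region, Cohen's d, and Holm-corrected Spearman
screens against clinical/cognitive measures. A group fixed effect β is also
re-expressed as `100 β` percentage points of normalized slope ("patients
habituate X% slower").

Because no participant-level data are public, the package ships a
synthetic-cohort generator with known ground truth: 2-min runs of 1 Hz
stimulus presentations, 10% small-image targets (none in the first 10 s), a
novelty peak 8 s post-onset decaying linearly to baseline by 18 s, AR(1)
volume noise, correlated hemispheres, spike artifacts, motion traces, and
Table-style demographics/clinical scores. Every downstream stage — ART-style
outlier QC (|Δglobal| > 5 SD or motion > 3 mm; runs with ≥2 outlier volumes
inside the window are excluded), nuisance residualization (motion, relative
displacement, outlier spikes, target events; no temporal filter), hemisphere
averaging, window detection, slope estimation, and inference — is exercised
against that ground truth.

## Worked example

```r
library(habslope)

cfg <- sim_config(n_control = 500, n_patient = 500,
                  regions = "anterior_hippocampus",
                  noise_sd = 1, outlier_rate = 0, seed = 314)
sim    <- simulate_cohort(cfg)
avg    <- hemi_average_table(sim$timeseries)
win    <- habituation_window(8, 18, cfg$tr_seconds)
slopes <- compute_slopes(avg, win, cfg$tr_seconds)
fit    <- fit_group_time_model(slopes, region = "anterior_hippocampus")
fit[fit$effect == "group", c("beta", "se", "F", "df_den", "p", "cohen_d",
                             "percent_slower")]
```

```
        beta         se        F df_den            p   cohen_d percent_slower
1 0.08905816 0.01629037 29.88723    998 5.786148e-08 0.3461048       8.905816
```

The simulation draws control slopes around −0.16 at baseline (−0.11 at
follow-up) and patient slopes around −0.06 (0.00), so the fitted group
effect β ≈ 0.09 recovers the configured difference of about 0.10 to within
its standard error: patients habituate about 9 percentage points slower
per second of window time, p < 1e-7 at n = 500 per group.

The six scripts under `analysis/` run the same machinery as a staged
workflow at the study's sample size (68 controls, 70 patients, three
regions, two visits): `01_simulate.R` → `02_qc.R` → `03_extract.R` →
`04_slopes.R` → `05_inference.R` → `06_report.R`, each writing its tables
under `results/run/`. `run_pipeline()` performs the same sequence in one
call.

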