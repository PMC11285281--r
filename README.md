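# lprx

Long-pressure-reactivity index (LPRx) derivation and critical-threshold
scanning for minute-resolution neuromonitoring time series.

## The problem

Cerebrovascular pressure reactivity — how well the cerebral vasculature
buffers systemic blood-pressure swings — is monitored in neuro-critical
care through the pressure reactivity index: a moving Pearson correlation
between intracranial pressure (ICP) and mean arterial pressure (MAP).
Classical PRx needs 10-second data and dedicated IT infrastructure. Most
ICU archives only store sporadic minute-scale medians. The *long* PRx
(LPRx) computes the same correlation from minute-by-minute samples:

LPRx_n(t) = corr( MAP_i , ICP_i ),  i over the last n consecutive samples,

for n in {10, 15, 20, 30, 60, 90, 120} (roughly 10–120 min of time),
evaluated every minute. Values lie in [−1, 1]; values toward +1 mean ICP
passively follows MAP (impaired autoregulation).

This package is for biostatisticians and neuromonitoring researchers who
need the full analysis chain behind LPRx threshold studies:

* **cleaning** — strict validity limits (0 < ICP < 80, 0 < MAP < 400 mmHg),
  removal of open external-ventricular-drain (EVD) periods, gap-limited
  imputation to a regular 1-min grid;
* **index derivation** — `moving_pearson()` / `compute_lprx()` on the
  sporadic samples as-is or on the imputed grid;
* **burden summaries** — per-patient grand means and percent time above
  key thresholds (> 0, > 0.2, > 0.3) over the full stay, first
  24/48/96/144 h and days 1–7;
* **sequential chi-square scan** — for each threshold on a fixed grid
  (−0.5…0.7 by 0.05 for LPRx; 0…40 mmHg by 0.5 for ICP), dichotomize
  patients (value > θ) against dichotomized 1-year Glasgow Outcome Scale
  (survival: GOS 1 vs 2–5; favorable: GOS 1–3 vs 4–5), compute the
  uncorrected Pearson chi-square, and report the maximal-χ² *critical
  threshold* — repeated across windows, time segments, EVD/IPD monitor
  subgroups and percent-time variants (`run_scan_battery()`);
* **a synthetic cohort generator** with known per-patient reactivity ρ and
  outcome statistically linked to it (`generate_cohort()`), so the whole
  pipeline is testable without patient data.

See `vignettes/lprx-methods.Rmd` for the model, parameter rationale and
numerical conventions.

## Worked example

```r
library(lprx)

params <- sim_params(n_patients = 40, stay_range_days = c(1, 3), seed = 1)
cohort <- generate_cohort(params)

# one patient: clean, derive LPRx_10, summarize
rec <- clean_record(cohort$records[[1]])
idx <- compute_lprx(rec, window_minutes = 10)
mean(idx$lprx, na.rm = TRUE)
#> [1] -0.09248076        # this patient's latent rho_true is -0.088

# cohort-level: per-patient grand means vs survival
means <- vapply(cohort$records, function(r)
  mean(compute_lprx(clean_record(r), 10)$lprx, na.rm = TRUE), numeric(1))
dead <- dichotomize_gos(cohort$truth$outcome_gos, "survival")
scan_thresholds(means, dead, threshold_grid("lprx"))
#> <threshold_scan> lprx grid, n=40
#>   best threshold 0.3 (chi2=25.281, p=4.96e-07)
```

The per-patient mean of the windowed correlation tracks the latent
coupling (here cor ≈ 0.98 across the 40 patients), and the scan locates
the critical threshold at 0.3 — the simulated outcome model switches its
death probability at ρ\* = 0.3, so the scan has recovered the break point
from the raw time series. On a cohort this small the located threshold
moves by a grid step or two across seeds; the packaged acceptance tests
quantify recovery over 20 seeds at n = 400.

Full pipeline (cohort files, burden summaries, comparison table, scan
battery, manifest) behind one configuration object:

```r
cfg <- analysis_config(sim = params, windows = c(10, 20),
                       segments = c("full", "first_24h"),
                       out_dir = "lprx_out", seed = 1)
run_pipeline(cfg)
```

or from the command line (exit codes 0/1/2 = ok/config error/runtime
failure):

```sh
Rscript inst/cli/lprx-cli.R all --config config.json --out lprx_out
```

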