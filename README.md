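# tvdtsim

Tumor growth simulation for virtual clinical trials (VCTs) of breast
cancer screening.

Screening trials that follow the same women across several imaging rounds
are slow and expensive; an in-silico alternative needs tumors that *grow*
between the simulated rounds at clinically realistic rates. `tvdtsim`
provides that growth engine and its evaluation harness:

* tumor volume doubling times (TVDT) are sampled from a gamma
  distribution fitted to clinical data (the **clinical fit**; canonical
  parameters from mean 297 days, SD 169 days);
* each virtual patient's tumor is a sphere growing exponentially in
  volume, so its diameter follows

  `d(t) = d_0 * 2^( t / (3 * TVDT) )`

  and, inversely, `TVDT = ln2 * Δt / (3 * ln(d_2/d_1))` from two sizes
  measured Δt apart (the factor 3 because volume scales as diameter
  cubed);
* a cohort generator draws first-round diameters uniformly on 3.5–13 mm
  and grows them across an 18-month (ages 40–54) or 24-month (ages 55–74)
  screening interval;
* a simulated observer records two orthogonal sizes per tumor at 0.1-mm
  precision in repeated sessions, with a configurable Gaussian
  intrareader error, and back-estimates each TVDT;
* an evaluation battery compares clinical, simulated (assigned), and
  estimated TVDT distributions: Shapiro–Wilk normality, Friedman
  session reproducibility, Anderson–Darling family selection with
  parametric bootstrap, two-sample Kolmogorov–Smirnov, Wilcoxon
  signed-rank, median difference/IQR, size regressions, and a fast/slow
  growth-quartile t-test;
* a lightweight lesion-patch renderer (sphere projection on 1/f^β texture
  at 70-µm pixel pitch) gives a 2-D surrogate of the imaging chain for
  automated size measurement experiments.

The audience is medical-imaging and screening-epidemiology researchers
building VCTs of temporal breast imaging.

## Worked example

```r
library(tvdtsim)

# a 4-mm tumor with a 317-day doubling time, 24 months later:
project_diameter(4.0, 317, months_to_days(24))
#> [1] 6.812285      # recorded as 6.8 mm at 0.1-mm precision

fit_from_moments(297, 169)
#> <clinical_fit: gamma>
#>   shape 3.0884, scale 96.16 days
#>   mean 297.0 days, sd 169.0 days

# full virtual experiment: 30 patients, 3 reading sessions
res <- run_pipeline(out_dir = "run1", n = 30, seed = 1)
res$report
#> Doubling-time evaluation report (30 patients, 3 sessions, alpha = 0.05)
#>
#> Reproducibility of size measurements (Friedman):
#>   round1: chi-sq = 3.25, p = 0.196
#>   round2: chi-sq = 0.85, p = 0.653
#>
#> Assigned vs estimated doubling times:
#>   simulated_vs_estimated_session1: KS p = 0.999, Wilcoxon p = 0.0919
#>   simulated_vs_estimated_session2: KS p = 0.999, Wilcoxon p = 0.6263
#>   simulated_vs_estimated_session3: KS p = 0.958, Wilcoxon p = 0.3931
#>
#> Median difference (IQR), days:
#>   session1: 2 (39), n = 30
#>   session2: -1 (27), n = 30
#>   session3: 1 (49), n = 30
#>
#> Size regression (measured ~ true):
#>   round1: slope 1.010, intercept -0.16, R^2 = 0.979
#>   round2: slope 1.000, intercept 0.02, R^2 = 1.000
#>
#> Fast vs slow growth classes (n = 7 each): t = -2.86, p = 0.0143
```

Reading the output: the Friedman p-values say the three simulated reading
sessions are mutually consistent in both rounds; the KS p-values say the
estimated doubling-time distribution is indistinguishable from the
assigned one, while the per-session median differences (a few days against
an IQR of tens of days) quantify the small systematic shift the paired
Wilcoxon test looks for. The size regressions sit on the diagonal — the
second round more tightly, because the same absolute reading error is
relatively smaller on the larger tumors. `run1/` contains `cohort.csv`,
`measurements.csv`, `tvdt_estimates.csv`, `report.json`, and a
`manifest.json` recording configuration and seed; reruns with the same
seed are bit-identical.

A command-line front end with the same pipeline is installed at
`inst/cli/tvdtsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tvdtsim.R", package="tvdtsim"))')" \
    all --n 30 --seed 1 --out run1
```

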