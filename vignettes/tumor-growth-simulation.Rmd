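---
title: "Simulating tumor growth for virtual screening trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tumor growth for virtual screening trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvdtsim)
```

## The growth model

`tvdtsim` treats each breast tumor as a homogeneous sphere whose volume
grows exponentially, parameterized by the tumor volume doubling time
(TVDT). Because volume scales as diameter cubed, the diameter obeys

$$ d(t) = d_0 \cdot 2^{\,t/(3\,\mathrm{TVDT})}, \qquad
   \mathrm{TVDT} = \frac{\ln 2 \,\Delta t}{3 \ln(d_2/d_1)} . $$

Both directions are exact inverses of each other
(`project_diameter()` / `estimate_tvdt()`), which the test suite asserts
to machine precision. Two modeling assumptions matter:

* **Exponential, not Gompertzian.** Over one screening interval (18–24
  months) and mammographically relevant sizes (roughly 5–35 mm),
  exponential growth is an adequate description and keeps the model
  two-parameter; sigmoidal laws describe deceleration at sizes beyond
  this window and are out of scope.
* **Spherical, not spiculated.** The sphere gives exact size/volume
  conversion (`sphere_volume()`), mirrors how readers report bulk size,
  and makes the two "orthogonal" measured extents exchangeable noisy
  reads of one true diameter.

The sign convention is chosen so that growth yields a positive doubling
time. Two degenerate cases can arise from noisy measurements and are
never silently dropped: equal sizes map to an `NA` with status
`"no_growth"` (infinite doubling time), shrinkage to status
`"shrinkage"` (an `NA` by default, or the signed negative value under
`shrinkage = "signed"`). Every downstream analysis reports how many
sentinel pairs it excluded, so `n_used + n_excluded` always reconciles.

## The clinical fit

Doubling times are strictly positive and right-skewed, so the sampling
source is a gamma distribution with the location fixed at zero. The
canonical parameterization is constructed from published moments — mean
297 days, SD 169 days — via `fit_from_moments()`, giving shape
$\mu^2/\sigma^2 \approx 3.09$ and scale $\sigma^2/\mu \approx 96.2$ days.
The raw clinical values behind those moments were published only as a
histogram, so the moment construction *is* the ground truth here; when
raw values are available (`read_tvdt_values()`), `fit_distribution()`
fits by maximum likelihood instead (ML is the default for data; the
moment route exists for the canonical fit).

Family selection (`select_family()`) computes the Anderson–Darling
statistic against each candidate family with its parameters estimated
from the data. Tabulated AD critical values assume known parameters, so
p-values come from a parametric bootstrap (default 1000 replicates,
parameters re-estimated per replicate). Gamma and normal are the
implemented candidates — the skewed alternative and its natural
symmetric rival.

## What the cohort generator emulates

`generate_cohort()` reproduces the study conditions of the screening
experiment it models:

| parameter | default | why |
|---|---|---|
| cohort size `n` | 30 | the reference experiment's cohort |
| TVDT source | gamma(297, 169 d) clinical fit | printed moments |
| first-round diameter | uniform 3.5–13 mm | just below the clinically detectable range, so second-round sizes land in it |
| age | uniform integers 40–74 years | only the age→interval mapping is constrained; a registry age table can be plugged in via `age_sampler` |
| screening interval | 18 mo if age ≤ 54, else 24 mo | the screening program being emulated |
| month length | 365.25/12 days (`"calendar"`); `"rounded"` gives 548/730 d | both conventions reproduce the worked example |
| breast volume / density | uniform 450–950 mL / 5–60% | metadata ranges of the phantom population; they do not affect growth |
| lesion location | uniform in a normalized unit cube | metadata only; location influenced only the (out-of-scope) image rendering |

Tumors whose second-round diameter exceeds 20 mm are flagged
`palpable_flag` but retained: interval cancers are deliberately not
simulated, so fast-growing tumors stay in the cohort. A consequence of
sampling an *unbounded* gamma is that roughly 2% of doubling times fall
below 60 days, and such tumors reach sizes far beyond anything a
screening program would observe (the woman would have presented
clinically long before). The plausibility tests therefore constrain the
bulk of the size distribution (median in the detectable range, ≥90%
below the 54-mm maximum a realized 30-patient cohort produced), never
the extremes.

## The simulated observer

The reader protocol being emulated records, per tumor and session, the
largest extent and the approximately orthogonal extent at 0.1-mm
precision, averages them, and feeds the mean into the doubling-time
formula. `simulate_measurement()` models each recorded size as

`round_0.1( max(true_d + bias + N(0, sd), 0.1) )`

with the two directions independent — under sphere symmetry both
directions see the same true diameter, so orthogonality needs no
geometric model. The default `sd` of **0.5 mm per direction with zero
bias is a tunable, not a measured fact**: no published summary
characterizes the intrareader error magnitude, only its downstream
consequences. 0.5 mm was chosen once as a value giving size-regression
scatter commensurate with reported reader behavior, and all conclusions
that depend on it are labelled as such. Each session×round combination
draws from its own deterministic substream of the master seed, so
repeated sessions are independent by construction and the Friedman
no-difference null holds exactly when sessions share one noise law.

What passing these tests does *not* show: anything about a human
reader's search, boundary-delineation, or anatomical-masking behavior.
The synthetic observer is unbiased Gaussian by construction; real
intrareader error need not be either. Real-reader measurement tables can
be ingested through `read_measurements()` and flow through the identical
estimation and evaluation path.

## The lesion-patch surrogate

`render_patch()`/`auto_measure()` form a deliberately minimal 2-D
surrogate of the imaging chain: the parallel projection of a sphere is
its chord length, $2\sqrt{r^2-\rho^2}$, normalized to peak contrast and
sampled at the 0.07-mm mammographic pixel pitch over an isotropic
$1/f^\beta$ Gaussian texture ($\beta = 3$ by default, a standard
mammographic-texture surrogate). The automatic measurement thresholds
the background-subtracted profile at 10% of peak, which spans
$0.995\,d$ — within one pixel of the true diameter. X-ray physics,
anatomy simulation, detector blur, and vendor processing are explicitly
out of scope; comparisons against reader-derived numbers go through the
observer module, never through this surrogate.

## Numerical and statistical choices

* **Quantiles/IQR**: linear-interpolation rule (R type 7) throughout;
  no convention was stated for the reference analysis, so one was fixed
  and documented.
* **KS test**: exact small-sample computation where R provides it
  (sample products below 10^4), the regime the n = 30 cohorts occupy.
* **Wilcoxon signed-rank**: zero differences dropped per the signed-rank
  convention, count reported; two identical samples short-circuit to a
  "no difference" result instead of a degenerate test object.
* **Friedman on fully tied data** returns statistic 0, p = 1 (the
  no-discrimination boundary) rather than NaN.
* **Growth classes**: fast = lowest, slow = highest quartile of
  *assigned* doubling time; each class holds `floor(n/4)` members, ranks
  tie-broken by input order for determinism; the class comparison uses
  the pooled-variance two-sample t-test on absolute relative errors.
* **Multiple testing**: none — tests are reported individually at
  α = 0.05, matching the analysis being mirrored.
* **Seeding**: one master seed deterministically derives all substreams
  (`derive_seed`), and sampling helpers restore the caller's RNG state,
  so whole-pipeline reruns are bit-identical.

## Problem sizes in the test suite

The suite exercises the same estimators at sizes chosen to keep a full
run at desk scale while leaving Monte-Carlo error far below the asserted
tolerances: 10^6 draws for moment/parameter recovery (2% tolerance),
1000 replicate cohorts of n = 30 for the sampling-distribution checks,
1000 replicates per test for type-I calibration (binomial SE 0.7%, with
the acceptance band widened to [0.02, 0.08] because exact small-sample
KS and signed-rank tests have discrete attainable sizes below the
nominal 5%), and 200 replicates for the shift-sensitivity contrast
between the paired Wilcoxon and two-sample KS tests.

## Known limitations

* The observer noise law (Gaussian, unbiased, size-independent) is the
  weakest link to reality; real reader error likely grows with size and
  anatomical masking.
* Only two screening rounds are generated, with fixed 18/24-month
  intervals; jittered screening dates and additional rounds would be
  straightforward extensions of the same growth law.
* No interval cancers: the fast tail of the doubling-time distribution
  is retained and flagged, which slightly fattens the large-size tail
  relative to a screened population.
* The lesion-patch module measures sizes reliably only against the
  synthetic texture it renders; it is not an image-analysis tool for
  real mammograms.
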