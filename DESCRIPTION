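Package: tvdtsim
Title: Tumor Growth Simulation for Virtual Clinical Trials of Breast
    Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates exponentially growing, spherical breast tumors
    across successive screening rounds for virtual clinical trials.
    Tumor volume doubling times are sampled from a gamma distribution
    fitted to clinical data, true tumor sizes are projected with the
    volume-doubling growth law, a simulated observer records noisy
    two-orthogonal-diameter size measurements at 0.1-mm precision over
    repeated sessions, and a statistical battery (Shapiro-Wilk, Friedman,
    Anderson-Darling with parametric bootstrap, two-sample
    Kolmogorov-Smirnov, Wilcoxon signed-rank, median difference and IQR,
    size regressions, and a fast/slow growth-class t-test) compares the
    clinical, simulated, and estimated doubling-time distributions.  A
    lightweight lesion-patch renderer provides a 2-D surrogate of the
    mammographic imaging chain for automated size measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
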