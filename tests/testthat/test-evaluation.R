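test_that("normality testing flags skew and rejects degenerate input", {
  skewed <- sample_tvdt(fit_from_moments(297, 169), 500, seed = 1)
  expect_lt(test_normality(skewed)$p_value, 0.05)  # gamma shape ~3 is skewed
  gauss <- withr::with_seed(2, rnorm(500, 300, 50))
  expect_gt(test_normality(gauss)$p_value, 0.001)
  expect_error(test_normality(c(1, 2)), "at least 3")
  expect_error(test_normality(rep(4, 10)), "degenerate")
})

test_that("reproducibility testing behaves at its boundaries", {
  base <- withr::with_seed(3, runif(20, 4, 13))
  same <- list(base, base, base)
  res <- test_reproducibility(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)  # identical sessions: no discrimination

  shifted <- list(base, base + 5, base)  # one session off by a constant
  expect_lt(test_reproducibility(shifted)$p_value, 0.05)

  expect_error(test_reproducibility(list(1:5, 1:4, 1:5)), "equal lengths")
})

test_that("pairwise comparison reports both tests and exclusion accounting", {
  x <- withr::with_seed(4, rgamma(30, 3, scale = 100))
  same <- compare_pair(x, x, paired = TRUE)
  expect_equal(same$ks$statistic, 0)
  expect_equal(same$wilcoxon$p_value, 1)
  expect_equal(same$wilcoxon$note, "no difference")

  y <- c(x[-1] + 20, NA)  # one sentinel pair
  res <- compare_pair(x, y, paired = TRUE)
  expect_equal(res$n_used + res$n_excluded, 30)
  expect_equal(res$n_excluded, 1)
  expect_true(res$ks$p_value >= 0 && res$ks$p_value <= 1)
  expect_true(res$wilcoxon$p_value >= 0 && res$wilcoxon$p_value <= 1)

  expect_error(compare_pair(1:3, 1:3), "at least 5")
  expect_error(compare_pair(c(rep(NA, 6), 1:4), 1:10, paired = TRUE),
               "at least 5")
})

test_that("median difference uses the linear-interpolation quantile rule", {
  x <- c(10, 20, 30, 40, 50)
  expect_equal(median_difference(x, x),
               list(median_days = 0, iqr_days = 0, n_used = 5,
                    n_excluded = 0))
  # assigned - estimated differences {-5, 0, 5, 10, 30}
  assigned <- c(0, 0, 0, 0, 0)
  estimated <- -c(-5, 0, 5, 10, 30)
  res <- median_difference(assigned, estimated)
  expect_equal(res$median_days, 5)
  expect_equal(res$iqr_days, 10)  # type-7 quartiles of the differences

  res2 <- median_difference(c(x, 1), c(x + 2, NA))
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$median_days, -2)
})

test_that("size regression recovers the identity and degrades with noise", {
  true_d <- seq(4, 13, length.out = 30)
  perfect <- regress_sizes(true_d, true_d)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$r_squared, 1)

  noisy <- regress_sizes(true_d, true_d + withr::with_seed(5, rnorm(30, 0, 0.5)))
  expect_equal(noisy$slope, 1, tolerance = 0.1)
  expect_lt(noisy$r_squared, 1)

  expect_error(regress_sizes(rep(5, 10), 1:10), "zero variance")
})

test_that("equal absolute noise gives a tighter fit in the second round", {
  # larger second-round tumors make the same absolute scatter relatively
  # smaller, so R^2 rises between rounds
  cohort <- make_cohort(n = 200, seed = 17)
  noise <- function(s) withr::with_seed(s, rnorm(200, 0, 0.5))
  r1 <- regress_sizes(cohort$d1_mm, cohort$d1_mm + noise(18))$r_squared
  r2 <- regress_sizes(cohort$d2_mm, cohort$d2_mm + noise(19))$r_squared
  expect_gt(r2, r1)
})

test_that("growth classes are the outer quartiles with floor(n/4) members", {
  assigned <- c(100, 200, 300, 400, 500, 600, 700, 800)
  res <- growth_class_analysis(assigned, assigned)
  expect_equal(res$n_per_class, 2)
  expect_identical(sort(res$fast$indices), 1:2)  # shortest doubling times
  expect_identical(sort(res$slow$indices), 7:8)
  expect_true(is.na(res$p_value))  # identical estimates: degenerate
  expect_match(res$note, "no difference")
  expect_length(intersect(res$fast$indices, res$slow$indices), 0)

  est <- assigned * withr::with_seed(6, exp(rnorm(8, 0, 0.2)))
  res2 <- growth_class_analysis(assigned, est)
  expect_true(res2$p_value >= 0 && res2$p_value <= 1)

  expect_error(growth_class_analysis(1:7, 1:7), "at least 8")
})

test_that("the full report is deterministic and internally consistent", {
  cohort <- make_cohort(n = 16, seed = 20)
  rec <- measure_cohort(cohort, observer_noise(sd = 0.5), seed = 21)
  fit <- fit_from_moments(297, 169)
  clin <- sample_tvdt(fit, 31, seed = 22)
  rep1 <- build_report(cohort, rec, fit, clinical = clin)
  rep2 <- build_report(cohort, rec, fit, clinical = clin)
  expect_equal(rep1, rep2)

  # every p-value in [0, 1]
  ps <- c(
    vapply(rep1$reproducibility, `[[`, numeric(1), "p_value"),
    vapply(rep1$pairwise, function(p) p$ks$p_value, numeric(1)),
    rep1$normality$simulated$p_value
  )
  expect_true(all(ps >= 0 & ps <= 1))

  # exclusion accounting per paired analysis
  for (nm in grep("simulated_vs_estimated", names(rep1$pairwise),
                  value = TRUE)) {
    pw <- rep1$pairwise[[nm]]
    expect_equal(pw$n_used + pw$n_excluded, 16)
  }

  # report JSON is valid and regenerates identically
  tmp1 <- withr::local_tempfile(fileext = ".json")
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, tmp1)
  write_report(rep2, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  parsed <- jsonlite::read_json(tmp1)
  expect_equal(parsed$alpha, 0.05)
  expect_equal(parsed$n_patients, 16)

  # inconsistent patient sets are a reconciliation error
  expect_error(build_report(cohort[-1, ], rec, fit), "patient")
})

test_that("plots build without error", {
  fit <- fit_from_moments(297, 169)
  v <- sample_tvdt(fit, 100, seed = 30)
  p1 <- plot_tvdt_hist(v, fit)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_fit_overlay(list(clinical = fit,
                              simulated = fit_from_moments(322, 217)))
  expect_s3_class(p2, "ggplot")
})
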