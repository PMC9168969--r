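test_that("noiseless measurements reduce to 0.1-mm rounding", {
  m <- simulate_measurement(6.81, observer_noise(sd = 0, bias = 0))
  expect_equal(m$size_a_mm, 6.8)
  expect_equal(m$size_b_mm, 6.8)
  # recorded sizes always sit on the 0.1-mm grid and stay positive
  m2 <- simulate_measurement(rep(0.05, 50), observer_noise(sd = 1), seed = 4)
  expect_true(all(m2$size_a_mm >= 0.1))
  expect_equal(m2$size_a_mm, round_size(m2$size_a_mm))
})

test_that("measurement noise is reproducible and unbiased", {
  a <- simulate_measurement(5, observer_noise(sd = 0.5), seed = 9)
  b <- simulate_measurement(5, observer_noise(sd = 0.5), seed = 9)
  expect_identical(a, b)

  big <- simulate_measurement(rep(7, 2e4), observer_noise(sd = 0.5), seed = 10)
  ms <- mean_diameter(big$size_a_mm, big$size_b_mm)
  expect_equal(mean(ms) - 7, 0, tolerance = 0.01)  # bias 0 within MC error

  biased <- simulate_measurement(rep(7, 2e4),
                                 observer_noise(sd = 0.5, bias = 0.3),
                                 seed = 10)
  expect_lt(abs(mean(mean_diameter(biased$size_a_mm, biased$size_b_mm)) -
                  7 - 0.3), 0.02)
})

test_that("a measured cohort has sessions x rounds x patients records", {
  cohort <- make_cohort(n = 30, seed = 5)
  rec <- measure_cohort(cohort, observer_noise(sd = 0.5), n_sessions = 3,
                        seed = 6)
  expect_equal(nrow(rec), 180)
  expect_equal(rec$mean_size_mm,
               mean_diameter(rec$size_a_mm, rec$size_b_mm))

  # zero noise: sessions identical; with noise: distinct substreams
  quiet <- noiseless_records(cohort)
  s1 <- quiet[quiet$session == 1, "mean_size_mm"]
  s2 <- quiet[quiet$session == 2, "mean_size_mm"]
  expect_identical(s1, s2)
  n1 <- rec[rec$session == 1, ]$mean_size_mm
  n2 <- rec[rec$session == 2, ]$mean_size_mm
  expect_false(identical(n1, n2))
})

test_that("doubling-time estimates propagate sentinels and match oracles", {
  cohort <- make_cohort(n = 15, seed = 8)
  quiet <- noiseless_records(cohort, n_sessions = 1)
  est <- estimate_cohort_tvdt(quiet, cohort)
  # noiseless: estimation error comes from rounding alone
  expect_true(all(est$status == "ok"))
  expect_equal(est$tvdt_est_days[match(cohort$id, est$patient_id)],
               cohort$tvdt_days, tolerance = 0.15)

  # closed-form check through the record path
  one <- tibble::tibble(patient_id = "P001", session = 1L, round = 1:2,
                        size_a_mm = c(4.1, 7.3), size_b_mm = c(4.1, 7.3))
  tiny <- tibble::tibble(id = "P001", interval_months = 24L)
  est1 <- estimate_cohort_tvdt(one, tiny, month_convention = "rounded")
  expect_equal(round(est1$tvdt_est_days, 1), 292.4)

  # equal sizes in both rounds -> undefined growth
  flat <- tibble::tibble(patient_id = "P001", session = 1L, round = 1:2,
                         size_a_mm = c(5, 5), size_b_mm = c(5, 5))
  estf <- estimate_cohort_tvdt(flat, tiny)
  expect_identical(estf$status, "no_growth")
  expect_true(is.na(estf$tvdt_est_days))
})

test_that("a missing round is a structured error naming patient/session", {
  cohort <- make_cohort(n = 4, seed = 1)
  rec <- noiseless_records(cohort, n_sessions = 2)
  rec <- rec[!(rec$patient_id == "P002" & rec$session == 2 &
                 rec$round == 2), ]
  expect_error(estimate_cohort_tvdt(rec, cohort), "P002/2")
})

test_that("measurement CSV round trip validates sizes and granularity", {
  cohort <- make_cohort(n = 6, seed = 3)
  rec <- measure_cohort(cohort, observer_noise(sd = 0.5), seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rec, tmp)
  back <- read_measurements(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  bad <- rec
  bad$size_b_mm[3] <- -1
  write_measurements(bad, tmp)
  expect_error(read_measurements(tmp), "non-positive size")

  coarse <- rec
  coarse$size_a_mm <- round(coarse$size_a_mm / 0.5) * 0.5 + 0.25
  write_measurements(coarse, tmp)
  expect_warning(read_measurements(tmp), "0.1-mm grid")
})

test_that("rounding-induced doubling-time error shrinks as tumors grow", {
  # sweep the first-round diameter: with noiseless 0.1-mm-rounded sizes the
  # relative estimation error decreases with tumor size
  d1 <- seq(3.5, 13, by = 0.5)
  tvdt <- 297
  dt <- months_to_days(24)
  d2 <- project_diameter(d1, tvdt, dt)
  est <- as.numeric(estimate_tvdt(round_size(d1), round_size(d2), dt))
  rel_err <- abs(est - tvdt) / tvdt
  # compare mean error in the small-tumor third vs the large-tumor third
  k <- length(d1) %/% 3
  expect_gt(mean(rel_err[1:k]) + 1e-12,
            mean(rel_err[(length(d1) - k + 1):length(d1)]))
  expect_lt(max(rel_err), 0.1)
})

test_that("with unbiased noise the estimate error is sign-balanced", {
  cohort <- make_cohort(n = 200, seed = 31)
  rec <- measure_cohort(cohort, observer_noise(sd = 0.5), n_sessions = 1,
                        seed = 32)
  est <- estimate_cohort_tvdt(rec, cohort)
  est <- est[est$status == "ok", ]
  d <- est$tvdt_est_days -
    cohort$tvdt_days[match(est$patient_id, cohort$id)]
  expect_lt(abs(stats::median(d)) / stats::IQR(d), 0.25)
})
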