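# Simulated observer: repeated two-orthogonal-diameter size measurements at
# 0.1-mm recording precision, and the doubling-time estimates they imply.
#
# The reader study this emulates used one radiologist measuring each tumor's
# largest extent and the approximately orthogonal extent in three repeated
# sessions.  Since the simulated tumors are spheres, both directions share
# the true diameter; the two recorded sizes are modelled as i.i.d. noisy
# reads of it.

#' Observer measurement-noise model
#'
#' Additive Gaussian error per single-direction measurement, with optional
#' systematic bias.  The magnitude of real intrareader error is not known
#' from published summaries; the default `sd` of 0.5 mm is a tunable chosen
#' to give size scatter commensurate with reported reader regressions, not
#' a measured fact.
#'
#' @param sd Standard deviation in mm per measured direction (>= 0).
#' @param bias Systematic offset in mm added to every measurement.
#' @return A list of class `observer_noise`.
#' @export
observer_noise <- function(sd = 0.5, bias = 0) {
  check_scalar_number(sd, "sd", 0)
  check_scalar_number(bias, "bias")
  structure(list(sd = sd, bias = bias), class = "observer_noise")
}

#' Simulate one two-orthogonal-size measurement
#'
#' Each size is an independent draw of `true_d + bias + N(0, sd)`, floored
#' at 0.1 mm and rounded to the 0.1-mm recording precision.
#'
#' @param true_d True diameter in mm (> 0). Vectorized.
#' @param noise An [observer_noise()].
#' @param seed Optional seed for reproducibility.
#' @return A tibble with columns `size_a_mm`, `size_b_mm`.
#' @export
simulate_measurement <- function(true_d, noise = observer_noise(),
                                 seed = NULL) {
  stopifnot(inherits(noise, "observer_noise"))
  if (any(!is.finite(true_d)) || any(true_d <= 0)) {
    stop("`true_d` must be positive and finite", call. = FALSE)
  }
  n <- length(true_d)
  with_seed_if(seed, {
    one <- function() {
      raw <- true_d + noise$bias + stats::rnorm(n, 0, noise$sd)
      pmax(round_size(pmax(raw, 0.1)), 0.1)
    }
    tibble::tibble(size_a_mm = one(), size_b_mm = one())
  })
}

#' Measure a cohort in repeated sessions
#'
#' Produces `n_sessions x 2 rounds x n patients` measurement records.  Each
#' session/round combination uses its own deterministic substream of the
#' master seed, so sessions are independent by construction and the
#' no-difference (Friedman) null holds when they share one noise law.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param noise An [observer_noise()].
#' @param n_sessions Number of repeated reading sessions (default 3).
#' @param seed Optional master seed.
#' @return A tibble of measurement records: `patient_id`, `session`,
#'   `round`, `size_a_mm`, `size_b_mm`, `mean_size_mm`.
#' @export
measure_cohort <- function(cohort, noise = observer_noise(), n_sessions = 3,
                           seed = NULL) {
  stopifnot(all(c("id", "d1_mm", "d2_mm") %in% names(cohort)))
  check_scalar_number(n_sessions, "n_sessions", 1)
  grid <- expand.grid(session = seq_len(n_sessions), round = 1:2)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$session[i]
    r <- grid$round[i]
    sub_seed <- if (is.null(seed)) NULL else {
      derive_seed(seed, paste0("session", s, "round", r))
    }
    true_d <- if (r == 1) cohort$d1_mm else cohort$d2_mm
    m <- simulate_measurement(true_d, noise, seed = sub_seed)
    tibble::tibble(
      patient_id = cohort$id, session = as.integer(s), round = as.integer(r),
      size_a_mm = m$size_a_mm, size_b_mm = m$size_b_mm
    )
  })
  out <- dplyr::bind_rows(recs)
  out$mean_size_mm <- mean_diameter(out$size_a_mm, out$size_b_mm)
  dplyr::arrange(out, .data$patient_id, .data$session, .data$round)
}

#' Estimate per-patient, per-session doubling times from measurements
#'
#' For each patient and session, the mean of the two measured orthogonal
#' sizes at each round is fed to [estimate_tvdt()] with the patient's
#' screening interval.  Non-growth sentinels (possible under measurement
#' noise) are propagated as `NA` with an explicit `status`.
#'
#' @param records Measurement records from [measure_cohort()] or
#'   [read_measurements()].
#' @param cohort The cohort the records refer to (provides the interval).
#' @param month_convention Passed to [months_to_days()].
#' @param shrinkage Passed to [estimate_tvdt()].
#' @return A tibble: `patient_id`, `session`, `tvdt_est_days`, `status`.
#' @export
estimate_cohort_tvdt <- function(records, cohort,
                                 month_convention = "calendar",
                                 shrinkage = "sentinel") {
  stopifnot(all(c("patient_id", "session", "round") %in% names(records)))
  if (!"mean_size_mm" %in% names(records)) {
    records$mean_size_mm <- mean_diameter(records$size_a_mm, records$size_b_mm)
  }
  wide <- tidyr::pivot_wider(
    records[c("patient_id", "session", "round", "mean_size_mm")],
    names_from = "round", values_from = "mean_size_mm", names_prefix = "d"
  )
  if (!all(c("d1", "d2") %in% names(wide)) ||
      anyNA(wide$d1) || anyNA(wide$d2)) {
    miss <- wide[if (!all(c("d1", "d2") %in% names(wide))) TRUE else
      is.na(wide$d1) | is.na(wide$d2), c("patient_id", "session")]
    stop("missing round for patient/session: ",
         paste(utils::head(paste(miss$patient_id, miss$session, sep = "/"), 5),
               collapse = ", "), call. = FALSE)
  }
  idx <- match(wide$patient_id, cohort$id)
  if (anyNA(idx)) {
    stop("records refer to patients absent from the cohort", call. = FALSE)
  }
  dt <- months_to_days(cohort$interval_months[idx], month_convention)
  est <- estimate_tvdt(wide$d1, wide$d2, dt, shrinkage = shrinkage)
  tibble::tibble(
    patient_id = wide$patient_id,
    session = wide$session,
    tvdt_est_days = as.numeric(est),
    status = attr(est, "status")
  )
}

measurement_columns <- c("patient_id", "session", "round",
                         "size_a_mm", "size_b_mm")

#' Write / read measurement records as CSV
#'
#' Validates sizes on read: non-positive sizes are a row-level error;
#' granularity coarser than the 0.1-mm recording precision is accepted with
#' a warning.
#'
#' @param records Measurement records tibble.
#' @param path File path.
#' @return `read_measurements` returns the records tibble (with
#'   `mean_size_mm` recomputed); `write_measurements` returns the path
#'   invisibly.
#' @export
write_measurements <- function(records, path) {
  stopifnot(all(measurement_columns %in% names(records)))
  readr::write_csv(records[measurement_columns], path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          session = readr::col_integer(),
                          round = readr::col_integer(),
                          .default = readr::col_double()
                        ))
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing) > 0) {
    stop("measurement file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$size_a_mm) | df$size_a_mm <= 0 |
                 !is.finite(df$size_b_mm) | df$size_b_mm <= 0)
  if (length(bad) > 0) {
    stop("non-positive size in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  off_grid <- abs(df$size_a_mm - round_size(df$size_a_mm)) > 1e-9 |
    abs(df$size_b_mm - round_size(df$size_b_mm)) > 1e-9
  if (any(off_grid)) {
    warning(sum(off_grid),
            " record(s) not on the 0.1-mm grid; accepted as-is")
  }
  df$mean_size_mm <- mean_diameter(df$size_a_mm, df$size_b_mm)
  df[c(measurement_columns, "mean_size_mm")]
}
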