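# Virtual patient cohort: ages, screening intervals, assigned doubling
# times, and true tumor diameters at two screening rounds.

#' Configuration for cohort generation
#'
#' Defaults reproduce the study conditions of the screening simulation:
#' 30 patients, first-round diameters uniform on 3.5-13 mm (just below the
#' clinically detectable range, so second-round sizes land in it), ages
#' 40-74 with an 18-month interval up to age 54 and 24 months above,
#' doubling times drawn from the canonical clinical fit (gamma, mean 297 d,
#' SD 169 d), breast volume 450-950 mL and 5-60% dense compartments kept as
#' metadata.
#'
#' @param n Cohort size (>= 1).
#' @param seed Optional master seed for reproducible generation.
#' @param fit `clinical_fit` to sample doubling times from.
#' @param diameter_range First-round diameter range in mm, `c(low, high)`.
#' @param age_range Screening age range in years.
#' @param age_sampler Function `(n) -> ages`; the default draws integer ages
#'   uniformly over `age_range`.  Supply an empirical sampler to use a
#'   registry age-at-detection table.
#' @param interval_threshold Age (years) up to which the 18-month interval
#'   applies; older patients get 24 months.
#' @param month_convention Passed to [months_to_days()].
#' @param breast_volume_range Breast volume range in mL (metadata).
#' @param density_range Percent dense compartments range (metadata).
#' @param palpable_mm Second-round diameter above which a tumor is flagged
#'   as palpable (flagged, never removed: interval cancers are not
#'   simulated).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 30, seed = NULL,
                          fit = fit_from_moments(297, 169),
                          diameter_range = c(3.5, 13),
                          age_range = c(40, 74),
                          age_sampler = NULL,
                          interval_threshold = 54,
                          month_convention = "calendar",
                          breast_volume_range = c(450, 950),
                          density_range = c(5, 60),
                          palpable_mm = 20) {
  check_scalar_number(n, "n", 1)
  stopifnot(inherits(fit, "clinical_fit"),
            length(diameter_range) == 2, diameter_range[1] > 0,
            diameter_range[1] < diameter_range[2],
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(
    list(n = as.integer(n), seed = seed, fit = fit,
         diameter_range = diameter_range, age_range = age_range,
         age_sampler = age_sampler, interval_threshold = interval_threshold,
         month_convention = month_convention,
         breast_volume_range = breast_volume_range,
         density_range = density_range, palpable_mm = palpable_mm),
    class = "cohort_config"
  )
}

#' Assign the screening interval from patient age
#'
#' The screening program images women aged 40-54 every 18 months and women
#' aged 55-74 every 24 months.
#'
#' @param age Age in years (within 40-74 by default). Vectorized.
#' @param threshold Age up to (and including) which 18 months applies.
#' @param age_range Admissible age range.
#' @return Interval in months (18 or 24).
#' @examples
#' assign_interval(c(47, 55))  # 18, 24
#' @export
assign_interval <- function(age, threshold = 54, age_range = c(40, 74)) {
  if (any(!is.finite(age)) || any(age < age_range[1]) ||
      any(age > age_range[2])) {
    stop(sprintf("age must lie in [%g, %g]", age_range[1], age_range[2]),
         call. = FALSE)
  }
  ifelse(age <= threshold, 18L, 24L)
}

#' Generate a virtual patient cohort
#'
#' Draws one doubling time per patient from the clinical fit, a first-round
#' diameter uniform over the configured range, an age (which fixes the
#' screening interval), and grows the tumor to the second round with
#' [project_diameter()].  Breast volume, density, and a normalized lesion
#' location are recorded as metadata; they do not affect growth.  Tumors
#' exceeding the palpable size at the second round are flagged
#' (`palpable_flag`), not removed.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `id`, `age_years`,
#'   `interval_months`, `tvdt_days`, `d1_mm`, `d2_mm`, `breast_volume_ml`,
#'   `density_pct`, `loc_x`, `loc_y`, `loc_z`, `palpable_flag`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  with_seed_if(config$seed, {
    ages <- if (is.null(config$age_sampler)) {
      sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
    } else {
      config$age_sampler(n)
    }
    interval <- assign_interval(ages, config$interval_threshold,
                                config$age_range)
    tvdt <- sample_tvdt(config$fit, n)
    d1 <- stats::runif(n, config$diameter_range[1], config$diameter_range[2])
    d2 <- project_diameter(d1, tvdt,
                           months_to_days(interval, config$month_convention))
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      age_years = as.integer(ages),
      interval_months = as.integer(interval),
      tvdt_days = tvdt,
      d1_mm = d1,
      d2_mm = d2,
      breast_volume_ml = stats::runif(n, config$breast_volume_range[1],
                                      config$breast_volume_range[2]),
      density_pct = stats::runif(n, config$density_range[1],
                                 config$density_range[2]),
      loc_x = stats::runif(n), loc_y = stats::runif(n), loc_z = stats::runif(n),
      palpable_flag = d2 > config$palpable_mm
    )
  })
}

cohort_columns <- c("id", "age_years", "interval_months", "tvdt_days",
                    "d1_mm", "d2_mm", "breast_volume_ml", "density_pct",
                    "loc_x", "loc_y", "loc_z", "palpable_flag")

#' Write / read a cohort as CSV
#'
#' The CSV round trip is lossless for all patient fields (full floating
#' point precision is written).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort` returns the cohort tibble; `write_cohort` returns
#'   the path invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  readr::write_csv(cohort[cohort_columns], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          id = readr::col_character(),
                          age_years = readr::col_integer(),
                          interval_months = readr::col_integer(),
                          palpable_flag = readr::col_logical(),
                          .default = readr::col_double()
                        ))
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing) > 0) {
    stop("cohort file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$d1_mm) & !is.na(df$d2_mm) &
                 (df$d1_mm <= 0 | df$d2_mm <= 0))
  if (length(bad) > 0) {
    stop("non-positive diameter in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df[cohort_columns]
}
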