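# Exponential, sphere-approximated tumor growth and its inversion.
#
# Under exponential volume growth with doubling time TVDT, the volume after
# an interval dt is V0 * 2^(dt/TVDT).  With a spherical tumor, V ~ d^3, so the
# diameter grows as d0 * 2^(dt/(3*TVDT)) and, conversely,
# TVDT = ln2 * dt / (3 * ln(d_late/d_early)).

#' Project a tumor diameter forward in time
#'
#' Applies the exponential, sphere-approximated growth law: a tumor of
#' diameter `d_start` with volume doubling time `tvdt` reaches
#' `d_start * 2^(dt / (3 * tvdt))` after `dt` days.  The factor 3 converts
#' volume doublings to diameter doublings (volume scales as diameter cubed).
#'
#' @param d_start Starting diameter in mm (> 0). Vectorized.
#' @param tvdt Tumor volume doubling time in days (> 0).
#' @param dt Elapsed time in days (>= 0).
#' @return Projected diameter in mm (not rounded).
#' @examples
#' project_diameter(4.0, 317, months_to_days(24))  # ~6.8 mm
#' @seealso [estimate_tvdt()] for the inverse operation.
#' @export
project_diameter <- function(d_start, tvdt, dt) {
  if (any(!is.finite(d_start)) || any(d_start <= 0)) {
    stop("`d_start` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(tvdt)) || any(tvdt <= 0)) {
    stop("`tvdt` must be positive and finite", call. = FALSE)
  }
  if (any(dt < 0)) stop("`dt` must be non-negative", call. = FALSE)
  d_start * 2^(dt / (3 * tvdt))
}

#' Estimate the tumor volume doubling time from two diameters
#'
#' Inverts the exponential growth law:
#' `TVDT = ln2 * dt / (3 * ln(d_late / d_early))`, positive for a growing
#' tumor.  Non-growth cases, which arise under measurement noise, are mapped
#' to explicit sentinels rather than silently dropped: equal diameters give
#' `NA` with status `"no_growth"` (the doubling time is undefined/infinite);
#' shrinkage gives `NA` with status `"shrinkage"` under the default policy,
#' or the signed (negative) value when `shrinkage = "signed"`.
#'
#' @param d_early Diameter at the first time point, mm (> 0). Vectorized.
#' @param d_late Diameter at the second time point, mm (> 0).
#' @param dt Interval between the two time points in days (> 0).
#' @param shrinkage Policy for `d_late < d_early`: `"sentinel"` (default,
#'   `NA`) or `"signed"` (negative doubling time).
#' @return Numeric vector of doubling times in days, with a `"status"`
#'   attribute (`"ok"`, `"no_growth"` or `"shrinkage"` per element).
#' @examples
#' estimate_tvdt(4.0, 8.0, 900)  # 300 days: one diameter doubling
#' @export
estimate_tvdt <- function(d_early, d_late, dt,
                          shrinkage = c("sentinel", "signed")) {
  shrinkage <- match.arg(shrinkage)
  if (any(!is.finite(d_early)) || any(d_early <= 0) ||
      any(!is.finite(d_late)) || any(d_late <= 0)) {
    stop("diameters must be positive and finite", call. = FALSE)
  }
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  tvdt <- log(2) * dt / (3 * log(d_late / d_early))
  status <- rep("ok", length(tvdt))
  no_growth <- d_late == d_early
  shrink <- d_late < d_early
  tvdt[no_growth] <- NA_real_
  status[no_growth] <- "no_growth"
  status[shrink] <- "shrinkage"
  if (shrinkage == "sentinel") tvdt[shrink] <- NA_real_
  structure(tvdt, status = status)
}

#' Sphere volume from diameter
#'
#' Volume of the spherical tumor approximation, `(pi/6) * d^3`.
#'
#' @param d Diameter in mm (>= 0). Vectorized.
#' @return Volume in mm^3.
#' @export
sphere_volume <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("`d` must be non-negative and finite", call. = FALSE)
  }
  pi / 6 * d^3
}

#' Mean of two orthogonal size measurements
#'
#' The reader protocol records the largest tumor extent and the extent in the
#' approximately orthogonal direction; their arithmetic mean is the diameter
#' used in the spherical approximation.
#'
#' @param a,b The two measured sizes in mm (> 0). Vectorized.
#' @return `(a + b) / 2` in mm.
#' @export
mean_diameter <- function(a, b) {
  if (any(!is.finite(a)) || any(a <= 0) || any(!is.finite(b)) || any(b <= 0)) {
    stop("sizes must be positive and finite", call. = FALSE)
  }
  (a + b) / 2
}

#' Convert a screening interval in months to days
#'
#' The default `"calendar"` convention uses the mean Gregorian month of
#' 365.25/12 days (18 months = 547.875 d, 24 months = 730.5 d).  The
#' `"rounded"` convention rounds the calendar value to whole days
#' (548 and 730 d), matching the common habit of quoting whole-day intervals.
#'
#' @param months Interval in months. Vectorized.
#' @param convention `"calendar"` (default) or `"rounded"`.
#' @return Interval in days.
#' @export
months_to_days <- function(months, convention = c("calendar", "rounded")) {
  convention <- match.arg(convention)
  days <- months * 365.25 / 12
  if (convention == "rounded") days <- round(days)
  days
}

#' Round a size to the reader's recording precision
#'
#' Sizes are recorded at 0.1-mm granularity.
#'
#' @param d Size in mm.
#' @param precision Recording granularity in mm (default 0.1).
#' @return `d` rounded to the nearest multiple of `precision`.
#' @export
round_size <- function(d, precision = 0.1) {
  round(d / precision) * precision
}
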