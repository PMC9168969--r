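# The "clinical fit": the probability distribution of tumor volume doubling
# times fitted to clinical data, used as the sampling source for virtual
# cohorts.  Doubling times are strictly positive durations, so the gamma
# family (location fixed at zero) is the default; a normal family is kept as
# the comparison candidate for model selection.

#' Construct a clinical TVDT distribution object
#'
#' @param family `"gamma"` or `"normal"`.
#' @param shape,scale Gamma parameters (shape dimensionless, scale in days).
#' @param mean,sd Moments in days; for gamma these are derived from
#'   shape/scale and must satisfy `mean = shape*scale`, `sd^2 = shape*scale^2`.
#' @return An object of class `clinical_fit`.
#' @keywords internal
new_clinical_fit <- function(family, shape = NULL, scale = NULL, mean, sd) {
  stopifnot(family %in% c("gamma", "normal"))
  check_scalar_number(mean, "mean", 0, strict = TRUE)
  check_scalar_number(sd, "sd", 0, strict = TRUE)
  if (family == "gamma") {
    check_scalar_number(shape, "shape", 0, strict = TRUE)
    check_scalar_number(scale, "scale", 0, strict = TRUE)
    stopifnot(abs(shape * scale - mean) < 1e-8 * mean,
              abs(shape * scale^2 - sd^2) < 1e-8 * sd^2)
  }
  structure(
    list(family = family, shape = shape, scale = scale, mean = mean, sd = sd),
    class = "clinical_fit"
  )
}

#' @export
print.clinical_fit <- function(x, ...) {
  cat(sprintf("<clinical_fit: %s>\n", x$family))
  if (x$family == "gamma") {
    cat(sprintf("  shape %.4f, scale %.2f days\n", x$shape, x$scale))
  }
  cat(sprintf("  mean %.1f days, sd %.1f days\n", x$mean, x$sd))
  invisible(x)
}

#' Build the clinical fit from its published moments
#'
#' Inverts the gamma moment identities: `shape = mean^2/sd^2`,
#' `scale = sd^2/mean`.  This constructs the canonical clinical fit
#' (mean 297 days, SD 169 days) without access to the raw doubling-time
#' values, which were published only as a histogram.
#'
#' @param mean Mean doubling time in days (> 0).
#' @param sd Standard deviation in days (> 0).
#' @return A `clinical_fit` of family gamma.
#' @examples
#' fit_from_moments(297, 169)  # shape ~3.09, scale ~96.2 days
#' @export
fit_from_moments <- function(mean = 297, sd = 169) {
  check_scalar_number(mean, "mean", 0, strict = TRUE)
  check_scalar_number(sd, "sd", 0, strict = TRUE)
  new_clinical_fit("gamma", shape = mean^2 / sd^2, scale = sd^2 / mean,
                   mean = mean, sd = sd)
}

#' Fit a distribution family to doubling-time values
#'
#' Maximum-likelihood fit of the requested family.  The gamma fit fixes the
#' location at zero, since doubling times are strictly positive durations.
#'
#' @param values Numeric vector of doubling times in days (>= 3 finite
#'   values; strictly positive for the gamma family).
#' @param family `"gamma"` (default) or `"normal"`.
#' @return A `clinical_fit` carrying the ML parameters and the moments they
#'   imply.
#' @export
fit_distribution <- function(values, family = c("gamma", "normal")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(values) < 3) {
    stop("need at least 3 values to fit a distribution", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate fit: all values are identical", call. = FALSE)
  }
  if (family == "gamma") {
    if (any(values <= 0)) {
      stop("gamma family requires strictly positive values", call. = FALSE)
    }
    fd <- fitdistrplus::fitdist(values, "gamma", method = "mle")
    shape <- unname(fd$estimate["shape"])
    scale <- 1 / unname(fd$estimate["rate"])
    new_clinical_fit("gamma", shape = shape, scale = scale,
                     mean = shape * scale, sd = sqrt(shape) * scale)
  } else {
    # closed-form ML for the normal: sample mean, sd with denominator n
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))
    new_clinical_fit("normal", mean = m, sd = s)
  }
}

#' Sample doubling times from a clinical fit
#'
#' @param fit A `clinical_fit`.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; a fixed seed gives a reproducible
#'   sequence without touching the caller's RNG state.
#' @return Numeric vector of `n` doubling times in days.
#' @export
sample_tvdt <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "clinical_fit"))
  check_scalar_number(n, "n", 1)
  with_seed_if(seed, {
    if (fit$family == "gamma") {
      stats::rgamma(n, shape = fit$shape, scale = fit$scale)
    } else {
      stats::rnorm(n, mean = fit$mean, sd = fit$sd)
    }
  })
}

# Density/CDF of a clinical_fit, used for plotting and goodness of fit.
fit_density <- function(fit, x) {
  if (fit$family == "gamma") {
    stats::dgamma(x, shape = fit$shape, scale = fit$scale)
  } else {
    stats::dnorm(x, mean = fit$mean, sd = fit$sd)
  }
}

fit_cdf <- function(fit, x) {
  if (fit$family == "gamma") {
    stats::pgamma(x, shape = fit$shape, scale = fit$scale)
  } else {
    stats::pnorm(x, mean = fit$mean, sd = fit$sd)
  }
}

# Anderson-Darling statistic of `x` against a fitted clinical_fit.
ad_statistic <- function(x, fit) {
  x <- sort(x)
  n <- length(x)
  u <- fit_cdf(fit, x)
  # guard the logs against numerically exact 0/1
  eps <- .Machine$double.eps
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Rank candidate distribution families by goodness of fit
#'
#' For each candidate family the parameters are estimated by maximum
#' likelihood and the Anderson-Darling statistic is computed against the
#' fitted distribution.  Because the parameters are estimated from the data,
#' tabulated critical values do not apply; the p-value is obtained by
#' parametric bootstrap, re-estimating the parameters in every replicate.
#' Families are ranked by decreasing p-value.
#'
#' @param values Numeric doubling times in days (>= 8 values).
#' @param candidates Character vector of families to consider
#'   (subset of `"gamma"`, `"normal"`).
#' @param n_boot Bootstrap replicates per family (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return A data frame with one row per family: `family`, `ad_statistic`,
#'   `p_value`, ordered best fit first, plus the fitted objects in
#'   `attr(, "fits")`.
#' @export
select_family <- function(values, candidates = c("gamma", "normal"),
                          n_boot = 1000, seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 8) {
    stop("need at least 8 values for family selection", call. = FALSE)
  }
  candidates <- match.arg(candidates, c("gamma", "normal"), several.ok = TRUE)
  res <- lapply(candidates, function(fam) {
    fit <- fit_distribution(values, fam)
    a_obs <- ad_statistic(values, fit)
    boot <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(b) {
        xb <- sample_tvdt(fit, length(values))
        if (fam == "gamma") xb <- pmax(xb, .Machine$double.eps)
        fb <- tryCatch(fit_distribution(xb, fam), error = function(e) fit)
        ad_statistic(xb, fb)
      }, numeric(1))
    })
    list(fit = fit, stat = a_obs, p = (1 + sum(boot >= a_obs)) / (n_boot + 1))
  })
  names(res) <- candidates
  out <- data.frame(
    family = candidates,
    ad_statistic = vapply(res, `[[`, numeric(1), "stat"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    row.names = NULL
  )
  out <- out[order(-out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- lapply(res, `[[`, "fit")
  out
}

#' Read clinical doubling-time values from CSV
#'
#' Expects a headered CSV with a `tvdt_days` column.
#'
#' @param path File path.
#' @return Numeric vector of doubling times in days.
#' @export
read_tvdt_values <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"tvdt_days" %in% names(df)) {
    stop("file must contain a `tvdt_days` column", call. = FALSE)
  }
  v <- df$tvdt_days
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("`tvdt_days` must be positive and finite", call. = FALSE)
  }
  v
}

#' Write a fitted distribution summary as JSON
#'
#' @param fit A `clinical_fit`.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "clinical_fit"))
  jsonlite::write_json(
    fit[!vapply(fit, is.null, logical(1))],
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
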