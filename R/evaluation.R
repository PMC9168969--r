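# Statistical battery comparing clinical, simulated (assigned), and
# estimated doubling-time data sets: normality, session reproducibility,
# nonparametric pairwise comparisons, median difference / IQR, size
# regressions, and the fast/slow growth-class error analysis.  Tests are
# reported individually at the 0.05 level; no multiplicity adjustment is
# applied.

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector (n >= 3, non-degenerate).
#' @return List with `statistic` (W) and `p_value`.
#' @export
test_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Friedman test of measurement-session reproducibility
#'
#' Paired comparison of the same quantities (e.g. measured sizes of the same
#' tumors) across repeated reading sessions.
#'
#' @param sessions A numeric matrix (rows = subjects, columns = sessions) or
#'   a list of equal-length numeric vectors, one per session.
#' @return List with `statistic` (Friedman chi-square), `df`, and `p_value`;
#'   identical sessions give statistic 0 and p = 1 (no discrimination).
#' @export
test_reproducibility <- function(sessions) {
  if (is.list(sessions) && !is.data.frame(sessions)) {
    len <- lengths(sessions)
    if (length(unique(len)) != 1) {
      stop("sessions must have equal lengths", call. = FALSE)
    }
    sessions <- do.call(cbind, sessions)
  }
  sessions <- as.matrix(sessions)
  if (ncol(sessions) < 2 || nrow(sessions) < 3) {
    stop("need >= 2 sessions and >= 3 subjects", call. = FALSE)
  }
  # fully tied rows (e.g. identical sessions) leave the rank variance at
  # zero; report the no-discrimination boundary rather than NaN
  spread <- apply(sessions, 1, function(r) max(r) - min(r))
  if (all(spread == 0)) {
    return(list(statistic = 0, df = ncol(sessions) - 1, p_value = 1))
  }
  ft <- stats::friedman.test(sessions)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

#' Compare two doubling-time data sets
#'
#' Runs the two-sample Kolmogorov-Smirnov test (same distribution?) and,
#' for paired data, the Wilcoxon signed-rank test (systematic shift in the
#' pairs?).  Sentinel (`NA`) doubling times are excluded — pairwise for
#' paired data — and the exclusion count is reported, so
#' `n_used + n_excluded` always accounts for the input.  The KS test uses
#' the exact small-sample computation where R provides it; zero differences
#' in the signed-rank test are dropped per the signed-rank convention, with
#' the count reported.  Two identical samples are reported as no difference
#' (KS statistic 0; Wilcoxon degenerate with p = 1).
#'
#' @param x,y Numeric vectors (n >= 5 each after exclusion).
#' @param paired Are `x[i]` and `y[i]` measurements of the same patient?
#' @return List: `ks` (statistic, p_value), `wilcoxon` (statistic, p_value,
#'   n_zero_dropped; `NULL` if unpaired), `n_used`, `n_excluded`.
#' @export
compare_pair <- function(x, y, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired comparison requires equal lengths", call. = FALSE)
    }
    keep <- is.finite(x) & is.finite(y)
    n_excluded <- sum(!keep)
    x <- x[keep]; y <- y[keep]
  } else {
    n_excluded <- sum(!is.finite(x)) + sum(!is.finite(y))
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
  }
  if (length(x) < 5 || length(y) < 5) {
    stop("need at least 5 usable values per sample", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(x, y))
  out <- list(
    ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
    wilcoxon = NULL,
    n_used = length(x), n_excluded = n_excluded
  )
  if (paired) {
    d <- x - y
    n_zero <- sum(d == 0)
    if (all(d == 0)) {
      out$wilcoxon <- list(statistic = 0, p_value = 1,
                           n_zero_dropped = n_zero, note = "no difference")
    } else {
      w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      out$wilcoxon <- list(statistic = unname(w$statistic),
                           p_value = w$p.value, n_zero_dropped = n_zero)
    }
  }
  out
}

#' Median difference and IQR between assigned and estimated doubling times
#'
#' Per-patient differences are `assigned - estimated` (a positive median
#' means the estimates run short).  Quartiles use the linear-interpolation
#' quantile rule (R type 7).  Sentinel pairs are excluded with the count
#' reported.
#'
#' @param assigned,estimated Paired numeric vectors (days).
#' @return List: `median_days`, `iqr_days`, `n_used`, `n_excluded`.
#' @export
median_difference <- function(assigned, estimated) {
  if (length(assigned) != length(estimated)) {
    stop("inputs must be paired (equal length)", call. = FALSE)
  }
  keep <- is.finite(assigned) & is.finite(estimated)
  if (!any(keep)) stop("no usable pairs after sentinel exclusion",
                       call. = FALSE)
  d <- assigned[keep] - estimated[keep]
  list(median_days = stats::median(d),
       iqr_days = unname(stats::IQR(d, type = 7)),
       n_used = sum(keep), n_excluded = sum(!keep))
}

#' Regress measured tumor sizes on the true (simulated) sizes
#'
#' Ordinary least squares of `measured ~ true`, one fit per screening round
#' in typical use.  A slope near 1 and intercept near 0 indicate unbiased
#' size measurement; the R-squared summarizes scatter.
#'
#' @param true_sizes,measured_sizes Paired numeric vectors in mm (n >= 3).
#' @return List: `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_sizes <- function(true_sizes, measured_sizes) {
  keep <- is.finite(true_sizes) & is.finite(measured_sizes)
  x <- true_sizes[keep]; y <- measured_sizes[keep]
  if (length(x) < 3) stop("need at least 3 paired sizes", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("zero variance in true sizes", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # a perfect fit triggers a harmless precision warning in summary.lm
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(x))
}

#' Fast/slow growth-class accuracy analysis
#'
#' Fast-growing tumors are the lowest quartile of assigned doubling time,
#' slow-growing the highest quartile; each class holds `floor(n/4)` members
#' (ranking by assigned value, ties broken by input order for determinism).
#' The per-patient absolute relative error `|estimated - assigned|/assigned`
#' is compared between the classes with the two-sample t-test (pooled
#' variance).
#'
#' @param assigned,estimated Paired numeric doubling times in days
#'   (n >= 8 so each class holds >= 2 members).
#' @return List: `n_per_class`, `fast` / `slow` (indices, mean_abs_rel_error),
#'   `t_statistic`, `p_value` (both `NA` with a note when the errors are
#'   degenerate, e.g. estimated == assigned everywhere).
#' @export
growth_class_analysis <- function(assigned, estimated) {
  if (length(assigned) != length(estimated)) {
    stop("inputs must be paired (equal length)", call. = FALSE)
  }
  n <- length(assigned)
  if (n < 8) stop("need at least 8 patients for quartile classes",
                  call. = FALSE)
  k <- floor(n / 4)
  ord <- order(assigned, seq_len(n))  # ties broken by input order
  fast_idx <- ord[seq_len(k)]
  slow_idx <- ord[seq(n - k + 1, n)]
  rel_err <- abs(estimated - assigned) / assigned
  err_fast <- rel_err[fast_idx]
  err_slow <- rel_err[slow_idx]
  if (any(!is.finite(c(err_fast, err_slow)))) {
    stop("sentinel estimates inside a quartile class; exclude them first",
         call. = FALSE)
  }
  out <- list(
    n_per_class = k,
    fast = list(indices = fast_idx, mean_abs_rel_error = mean(err_fast)),
    slow = list(indices = slow_idx, mean_abs_rel_error = mean(err_slow))
  )
  if (stats::sd(c(err_fast, err_slow)) == 0) {
    out$t_statistic <- NA_real_
    out$p_value <- NA_real_
    out$note <- "degenerate: identical errors in both classes (no difference)"
  } else {
    tt <- stats::t.test(err_fast, err_slow, var.equal = TRUE)
    out$t_statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  }
  out
}

#' Assemble the full evaluation report
#'
#' Runs the whole battery on one simulated screening experiment: normality
#' of each doubling-time data set, Friedman reproducibility of the size
#' measurements per round, paired comparisons of assigned vs estimated
#' doubling times per session, median difference / IQR per session, size
#' regression per round, and the fast/slow quartile analysis on the
#' session-averaged estimates.  When clinical doubling-time values are
#' supplied, clinical-vs-estimated and clinical-vs-fit comparisons are
#' added.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param records Measurement records from [measure_cohort()].
#' @param fit The `clinical_fit` the cohort was sampled from.
#' @param clinical Optional numeric vector of clinical doubling times
#'   (days).
#' @param alpha Significance level recorded in the report (default 0.05).
#' @param month_convention Passed to [estimate_cohort_tvdt()].
#' @return A list of class `tvdt_report`.
#' @export
build_report <- function(cohort, records, fit, clinical = NULL,
                         alpha = 0.05, month_convention = "calendar") {
  stopifnot(inherits(fit, "clinical_fit"))
  est <- estimate_cohort_tvdt(records, cohort,
                              month_convention = month_convention)
  if (!setequal(unique(est$patient_id), cohort$id)) {
    stop("records and cohort cover different patient sets", call. = FALSE)
  }
  sessions <- sort(unique(est$session))
  est_wide <- tidyr::pivot_wider(est[c("patient_id", "session",
                                       "tvdt_est_days")],
                                 names_from = "session",
                                 values_from = "tvdt_est_days")
  est_wide <- est_wide[match(cohort$id, est_wide$patient_id), ]
  est_mat <- as.matrix(est_wide[, -1, drop = FALSE])
  est_avg <- rowMeans(est_mat)

  normality <- list(simulated = test_normality(cohort$tvdt_days))
  for (s in sessions) {
    v <- est_mat[, as.character(s)]
    normality[[paste0("estimated_session", s)]] <-
      tryCatch(test_normality(v), error = function(e) list(error = conditionMessage(e)))
  }
  if (!is.null(clinical)) normality$clinical <- test_normality(clinical)

  reproducibility <- lapply(1:2, function(r) {
    sz <- records[records$round == r, c("patient_id", "session",
                                        "mean_size_mm")]
    wide <- tidyr::pivot_wider(sz, names_from = "session",
                               values_from = "mean_size_mm")
    test_reproducibility(as.matrix(wide[, -1]))
  })
  names(reproducibility) <- c("round1", "round2")

  pairwise <- list()
  for (s in sessions) {
    pairwise[[paste0("simulated_vs_estimated_session", s)]] <-
      compare_pair(cohort$tvdt_days, est_mat[, as.character(s)],
                   paired = TRUE)
  }
  if (!is.null(clinical)) {
    for (s in sessions) {
      pairwise[[paste0("clinical_vs_estimated_session", s)]] <-
        compare_pair(clinical, est_mat[, as.character(s)], paired = FALSE)
    }
    pairwise$clinical_vs_simulated <-
      compare_pair(clinical, cohort$tvdt_days, paired = FALSE)
  }

  median_diff <- lapply(sessions, function(s) {
    median_difference(cohort$tvdt_days, est_mat[, as.character(s)])
  })
  names(median_diff) <- paste0("session", sessions)

  regression <- lapply(1:2, function(r) {
    sz <- records[records$round == r, ]
    true_d <- if (r == 1) cohort$d1_mm else cohort$d2_mm
    regress_sizes(true_d[match(sz$patient_id, cohort$id)], sz$mean_size_mm)
  })
  names(regression) <- c("round1", "round2")

  keep <- is.finite(est_avg)
  growth_class <- growth_class_analysis(cohort$tvdt_days[keep],
                                        est_avg[keep])

  structure(
    list(
      alpha = alpha,
      n_patients = nrow(cohort),
      n_sessions = length(sessions),
      family_selection = NULL,
      normality = normality,
      reproducibility = reproducibility,
      pairwise = pairwise,
      median_diff = median_diff,
      regression = regression,
      growth_class = growth_class,
      estimates = est,
      fit = fit
    ),
    class = "tvdt_report"
  )
}

#' @export
print.tvdt_report <- function(x, ...) {
  cat(sprintf("Doubling-time evaluation report (%d patients, %d sessions, alpha = %g)\n",
              x$n_patients, x$n_sessions, x$alpha))
  cat("\nReproducibility of size measurements (Friedman):\n")
  for (r in names(x$reproducibility)) {
    cat(sprintf("  %s: chi-sq = %.2f, p = %.3f\n", r,
                x$reproducibility[[r]]$statistic,
                x$reproducibility[[r]]$p_value))
  }
  cat("\nAssigned vs estimated doubling times:\n")
  for (nm in grep("^simulated_vs_estimated", names(x$pairwise),
                  value = TRUE)) {
    pw <- x$pairwise[[nm]]
    cat(sprintf("  %s: KS p = %.3f, Wilcoxon p = %.4f\n", nm,
                pw$ks$p_value, pw$wilcoxon$p_value))
  }
  cat("\nMedian difference (IQR), days:\n")
  for (nm in names(x$median_diff)) {
    md <- x$median_diff[[nm]]
    cat(sprintf("  %s: %.0f (%.0f), n = %d\n", nm, md$median_days,
                md$iqr_days, md$n_used))
  }
  cat("\nSize regression (measured ~ true):\n")
  for (nm in names(x$regression)) {
    rg <- x$regression[[nm]]
    cat(sprintf("  %s: slope %.3f, intercept %.2f, R^2 = %.3f\n", nm,
                rg$slope, rg$intercept, rg$r_squared))
  }
  cat(sprintf("\nFast vs slow growth classes (n = %d each): t = %s, p = %s\n",
              x$growth_class$n_per_class,
              format(x$growth_class$t_statistic, digits = 3),
              format(x$growth_class$p_value, digits = 3)))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A `tvdt_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "tvdt_report"))
  out <- report
  out$estimates <- as.data.frame(out$estimates)
  out$fit <- out$fit[!vapply(out$fit, is.null, logical(1))]
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Histogram of doubling times with a fitted density overlay
#'
#' @param values Numeric doubling times (days).
#' @param fit Optional `clinical_fit` whose density is overlaid.
#' @param binwidth Histogram bin width in days.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_tvdt_hist <- function(values, fit = NULL, binwidth = 100,
                           title = "Doubling times") {
  df <- data.frame(tvdt = values[is.finite(values)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tvdt)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey75",
                            colour = "grey30") +
    ggplot2::labs(x = "Doubling time (days)", y = "Density",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(max(1, min(df$tvdt) * 0.5), max(df$tvdt) * 1.2,
              length.out = 400)
    p <- p + ggplot2::geom_line(
      data = data.frame(x = xs, y = fit_density(fit, xs)),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "red",
      linewidth = 0.8
    )
  }
  p
}

#' Overlay the fitted densities of several doubling-time data sets
#'
#' @param fits Named list of `clinical_fit` objects.
#' @param xlim Range of doubling times to draw, days.
#' @return A ggplot object.
#' @export
plot_fit_overlay <- function(fits, xlim = c(1, 1500)) {
  stopifnot(length(names(fits)) == length(fits))
  xs <- seq(xlim[1], xlim[2], length.out = 500)
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    data.frame(dataset = nm, x = xs, y = fit_density(fits[[nm]], xs))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$dataset)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Doubling time (days)", y = "Density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
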