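# End-to-end pipeline: simulate a cohort, measure it, estimate doubling
# times, evaluate, and write all artifacts with one master seed.  This is
# the programmatic core behind the command-line front end in
# `inst/cli/tvdtsim.R`.

#' Run the full virtual screening experiment
#'
#' Chains cohort generation, the simulated observer (three sessions by
#' default), doubling-time estimation, and the statistical evaluation, and
#' writes every artifact to `out_dir`: `cohort.csv`, `measurements.csv`,
#' `tvdt_estimates.csv`, `report.json`, `clinical_fit.json`, and a
#' `manifest.json` recording the configuration and seed.  All randomness
#' derives from the single master seed, so a rerun with the same
#' configuration is identical.
#'
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing and just returns the results.
#' @param n Cohort size.
#' @param seed Master seed.
#' @param fit `clinical_fit` sampling source for doubling times.
#' @param noise [observer_noise()] model for the simulated reader.
#' @param n_sessions Number of repeated measurement sessions.
#' @param month_convention Passed to [months_to_days()].
#' @param clinical Optional clinical doubling-time values (days) to include
#'   in the comparisons.
#' @return Invisibly, a list with `cohort`, `records`, `estimates`,
#'   `report`, and `paths` (when written).
#' @export
run_pipeline <- function(out_dir = NULL, n = 30, seed = 1,
                         fit = fit_from_moments(297, 169),
                         noise = observer_noise(), n_sessions = 3,
                         month_convention = "calendar", clinical = NULL) {
  cfg <- cohort_config(n = n, seed = derive_seed(seed, "cohort"), fit = fit,
                       month_convention = month_convention)
  cohort <- generate_cohort(cfg)
  records <- measure_cohort(cohort, noise = noise, n_sessions = n_sessions,
                            seed = derive_seed(seed, "observer"))
  estimates <- estimate_cohort_tvdt(records, cohort,
                                    month_convention = month_convention)
  report <- build_report(cohort, records, fit, clinical = clinical,
                         month_convention = month_convention)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      cohort = file.path(out_dir, "cohort.csv"),
      measurements = file.path(out_dir, "measurements.csv"),
      estimates = file.path(out_dir, "tvdt_estimates.csv"),
      report = file.path(out_dir, "report.json"),
      fit = file.path(out_dir, "clinical_fit.json"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_cohort(cohort, paths$cohort)
    write_measurements(records, paths$measurements)
    readr::write_csv(estimates, paths$estimates)
    write_report(report, paths$report)
    write_fit(fit, paths$fit)
    manifest <- list(
      package = "tvdtsim",
      version = as.character(utils::packageVersion("tvdtsim")),
      seed = seed, n = n, n_sessions = n_sessions,
      month_convention = month_convention,
      noise = unclass(noise),
      fit = fit[!vapply(fit, is.null, logical(1))]
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(cohort = cohort, records = records, estimates = estimates,
                 report = report, paths = paths))
}
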