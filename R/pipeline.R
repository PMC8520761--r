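#' Run one simulated experiment end to end
#'
#' Orchestrates the full pipeline for one experiment: builds the
#' design, optionally generates the complete stimulus inventory,
#' simulates a cohort of Weber-noise grouping observers, fits every
#' subject-by-condition psychometric function, and runs the
#' repeated-measures analyses on the fitted PSEs and CoVs (two-way
#' contour-by-colour ANOVA for experiment 1, one-way contour ANOVA for
#' experiments 2 and 3, plus Bonferroni post hocs and polynomial trend
#' contrasts on the contour factor). All randomness derives from
#' `seed`; identical calls give identical outputs.
#'
#' @param experiment 1, 2 or 3.
#' @param seed Integer master seed.
#' @param params Cohort [observer_params()].
#' @param n_subjects Cohort size; defaults to the design's sample size.
#' @param stimuli Also generate the full stimulus set (slower)?
#' @param bootstrap Attach bootstrap CIs to every fit (much slower)?
#' @param sdlog Between-subject Weber-fraction spread; see
#'   [simulate_cohort()].
#' @param out_dir Optional directory; when given, trials, fits, ANOVA
#'   tables and a plain-text report (and the stimulus manifest/JSON when
#'   `stimuli`) are written beneath it.
#' @return An `icnum_run` list: `design`, `trials`, `fits`, `anova_pse`,
#'   `anova_cov`, `posthoc`, `trend`, `stimuli` (or NULL), `report`
#'   (character vector), `seed`.
#' @export
#' @examples
#' \donttest{
#' run <- run_experiment(2, seed = 7, n_subjects = 8)
#' run$anova_pse
#' }
run_experiment <- function(experiment = 1, seed = 1L,
                           params = observer_params(),
                           n_subjects = NULL, stimuli = FALSE,
                           bootstrap = FALSE, sdlog = 0.15,
                           out_dir = NULL) {
  design <- build_design(experiment)
  if (is.null(n_subjects)) n_subjects <- design$n_subjects
  seeds <- derive_seeds(seed, 3)

  stim <- NULL
  if (stimuli) {
    stim <- generate_stimulus_set(experiment, seed = seeds[1])
  }
  trials <- simulate_cohort(design, params, n_subjects = n_subjects,
                            seed = seeds[2], sdlog = sdlog)
  fits <- fit_conditions(trials, bootstrap = bootstrap, seed = seeds[3])

  within <- if (experiment == 1) c("n_ic", "scheme") else "n_ic"
  anova_pse <- rm_anova(fits, dv = "pse", within = within)
  anova_cov <- rm_anova(fits, dv = "cov", within = within)
  posthoc <- bonferroni_posthoc(fits, dv = "pse", factor = "n_ic")
  trend <- linear_trend(fits, dv = "pse", factor = "n_ic")

  run <- structure(
    list(design = design, trials = trials, fits = fits,
         anova_pse = anova_pse, anova_cov = anova_cov,
         posthoc = posthoc, trend = trend,
         stimuli = stim, seed = as.integer(seed),
         report = character(0)),
    class = "icnum_run"
  )
  run$report <- run_report(run)
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

run_report <- function(run) {
  eff <- run$anova_pse$effects
  ic <- eff[eff$effect == "n_ic", ]
  p_ic <- if (ic$gg_primary) ic$p.value_gg else ic$p.value
  lines <- c(
    sprintf("Experiment %d: %d subjects, %d conditions, %d trials/subject",
            run$design$experiment, run$anova_pse$n_subjects,
            run$design$n_conditions, run$design$n_trials),
    sprintf("PSE ~ number of illusory contours: F(%g, %g) = %.2f, eps = %.2f, p = %.4g [%s]",
            ic$df1, ic$df2, ic$statistic, ic$epsilon, p_ic,
            if (p_ic < 0.05) "significant" else "n.s."),
    sprintf("Linear trend of PSE over contours: t(%g) = %.2f, p = %.4g",
            run$trend$df[1], run$trend$statistic[1], run$trend$p.value[1])
  )
  if ("scheme" %in% eff$effect) {
    int <- eff[eff$effect == "n_ic:scheme", ]
    p_int <- if (int$gg_primary) int$p.value_gg else int$p.value
    lines <- c(lines, sprintf(
      "Contours x colour interaction: F(%g, %g) = %.2f, p = %.4g [%s]",
      int$df1, int$df2, int$statistic, p_int,
      if (p_int < 0.05) "significant" else "n.s."))
  }
  cov_ic <- run$anova_cov$effects
  cov_ic <- cov_ic[cov_ic$effect == "n_ic", ]
  p_cov <- if (cov_ic$gg_primary) cov_ic$p.value_gg else cov_ic$p.value
  c(lines, sprintf(
    "CoV ~ number of contours: F(%g, %g) = %.2f, p = %.4g [%s] (Weber constancy)",
    cov_ic$df1, cov_ic$df2, cov_ic$statistic, p_cov,
    if (p_cov < 0.05) "significant" else "n.s."))
}

#' @export
print.icnum_run <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

# write all tabular outputs of a run; deterministic CSVs
write_run <- function(run, out_dir) {
  dirs <- file.path(out_dir, c("trials", "fits", "stats"))
  if (!is.null(run$stimuli)) dirs <- c(dirs, file.path(out_dir, "stimuli"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, path) {
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  }
  wcsv(run$trials, file.path(out_dir, "trials", "trials.csv"))
  wcsv(run$fits, file.path(out_dir, "fits", "fits.csv"))
  wcsv(tidy(run$anova_pse), file.path(out_dir, "stats", "anova_pse.csv"))
  wcsv(tidy(run$anova_cov), file.path(out_dir, "stats", "anova_cov.csv"))
  wcsv(run$posthoc, file.path(out_dir, "stats", "posthoc_pse.csv"))
  wcsv(run$trend, file.path(out_dir, "stats", "trend_pse.csv"))
  writeLines(run$report, file.path(out_dir, "stats", "report.txt"))
  if (!is.null(run$stimuli)) {
    wcsv(run$stimuli$manifest, file.path(out_dir, "stimuli", "manifest.csv"))
    for (id in names(run$stimuli$patterns)) {
      pattern_to_json(run$stimuli$patterns[[id]],
                      file.path(out_dir, "stimuli", paste0(id, ".json")))
    }
  }
  invisible(out_dir)
}

#' Plot mean PSE (or CoV) against the number of illusory contours
#'
#' Condition means with +/- 1 SEM error bars over subjects, one line per
#' colour scheme, mirroring the standard summary figure of this
#' paradigm.
#'
#' @param fits A per-condition fit table from [fit_conditions()].
#' @param dv `"pse"` or `"cov"`.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(fits, dv = c("pse", "cov")) {
  dv <- match.arg(dv)
  has_scheme <- "scheme" %in% names(fits) && length(unique(fits$scheme)) > 1
  grp <- c("n_ic", if (has_scheme) "scheme")
  summ <- fits |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(mean = mean(.data[[dv]]),
              sem = sd(.data[[dv]]) / sqrt(n()), .groups = "drop")
  aes_base <- if (has_scheme) {
    ggplot2::aes(x = .data$n_ic, y = .data$mean, colour = .data$scheme,
                 group = .data$scheme)
  } else {
    ggplot2::aes(x = .data$n_ic, y = .data$mean, group = 1)
  }
  ggplot2::ggplot(summ, aes_base) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::scale_x_continuous(breaks = c(0, 2, 4)) +
    ggplot2::labs(x = "number of illusory contours",
                  y = if (dv == "pse") "mean PSE (items)" else "mean CoV") +
    ggplot2::theme_minimal()
}
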