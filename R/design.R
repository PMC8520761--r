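#' Build the factorial design of one experiment
#'
#' Returns the trial-design bookkeeping of the three 2AFC numerosity
#' discrimination experiments: test numerosities 9-15 against a fixed
#' 12-item reference, illusory-contour levels 0/2/4, 16 trials per
#' condition cell split over two counterbalanced blocks, 24 training
#' trials, and 8 base patterns per numerosity. Experiment 1 crosses the
#' contour factor with inducer colour (all-black vs all-white: 42
#' condition cells, 672 experimental trials); experiments 2 and 3 use
#' the mixed reverse-contrast scheme only (21 cells, 336 trials);
#' experiment 3 is the closed-inducer control.
#'
#' @param experiment 1, 2 or 3.
#' @return An `experiment_design` list whose `$conditions` tibble has one
#'   row per condition cell (`n_ic`, `numerosity`, `scheme`).
#' @export
#' @examples
#' d <- build_design(1)
#' d$n_conditions  # 42
#' d$n_trials      # 672
build_design <- function(experiment) {
  if (!length(experiment) == 1 || !experiment %in% 1:3) {
    abort("`experiment` must be 1, 2 or 3.")
  }
  schemes <- if (experiment == 1) c("all_black", "all_white") else "mixed"
  conditions <- tidyr::expand_grid(
    n_ic = c(0L, 2L, 4L),
    numerosity = 9:15,
    scheme = schemes
  )
  design <- list(
    experiment = as.integer(experiment),
    numerosities = 9:15,
    reference_n = 12L,
    ic_levels = c(0L, 2L, 4L),
    schemes = schemes,
    trials_per_condition = 16L,
    blocks = 2L,
    training_trials = 24L,
    base_patterns_per_numerosity = 8L,
    closed = experiment == 3,
    n_subjects = c(28L, 23L, 24L)[experiment],
    conditions = conditions,
    n_conditions = nrow(conditions),
    n_trials = nrow(conditions) * 16L
  )
  structure(design, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> experiment %d: %d conditions (%d IC levels x %d numerosities x %d scheme(s)), %d trials, %s inducers\n",
    x$experiment, x$n_conditions, length(x$ic_levels),
    length(x$numerosities), length(x$schemes), x$n_trials,
    if (x$closed) "closed" else "open"
  ))
  invisible(x)
}
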