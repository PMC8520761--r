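#' Parameters of the Weber-noise grouping observer
#'
#' The synthetic observer encodes each array's numerosity with
#' multiplicative (Weber-law) Gaussian noise and treats every
#' illusory-contour-connected pair of inducers as contributing
#' `pair_weight` effective items instead of 2: the illusory line binds
#' the two Pac-Men into one dumbbell-like object, so a connected pair
#' counts as less than two units. Grouping is blind to contrast
#' polarity (the boundary-completion process it stands for pools across
#' opposite contrasts) and, unless `applies_to_closed` is set, does not
#' operate on closed inducers, whose sealed notches prevent contour
#' completion.
#'
#' @param weber Weber fraction w > 0; the internal estimate of an array
#'   with effective numerosity E is Gaussian with mean E and SD w * E.
#' @param pair_weight Effective item count of one connected pair, in
#'   \[1, 2\]; 2 means no grouping, 1 means full fusion into one unit.
#' @param lapse Probability, in \[0, 0.05\], that a trial's response is
#'   replaced by a fair coin flip (attention lapse, finger error).
#' @param applies_to_closed Should grouping also apply to closed
#'   inducers? `FALSE` reflects the blocked contour completion.
#' @return An `observer_params` list.
#' @export
#' @examples
#' observer_params(weber = 0.2, pair_weight = 1.8)
observer_params <- function(weber = 0.2, pair_weight = 1.8, lapse = 0.02,
                            applies_to_closed = FALSE) {
  assert_number(weber, "weber", lower = 1e-12)
  assert_number(pair_weight, "pair_weight", lower = 1, upper = 2)
  assert_number(lapse, "lapse", lower = 0, upper = 0.05)
  assert_flag(applies_to_closed, "applies_to_closed")
  structure(
    list(weber = weber, pair_weight = pair_weight, lapse = lapse,
         applies_to_closed = applies_to_closed),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> w = %.3f, pair_weight = %.3f, lapse = %.3f, grouping on closed inducers: %s\n",
    x$weber, x$pair_weight, x$lapse, x$applies_to_closed
  ))
  invisible(x)
}

#' Effective numerosity under illusory-contour grouping
#'
#' The observer's unit count for an array of `n` items of which `k`
#' pairs are contour-connected: each connected pair contributes
#' `pair_weight` units instead of 2, giving `n - k * (2 - pair_weight)`.
#' Closed inducers block contour completion, so for `closed = TRUE` the
#' count stays `n` unless the observer's `applies_to_closed` is set.
#'
#' @param n Physical numerosity (vectorised).
#' @param k Number of connected pairs (vectorised); `2 * k` must not
#'   exceed `n`.
#' @param params An [observer_params()].
#' @param closed Are the inducers closed?
#' @return Effective numerosity, same length as `n`.
#' @export
#' @examples
#' effective_numerosity(12, 4, observer_params(pair_weight = 1))  # 8
effective_numerosity <- function(n, k, params, closed = FALSE) {
  stopifnot(inherits(params, "observer_params"))
  if (any(2 * k > n)) abort("`k` pairs require at least 2 * k items.")
  if (closed && !params$applies_to_closed) {
    return(as.numeric(n))
  }
  n - k * (2 - params$pair_weight)
}

#' Simulate 2AFC numerosity trials
#'
#' Simulates `n_trials` independent two-alternative forced-choice trials
#' of a test array (`n_test` items, `n_ic` connected pairs) against the
#' 12-item zero-contour reference. On each trial the observer draws
#' internal estimates for both arrays — Gaussian with mean equal to the
#' effective numerosity and SD equal to `weber` times that mean — and
#' chooses the array with the larger draw (exact ties broken by a fair
#' coin); with probability `lapse` the response is replaced by a coin
#' flip.
#'
#' @param n_test Test numerosity.
#' @param n_ic Connected pairs in the test array (the reference never
#'   carries contours).
#' @param params An [observer_params()].
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param closed Closed-inducer stimuli?
#' @param n_ref Reference numerosity.
#' @return Logical vector: was the test array chosen as more numerous?
#' @export
simulate_trials <- function(n_test, n_ic, params, n_trials = 16L,
                            seed = 1L, closed = FALSE, n_ref = 12L) {
  stopifnot(inherits(params, "observer_params"))
  e_test <- effective_numerosity(n_test, n_ic, params, closed)
  e_ref <- effective_numerosity(n_ref, 0L, params, closed)
  withr::with_seed(as.integer(seed), {
    draw_choices(rep(e_test, n_trials), rep(e_ref, n_trials), params)
  })
}

# vectorised core; assumes the RNG state is already managed by callers
draw_choices <- function(e_test, e_ref, params) {
  n <- length(e_test)
  est_t <- rnorm(n, mean = e_test, sd = params$weber * e_test)
  est_r <- rnorm(n, mean = e_ref, sd = params$weber * e_ref)
  chosen <- est_t > est_r
  tie <- est_t == est_r
  if (any(tie)) chosen[tie] <- runif(sum(tie)) < 0.5
  if (params$lapse > 0) {
    lapsed <- runif(n) < params$lapse
    if (any(lapsed)) chosen[lapsed] <- runif(sum(lapsed)) < 0.5
  }
  chosen
}

# closed-form P(test chosen): comparison of two independent Gaussians
# plus the lapse mixture. Used as an oracle in tests and for power
# reasoning; exported because it is the observer's analytic signature.

#' Analytic choice probability of the observer
#'
#' Probability that the test array is chosen, from the closed form for
#' the comparison of two independent Gaussian estimates:
#' `(1 - lapse) * pnorm((E_t - E_r) / sqrt(w^2 E_t^2 + w^2 E_r^2)) +
#' lapse / 2`.
#'
#' @inheritParams simulate_trials
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(n_test, n_ic, params, closed = FALSE,
                               n_ref = 12L) {
  e_t <- effective_numerosity(n_test, n_ic, params, closed)
  e_r <- effective_numerosity(n_ref, 0L, params, closed)
  p <- pnorm((e_t - e_r) / sqrt(params$weber^2 * (e_t^2 + e_r^2)))
  (1 - params$lapse) * p + params$lapse / 2
}

#' Simulate one subject's full experiment
#'
#' Enumerates the complete trial table of a design — 16 trials per
#' condition cell, the test side balanced left/right within each cell
#' and split evenly over the two blocks, order randomised within block —
#' and fills in the observer's responses. Reproducible: the same seed
#' yields an identical table.
#'
#' @param design An [build_design()] design.
#' @param params An [observer_params()].
#' @param seed Integer seed.
#' @param subject Subject identifier stored in the output.
#' @return A tibble with one row per trial: `experiment`, `subject`,
#'   `block`, `trial`, `n_ic`, `scheme`, `n_test`, `n_ref`, `side`
#'   (test side), `response` (test chosen), `rt_placeholder`.
#' @export
#' @examples
#' trials <- simulate_experiment(build_design(2), observer_params(), seed = 1)
#' nrow(trials)  # 336
simulate_experiment <- function(design, params = observer_params(),
                                seed = 1L, subject = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  tpc <- design$trials_per_condition
  if (tpc %% (2L * design$blocks) != 0L) {
    abort("trials per condition must split evenly over sides and blocks.")
  }
  per_block_side <- tpc / (2L * design$blocks)
  trials <- tidyr::expand_grid(
    design$conditions,
    block = seq_len(design$blocks),
    side = c("left", "right"),
    rep = seq_len(per_block_side)
  )
  withr::with_seed(as.integer(seed), {
    # randomise presentation order within block
    trials <- trials[order(trials$block, runif(nrow(trials))), ]
    trials$trial <- stats::ave(seq_len(nrow(trials)), trials$block,
                               FUN = seq_along)
    e_test <- effective_numerosity(trials$numerosity, trials$n_ic, params,
                                   design$closed)
    e_ref <- rep(effective_numerosity(design$reference_n, 0L, params,
                                      design$closed), nrow(trials))
    trials$response <- draw_choices(e_test, e_ref, params)
  })
  tibble(
    experiment = design$experiment,
    subject = subject,
    block = trials$block,
    trial = trials$trial,
    n_ic = trials$n_ic,
    scheme = trials$scheme,
    n_test = trials$numerosity,
    n_ref = design$reference_n,
    side = trials$side,
    response = trials$response,
    rt_placeholder = NA_real_
  )
}

#' Simulate a cohort of subjects
#'
#' Runs [simulate_experiment()] for `n_subjects` observers. By default
#' each subject's Weber fraction is drawn from a log-normal distribution
#' centred (median) on the cohort `params$weber` with log-SD `sdlog`,
#' capturing between-subject precision differences; set `sdlog = 0` for
#' identical observers. All per-subject seeds derive from `seed`.
#'
#' @param design An [build_design()] design.
#' @param params Cohort-level [observer_params()].
#' @param n_subjects Number of subjects; defaults to the design's sample
#'   size (28, 23 and 24 for experiments 1-3).
#' @param seed Integer master seed.
#' @param sdlog Between-subject log-SD of the Weber fraction.
#' @return A tibble of trials for all subjects (see
#'   [simulate_experiment()]).
#' @export
simulate_cohort <- function(design, params = observer_params(),
                            n_subjects = design$n_subjects, seed = 1L,
                            sdlog = 0.15) {
  stopifnot(inherits(design, "experiment_design"))
  seeds <- derive_seeds(seed, n_subjects + 1L)
  ws <- withr::with_seed(seeds[n_subjects + 1L], {
    exp(rnorm(n_subjects, mean = log(params$weber), sd = sdlog))
  })
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    ps <- params
    ps$weber <- ws[s]
    simulate_experiment(design, ps, seed = seeds[s], subject = s)
  })
}
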