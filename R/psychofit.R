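#' Cumulative-Gaussian psychometric function
#'
#' The standard four-parameter psychometric function
#' `psi(x) = gamma + (1 - gamma - lambda) * pnorm((x - mu) / sigma)`:
#' a cumulative Gaussian in test numerosity with a guess rate `gamma`
#' (lower asymptote) and lapse rate `lambda` (distance of the upper
#' asymptote from 1) absorbing stimulus-independent errors.
#'
#' @param x Test numerosity (vectorised).
#' @param mu Location, items.
#' @param sigma Spread, items; must be positive.
#' @param gamma,lambda Guess and lapse rates, each bounded to
#'   \[0, 0.05\] during fitting.
#' @return Choice probabilities in \[gamma, 1 - lambda\].
#' @export
#' @examples
#' predict_psychometric(12.5, mu = 12.5, sigma = 1)  # 0.5
predict_psychometric <- function(x, mu, sigma, gamma = 0, lambda = 0) {
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  gamma + (1 - gamma - lambda) * pnorm((x - mu) / sigma)
}

#' Point of subjective equality of a fitted psychometric function
#'
#' The test numerosity at which the test is chosen on 50% of trials,
#' solving `psi(x) = 0.5` on the full function including asymptotes:
#' `mu + sigma * qnorm((0.5 - gamma) / (1 - gamma - lambda))`. Equals
#' `mu` whenever `gamma == lambda`.
#'
#' @inheritParams predict_psychometric
#' @return PSE in items.
#' @export
pse_cumgauss <- function(mu, sigma, gamma = 0, lambda = 0) {
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  if (any(gamma >= 0.5) || any(lambda >= 0.5)) {
    abort("0.5 must lie strictly between the asymptotes.")
  }
  mu + sigma * qnorm((0.5 - gamma) / (1 - gamma - lambda))
}

#' Coefficient of variation
#'
#' Weber-fraction proxy: the fitted spread divided by the PSE. Constant
#' CoV across conditions is the signature of Weber-law performance.
#'
#' @param sigma Psychometric spread, items.
#' @param pse Point of subjective equality, items; must be positive.
#' @return `sigma / pse`.
#' @export
coef_variation <- function(sigma, pse) {
  if (any(pse <= 0)) abort("CoV undefined for PSE <= 0.")
  sigma / pse
}

# ---- likelihood machinery --------------------------------------------------

# grouped counts from a raw trial table
aggregate_trials <- function(trials) {
  if (all(c("x", "n_chosen", "n_total") %in% names(trials))) {
    return(as_tibble(trials[, c("x", "n_chosen", "n_total")]))
  }
  if (!all(c("n_test", "response") %in% names(trials))) {
    abort("need columns (x, n_chosen, n_total) or (n_test, response).")
  }
  trials |>
    group_by(x = .data$n_test) |>
    summarise(n_chosen = sum(.data$response), n_total = n(), .groups = "drop")
}

# binomial log-likelihood, vectorised over a parameter matrix
# theta: matrix with columns gamma, lambda, mu, sigma
loglik_matrix <- function(theta, counts) {
  eps <- 1e-12
  z <- outer(theta[, 3], counts$x, function(m, x) -m + x) / theta[, 4]
  p <- theta[, 1] + (1 - theta[, 1] - theta[, 2]) * pnorm(z)
  p <- pmin(pmax(p, eps), 1 - eps)
  as.vector(log(p) %*% counts$n_chosen +
              log(1 - p) %*% (counts$n_total - counts$n_chosen))
}

psy_negloglik <- function(par, counts) {
  eps <- 1e-12
  z <- (counts$x - par[3]) / par[4]
  p <- par[1] + (1 - par[1] - par[2]) * pnorm(z)
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(counts$n_chosen * log(p) +
         (counts$n_total - counts$n_chosen) * log(1 - p))
}

# analytic gradient of the negative log-likelihood
psy_negloglik_grad <- function(par, counts) {
  eps <- 1e-12
  z <- (counts$x - par[3]) / par[4]
  Phi <- pnorm(z)
  phi <- stats::dnorm(z)
  span <- 1 - par[1] - par[2]
  p <- pmin(pmax(par[1] + span * Phi, eps), 1 - eps)
  w <- counts$n_chosen / p - (counts$n_total - counts$n_chosen) / (1 - p)
  -c(
    sum(w * (1 - Phi)),
    sum(w * (-Phi)),
    sum(w * (-span * phi / par[4])),
    sum(w * (-span * phi * z / par[4]))
  )
}

default_start_grid <- function(counts, sigma_values = c(0.5, 1, 2, 4, 8)) {
  xr <- range(counts$x)
  as.matrix(tidyr::expand_grid(
    gamma = seq(0, 0.05, length.out = 4),
    lambda = seq(0, 0.05, length.out = 4),
    mu = seq(xr[1], xr[2], length.out = 5),
    sigma = sigma_values
  ))
}

#' Fit a psychometric function by maximum likelihood
#'
#' Maximises the binomial log-likelihood of grouped 2AFC counts over
#' (gamma, lambda, mu, sigma) with the guess and lapse rates bounded to
#' \[0, 0.05\]. A 4 x 4 x 5 x 5 start grid over (gamma, lambda, mu,
#' sigma) is evaluated in one vectorised pass and the best `n_polish`
#' grid points are polished with bounded quasi-Newton (L-BFGS-B); ties
#' are broken towards the smallest sigma. The spread is bounded below at
#' 0.05 items so step-like data cannot drive it to zero. The returned
#' fit carries the PSE (on the full function including asymptotes), the
#' CoV, the log-likelihood, honest convergence and boundary flags, and
#' the grouped counts for later bootstrapping.
#'
#' @param trials A data frame of raw trials (`n_test`, `response`) or
#'   grouped counts (`x`, `n_chosen`, `n_total`); at least two distinct
#'   stimulus levels.
#' @param mu_margin Half-width added to the stimulus range to bound mu.
#' @param sigma_max Upper bound on sigma, items.
#' @param n_polish Number of grid starts polished with L-BFGS-B.
#' @return A `psychometric_fit` object; see [glance.psychometric_fit()].
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   x = 9:15,
#'   n_total = 16,
#'   n_chosen = c(1, 2, 4, 8, 12, 14, 15)
#' )
#' fit <- fit_psychometric(counts)
#' glance(fit)
fit_psychometric <- function(trials, mu_margin = NULL, sigma_max = 30,
                             n_polish = 3L) {
  counts <- aggregate_trials(trials)
  if (nrow(counts) < 2) abort("need at least two distinct stimulus levels.")
  if (any(counts$n_total <= 0)) abort("every level needs at least one trial.")
  xr <- range(counts$x)
  span <- max(diff(xr), 1)
  if (is.null(mu_margin)) mu_margin <- span
  lower <- c(0, 0, xr[1] - mu_margin, 0.05)
  upper <- c(0.05, 0.05, xr[2] + mu_margin, sigma_max)

  grid <- default_start_grid(counts)
  ll <- loglik_matrix(grid, counts)
  ord <- order(-ll, grid[, 4])
  starts <- grid[ord[seq_len(min(n_polish, nrow(grid)))], , drop = FALSE]

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(starts[i, ], psy_negloglik, gr = psy_negloglik_grad,
            counts = counts,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL
    )
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs) == 0) abort("psychometric fit failed from every start.")
  vals <- vapply(runs, function(r) r$value, numeric(1))
  sigmas <- vapply(runs, function(r) r$par[4], numeric(1))
  best <- runs[[order(vals, sigmas)[1]]]

  par <- best$par
  names(par) <- c("gamma", "lambda", "mu", "sigma")
  at_bound <- (abs(par - lower) < 1e-6) | (abs(par - upper) < 1e-6)
  # gamma/lambda at 0 is their natural resting point, not a pathology
  boundary <- unname(at_bound["sigma"] || at_bound["mu"])
  pse <- pse_cumgauss(par["mu"], par["sigma"], par["gamma"], par["lambda"])
  structure(
    list(
      gamma = unname(par["gamma"]), lambda = unname(par["lambda"]),
      mu = unname(par["mu"]), sigma = unname(par["sigma"]),
      pse = unname(pse),
      cov = if (pse > 0) unname(par["sigma"] / pse) else NA_real_,
      loglik = -best$value,
      counts = counts,
      n_trials = sum(counts$n_total),
      converged = best$convergence == 0,
      boundary = boundary,
      bounds = list(lower = lower, upper = upper),
      ci_pse = NULL, ci_cov = NULL
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE = %.3f, CoV = %.3f, sigma = %.3f, gamma = %.3f, lambda = %.3f\n  logLik = %.3f over %d trials%s%s\n",
    x$pse, x$cov, x$sigma, x$gamma, x$lambda, x$loglik, x$n_trials,
    if (x$converged) "" else " [not converged]",
    if (x$boundary) " [boundary]" else ""
  ))
  if (!is.null(x$ci_pse)) {
    cat(sprintf("  95%% bootstrap CI for PSE: [%.3f, %.3f]\n",
                x$ci_pse[1], x$ci_pse[2]))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for a psychometric fit
#'
#' Parametric bootstrap (the default): at each stimulus level the
#' chosen-counts are resampled from `Binomial(n_total, psi_fit(x))`, the
#' function is refitted, and percentile intervals of the resampled PSEs
#' (and CoVs) are taken. The nonparametric flavour resamples the
#' observed counts `Binomial(n_total, n_chosen / n_total)` instead.
#' Refits that fail are dropped and counted; a warning is attached when
#' more than 20% fail.
#'
#' @param fit A converged `psychometric_fit`.
#' @param b Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param type `"parametric"` or `"nonparametric"`.
#' @return The fit with `ci_pse`, `ci_cov`, `boot` (tibble of resampled
#'   estimates) and `n_failed` filled in.
#' @export
bootstrap_psychometric <- function(fit, b = 200L, level = 0.95, seed = 1L,
                                   type = c("parametric", "nonparametric")) {
  stopifnot(inherits(fit, "psychometric_fit"))
  type <- match.arg(type)
  counts <- fit$counts
  p_gen <- if (type == "parametric") {
    predict_psychometric(counts$x, fit$mu, fit$sigma, fit$gamma, fit$lambda)
  } else {
    counts$n_chosen / counts$n_total
  }
  start <- c(fit$gamma, fit$lambda, fit$mu, fit$sigma)
  lower <- fit$bounds$lower
  upper <- fit$bounds$upper
  res <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(b), function(i) {
      cts <- counts
      cts$n_chosen <- rbinom(nrow(cts), cts$n_total, p_gen)
      run <- tryCatch(
        optim(start, psy_negloglik, gr = psy_negloglik_grad, counts = cts,
              method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = 1e7, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(run)) return(c(NA_real_, NA_real_))
      p <- run$par
      ps <- pse_cumgauss(p[3], p[4], p[1], p[2])
      c(ps, if (ps > 0) p[4] / ps else NA_real_)
    })
  })
  mat <- do.call(rbind, res)
  ok <- is.finite(mat[, 1])
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * b) {
    warn(sprintf("%d of %d bootstrap refits failed.", n_failed, b))
  }
  alpha <- (1 - level) / 2
  fit$boot <- tibble(pse = mat[, 1], cov = mat[, 2])
  fit$ci_pse <- unname(stats::quantile(mat[ok, 1], c(alpha, 1 - alpha)))
  cov_ok <- is.finite(mat[, 2])
  fit$ci_cov <- if (any(cov_ok)) {
    unname(stats::quantile(mat[cov_ok, 2], c(alpha, 1 - alpha)))
  } else {
    c(NA_real_, NA_real_)
  }
  fit$n_failed <- n_failed
  fit
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble(
    term = c("gamma", "lambda", "mu", "sigma"),
    estimate = c(x$gamma, x$lambda, x$mu, x$sigma)
  )
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, PSE, CoV, bootstrap CI
#'   bounds (NA before [bootstrap_psychometric()]), log-likelihood,
#'   trial count and convergence flags.
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(
    gamma = x$gamma, lambda = x$lambda, mu = x$mu, sigma = x$sigma,
    pse = x$pse, cov = x$cov,
    pse_lo = if (is.null(x$ci_pse)) NA_real_ else x$ci_pse[1],
    pse_hi = if (is.null(x$ci_pse)) NA_real_ else x$ci_pse[2],
    loglik = x$loglik, n_trials = x$n_trials,
    converged = x$converged, boundary = x$boundary
  )
}

#' Plot a psychometric fit
#'
#' Observed proportion chosen per stimulus level with the fitted
#' cumulative-Gaussian curve and the PSE marked at the 50% level.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  counts <- object$counts
  counts$prop <- counts$n_chosen / counts$n_total
  grid <- tibble(x = seq(min(counts$x), max(counts$x), length.out = 200))
  grid$p <- predict_psychometric(grid$x, object$mu, object$sigma,
                                 object$gamma, object$lambda)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$x, y = .data$prop)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$pse, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(
      x = "test numerosity (items)",
      y = "proportion test chosen",
      title = sprintf("PSE = %.2f items, CoV = %.3f", object$pse, object$cov)
    ) +
    ggplot2::theme_minimal()
}

#' Fit psychometric functions per condition
#'
#' Splits a trial table by subject and condition (any of `subject`,
#' `n_ic`, `scheme`, `experiment` present in the data), fits each cell's
#' psychometric function over test numerosity, and returns one tidy row
#' per fit. Optionally attaches bootstrap CIs.
#'
#' @param trials A trial tibble from [simulate_experiment()] /
#'   [simulate_cohort()] or with the same columns.
#' @param bootstrap Attach 95% bootstrap CIs (slower)?
#' @param b,seed Bootstrap resamples and seed (used when `bootstrap`).
#' @return A tibble with the grouping columns plus
#'   [glance.psychometric_fit()]'s columns.
#' @export
fit_conditions <- function(trials, bootstrap = FALSE, b = 200L, seed = 1L) {
  keys <- intersect(c("experiment", "subject", "n_ic", "scheme"), names(trials))
  if (length(keys) == 0) abort("no condition columns found in `trials`.")
  nested <- trials |>
    group_by(across(dplyr::all_of(keys))) |>
    tidyr::nest() |>
    ungroup()
  seeds <- derive_seeds(seed, nrow(nested))
  fits <- purrr::map2(nested$data, seq_len(nrow(nested)), function(d, i) {
    f <- fit_psychometric(d)
    if (bootstrap) f <- bootstrap_psychometric(f, b = b, seed = seeds[i])
    glance(f)
  })
  dplyr::bind_cols(select(nested, -"data"), bind_rows(fits))
}
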