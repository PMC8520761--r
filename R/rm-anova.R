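# Orthonormal contrast rows spanning the (a-1)-dimensional effect space
# of a within factor with a levels.
orthonormal_contrasts <- function(a) {
  C <- stats::contr.helmert(a)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)
}

# Greenhouse-Geisser epsilon from the covariance of subject-level scores
# (one column per cell of the effect) projected onto orthonormal
# contrasts spanning the effect.
gg_epsilon <- function(scores, contrasts) {
  S <- stats::cov(scores)
  M <- contrasts %*% S %*% t(contrasts)
  q <- nrow(contrasts)
  if (sum(M^2) == 0) return(1)  # no within-effect variance: sphericity moot
  sum(diag(M))^2 / (q * sum(M^2))
}

# subject x level matrix of cell means; errors on unbalanced/missing data
subject_level_matrix <- function(data, dv, factors, subject) {
  f_list <- c(list(data[[subject]]), lapply(factors, function(f) data[[f]]))
  counts <- tapply(data[[dv]], f_list, length)
  if (any(is.na(counts))) {
    abort("design is incomplete: some subject x cell combinations are missing.")
  }
  cell_reps <- unique(as.vector(counts))
  if (length(cell_reps) != 1) {
    abort("design is unbalanced: unequal replicates per subject x cell.")
  }
  tapply(data[[dv]], f_list, mean)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate repeated-measures decomposition for one or two
#' within-subject factors on a complete balanced table of per-subject
#' measures (for example the fitted PSEs or CoVs of each subject and
#' condition). For each effect the error term is the subject-by-effect
#' interaction; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. The Greenhouse-Geisser epsilon
#' is always computed (from the covariance of the subject scores
#' projected onto the effect's orthonormal contrasts) and both the
#' uncorrected p value and the epsilon-corrected p value (on df
#' multiplied by epsilon) are reported; the corrected value is flagged
#' as primary when epsilon < 0.95. A factor with two levels has
#' epsilon = 1 exactly.
#'
#' @param data A data frame with one measure per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-factor columns.
#' @param subject Name of the subject-identifier column.
#' @return An `rm_anova_fit`; `tidy()` returns one row per effect with
#'   `ss`, `ss_error`, `df1`, `df2`, `statistic` (F), `epsilon`,
#'   `p.value`, `p.value_gg`, `pes` and `gg_primary`.
#' @export
#' @examples
#' pses <- tidyr::expand_grid(subject = 1:6, n_ic = c(0, 2, 4)) |>
#'   dplyr::mutate(pse = 12 + 0.3 * n_ic / 2 + stats::rnorm(18, 0, 0.4))
#' rm_anova(pses, dv = "pse", within = "n_ic")
rm_anova <- function(data, dv, within, subject = "subject") {
  if (!dv %in% names(data)) abort(sprintf("column `%s` not found.", dv))
  if (!subject %in% names(data)) abort(sprintf("column `%s` not found.", subject))
  if (!all(within %in% names(data))) abort("within factor column(s) not found.")
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors.")
  Y <- subject_level_matrix(data, dv, within, subject)
  n <- dim(Y)[1]
  if (n < 3) abort("need at least 3 subjects.")

  if (length(within) == 1) {
    a <- dim(Y)[2]
    grand <- mean(Y)
    am <- colMeans(Y)
    sm <- rowMeans(Y)
    ss_a <- n * sum((am - grand)^2)
    resid <- Y - outer(sm, rep(1, a)) - outer(rep(1, n), am) + grand
    ss_err <- sum(resid^2)
    eps <- gg_epsilon(Y, orthonormal_contrasts(a))
    effects <- anova_effect_row(within, ss_a, ss_err, a - 1, (a - 1) * (n - 1), eps)
  } else {
    a <- dim(Y)[2]; b <- dim(Y)[3]
    grand <- mean(Y)
    ZA <- apply(Y, c(1, 2), mean)
    ZB <- apply(Y, c(1, 3), mean)
    sm <- apply(Y, 1, mean)
    am <- colMeans(ZA)
    bm <- colMeans(ZB)
    cell <- apply(Y, c(2, 3), mean)

    ss_a <- n * b * sum((am - grand)^2)
    ss_b <- n * a * sum((bm - grand)^2)
    ss_ab <- n * sum((cell - outer(am, rep(1, b)) -
                        outer(rep(1, a), bm) + grand)^2)
    ss_s <- a * b * sum((sm - grand)^2)
    ss_as <- b * sum((ZA - outer(sm, rep(1, a)) - outer(rep(1, n), am) + grand)^2)
    ss_bs <- a * sum((ZB - outer(sm, rep(1, b)) - outer(rep(1, n), bm) + grand)^2)
    ss_tot <- sum((Y - grand)^2)
    ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

    CA <- orthonormal_contrasts(a)
    CB <- orthonormal_contrasts(b)
    W <- t(apply(Y, 1, function(m) as.vector(t(m))))  # col (j-1)*b + k
    eps_a <- gg_epsilon(ZA, CA)
    eps_b <- gg_epsilon(ZB, CB)
    eps_ab <- gg_epsilon(W, kronecker(CA, CB))

    effects <- bind_rows(
      anova_effect_row(within[1], ss_a, ss_as, a - 1, (a - 1) * (n - 1), eps_a),
      anova_effect_row(within[2], ss_b, ss_bs, b - 1, (b - 1) * (n - 1), eps_b),
      anova_effect_row(paste(within, collapse = ":"), ss_ab, ss_abs,
                       (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1), eps_ab)
    )
  }
  structure(
    list(effects = effects, n_subjects = n, dv = dv, within = within),
    class = "rm_anova_fit"
  )
}

anova_effect_row <- function(effect, ss, ss_err, df1, df2, eps) {
  ms <- ss / df1
  ms_err <- ss_err / df2
  Fv <- if (ms == 0) 0 else ms / ms_err  # a null effect is F = 0 even
  # when the error stratum is also degenerate
  tibble(
    effect = effect,
    ss = ss, ss_error = ss_err,
    df1 = df1, df2 = df2,
    statistic = Fv,
    epsilon = eps,
    p.value = pf(Fv, df1, df2, lower.tail = FALSE),
    p.value_gg = pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
    pes = ss / (ss + ss_err),
    gg_primary = eps < 0.95
  )
}

#' @export
print.rm_anova_fit <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on `%s` (%d subjects)\n",
              x$dv, x$n_subjects))
  df <- x$effects
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-16s F(%g, %g) = %.3f, eps = %.3f, p = %.4g (GG p = %.4g)%s, pes = %.3f\n",
      df$effect[i], df$df1[i], df$df2[i], df$statistic[i], df$epsilon[i],
      df$p.value[i], df$p.value_gg[i],
      if (df$gg_primary[i]) " [GG primary]" else "", df$pes[i]
    ))
  }
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova_fit`.
#' @param ... Unused.
#' @export
tidy.rm_anova_fit <- function(x, ...) {
  x$effects
}

#' @rdname rm_anova
#' @export
glance.rm_anova_fit <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_effects = nrow(x$effects),
         dv = x$dv)
}
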