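# One-way pooled error term: MS and df of the subject-by-factor
# interaction, after collapsing over any other factors.
pooled_error <- function(Y) {
  n <- nrow(Y); a <- ncol(Y)
  grand <- mean(Y)
  resid <- Y - outer(rowMeans(Y), rep(1, a)) -
    outer(rep(1, n), colMeans(Y)) + grand
  df <- (a - 1) * (n - 1)
  list(ms = sum(resid^2) / df, df = df)
}

level_order <- function(x) {
  lv <- unique(x)
  num <- suppressWarnings(as.numeric(as.character(lv)))
  if (!anyNA(num)) lv[order(num)] else sort(lv)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All pairwise paired comparisons between the levels of a within
#' factor, on per-subject means collapsed over any other factors. With
#' the default pooled error term, every comparison uses the
#' subject-by-factor interaction mean square and its degrees of freedom
#' (the shared-df reporting style, for example t(54) with 28 subjects
#' and 3 levels); `error = "pairwise"` instead runs ordinary paired t
#' tests per pair (df = n - 1). Raw p values are multiplied by the
#' number of comparisons and capped at 1.
#'
#' @param data Per-subject measures (one or more rows per subject x
#'   level; extra factors are averaged out).
#' @param dv Dependent-variable column name.
#' @param factor Within-factor column name (at least 2 levels).
#' @param subject Subject-identifier column name.
#' @param error `"pooled"` or `"pairwise"` error term.
#' @return A tibble with one row per pair: `pair`, `estimate` (first
#'   minus second level mean), `statistic` (t), `df`, `p.value` (raw)
#'   and `p.value_adj` (Bonferroni).
#' @export
bonferroni_posthoc <- function(data, dv, factor, subject = "subject",
                               error = c("pooled", "pairwise")) {
  error <- match.arg(error)
  Y <- subject_level_matrix(data, dv, factor, subject)
  lv <- level_order(data[[factor]])
  Y <- Y[, as.character(lv), drop = FALSE]
  n <- nrow(Y); a <- ncol(Y)
  if (a < 2) abort("need at least 2 factor levels.")
  if (n < 2) abort("need at least 2 subjects.")
  pairs <- utils::combn(a, 2)
  n_pairs <- ncol(pairs)
  pe <- pooled_error(Y)
  rows <- lapply(seq_len(n_pairs), function(c) {
    j <- pairs[1, c]; k <- pairs[2, c]
    est <- mean(Y[, j]) - mean(Y[, k])
    if (error == "pooled") {
      se <- sqrt(2 * pe$ms / n)
      df <- pe$df
    } else {
      d <- Y[, j] - Y[, k]
      se <- sd(d) / sqrt(n)
      df <- n - 1
    }
    tstat <- if (se == 0) 0 else est / se
    p <- 2 * pt(-abs(tstat), df)
    tibble(
      pair = sprintf("%s vs %s", lv[j], lv[k]),
      estimate = est, statistic = tstat, df = df,
      p.value = p, p.value_adj = min(1, p * n_pairs)
    )
  })
  bind_rows(rows)
}

#' Polynomial trend contrasts over an ordered three-level factor
#'
#' Linear (-1, 0, +1) and quadratic (1, -2, 1) contrasts over the three
#' equally spaced ordered levels of a within factor (for example the
#' 0/2/4 illusory-contour levels). With the default pooled error term
#' the contrast is tested against the subject-by-factor interaction
#' mean square (matching the shared-df t reported alongside the
#' repeated-measures ANOVA); `error = "per_subject"` computes a
#' contrast score per subject and runs a one-sample t against 0
#' (df = n - 1).
#'
#' @inheritParams bonferroni_posthoc
#' @param error `"pooled"` or `"per_subject"`.
#' @return A tibble with one row per contrast: `contrast`, `estimate`,
#'   `statistic` (t), `df`, `p.value`.
#' @export
linear_trend <- function(data, dv, factor, subject = "subject",
                         error = c("pooled", "per_subject")) {
  error <- match.arg(error)
  Y <- subject_level_matrix(data, dv, factor, subject)
  lv <- level_order(data[[factor]])
  if (length(lv) != 3) abort("trend contrasts require exactly 3 levels.")
  num <- suppressWarnings(as.numeric(as.character(lv)))
  if (!anyNA(num) && abs(diff(diff(num))) > 1e-9) {
    abort("trend contrasts require equally spaced levels.")
  }
  Y <- Y[, as.character(lv), drop = FALSE]
  n <- nrow(Y)
  weights <- list(linear = c(-1, 0, 1), quadratic = c(1, -2, 1))
  pe <- pooled_error(Y)
  rows <- lapply(names(weights), function(nm) {
    w <- weights[[nm]]
    est <- sum(w * colMeans(Y))
    if (error == "pooled") {
      se <- sqrt(pe$ms * sum(w^2) / n)
      df <- pe$df
    } else {
      scores <- as.vector(Y %*% w)
      se <- sd(scores) / sqrt(n)
      df <- n - 1
    }
    tstat <- if (se == 0) 0 else est / se
    tibble(contrast = nm, estimate = est, statistic = tstat, df = df,
           p.value = 2 * pt(-abs(tstat), df))
  })
  bind_rows(rows)
}
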