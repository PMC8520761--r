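rm_table <- function(Y, factor_name = "k") {
  n <- nrow(Y); a <- ncol(Y)
  out <- tidyr::expand_grid(subject = seq_len(n), lev = seq_len(a))
  out[[factor_name]] <- c(0, 2, 4, 6, 8)[out$lev]
  out$value <- Y[cbind(out$subject, out$lev)]
  out$lev <- NULL
  out
}

test_that("one-way RM-ANOVA matches the from-scratch decomposition oracle", {
  for (seed in c(1, 2, 3)) {
    Y <- withr::with_seed(seed, matrix(rnorm(6 * 3, mean = 12), 6, 3))
    res <- tidy(rm_anova(rm_table(Y), dv = "value", within = "k"))
    o <- oracle_rm_anova_oneway(Y)
    expect_equal(res$ss, o$ss_effect, tolerance = 1e-10)
    expect_equal(res$ss_error, o$ss_error, tolerance = 1e-10)
    expect_equal(res$statistic, o$F, tolerance = 1e-10)
    expect_equal(res$epsilon, o$epsilon, tolerance = 1e-10)
    expect_equal(res$pes, o$pes, tolerance = 1e-10)
    expect_equal(res$p.value, o$p, tolerance = 1e-10)
    expect_equal(res$df1, 2)
    expect_equal(res$df2, 10)
  }
})

test_that("two-way RM-ANOVA agrees with aov() error strata", {
  tab <- withr::with_seed(4, {
    tidyr::expand_grid(subject = factor(1:8), A = factor(c("a", "b", "c")),
                       B = factor(c("x", "y"))) |>
      dplyr::mutate(value = rnorm(48, mean = 10))
  })
  res <- tidy(rm_anova(tab, dv = "value", within = c("A", "B")))
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = tab)
  s <- summary(fit)
  f_aov <- c(
    s[["Error: subject:A"]][[1]]["A", "F value"],
    s[["Error: subject:B"]][[1]]["B", "F value"],
    s[["Error: subject:A:B"]][[1]]["A:B", "F value"]
  )
  p_aov <- c(
    s[["Error: subject:A"]][[1]]["A", "Pr(>F)"],
    s[["Error: subject:B"]][[1]]["B", "Pr(>F)"],
    s[["Error: subject:A:B"]][[1]]["A:B", "Pr(>F)"]
  )
  expect_equal(res$statistic, f_aov, tolerance = 1e-8)
  expect_equal(res$p.value, p_aov, tolerance = 1e-8)
  expect_equal(res$df1, c(2, 1, 2))
  expect_equal(res$df2, c(14, 7, 14))
  # two-level factor: sphericity trivially holds
  expect_equal(res$epsilon[2], 1)
  # epsilon is invariant to the contrast basis spanning the effect
  Y <- icnum:::subject_level_matrix(tab, "value", "A", "subject")
  C_poly <- t(stats::contr.poly(3))
  expect_equal(
    icnum:::gg_epsilon(Y, icnum:::orthonormal_contrasts(3)),
    icnum:::gg_epsilon(Y, C_poly),
    tolerance = 1e-10
  )
})

test_that("null and degenerate structures produce F = 0 and epsilon = 1", {
  # identical values across levels plus subject offsets -> F = 0
  # (integer offsets keep the zero sums of squares exact)
  Y <- matrix(rep(c(9, 11, 12, 13, 14, 16), 3), 6, 3)
  res <- tidy(rm_anova(rm_table(Y), dv = "value", within = "k"))
  expect_equal(res$statistic, 0)
  # epsilon bounds: 1/(a-1) <= eps <= 1
  Y2 <- withr::with_seed(8, matrix(rnorm(18), 6, 3))
  eps <- tidy(rm_anova(rm_table(Y2), dv = "value", within = "k"))$epsilon
  expect_gte(eps, 0.5)
  expect_lte(eps, 1)
})

test_that("RM-ANOVA statistics are invariant to relabeling, shift and scale", {
  Y <- withr::with_seed(11, matrix(rnorm(21, 12), 7, 3))
  base <- tidy(rm_anova(rm_table(Y), dv = "value", within = "k"))
  perm <- withr::with_seed(12, sample(7))
  res_p <- tidy(rm_anova(rm_table(Y[perm, ]), dv = "value", within = "k"))
  expect_equal(res_p$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(res_p$epsilon, base$epsilon, tolerance = 1e-12)
  res_s <- tidy(rm_anova(rm_table(Y + 100), dv = "value", within = "k"))
  expect_equal(res_s$statistic, base$statistic, tolerance = 1e-9)
  expect_equal(res_s$epsilon, base$epsilon, tolerance = 1e-9)
  res_c <- tidy(rm_anova(rm_table(Y * 3.7), dv = "value", within = "k"))
  expect_equal(res_c$statistic, base$statistic, tolerance = 1e-9)
  expect_equal(res_c$epsilon, base$epsilon, tolerance = 1e-9)
  expect_equal(res_c$pes, base$pes, tolerance = 1e-9)
})

test_that("unbalanced or incomplete tables are rejected", {
  tab <- rm_table(matrix(rnorm(18), 6, 3))
  expect_error(rm_anova(tab[-1, ], dv = "value", within = "k"), "missing")
  expect_error(rm_anova(dplyr::bind_rows(tab, tab[1, ]), dv = "value",
                        within = "k"), "unbalanced")
  expect_error(rm_anova(tab[tab$subject < 3, ], dv = "value", within = "k"),
               "3 subjects")
})

test_that("Bonferroni post hocs match direct paired-t formulas", {
  Y <- withr::with_seed(21, matrix(rnorm(24, 12), 8, 3))
  tab <- rm_table(Y)
  ph <- bonferroni_posthoc(tab, dv = "value", factor = "k", error = "pairwise")
  expect_equal(nrow(ph), 3)
  # direct formula for the first pair (levels 0 vs 2)
  d <- Y[, 1] - Y[, 2]
  t_direct <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(ph$statistic[1], t_direct, tolerance = 1e-12)
  expect_equal(ph$df[1], 7)
  expect_equal(ph$p.value_adj, pmin(1, ph$p.value * 3))
  # pooled error term: shared df = (a-1)(n-1), t from the ANOVA MS_error
  php <- bonferroni_posthoc(tab, dv = "value", factor = "k", error = "pooled")
  expect_true(all(php$df == 14))
  o <- oracle_rm_anova_oneway(Y)
  ms_err <- o$ss_error / 14
  t_pooled <- (mean(Y[, 1]) - mean(Y[, 2])) / sqrt(2 * ms_err / 8)
  expect_equal(php$statistic[1], t_pooled, tolerance = 1e-12)
  # identical samples: t = 0, adjusted p = 1
  Yc <- matrix(rep(rnorm(8), 3), 8, 3)
  ph0 <- bonferroni_posthoc(rm_table(Yc), dv = "value", factor = "k",
                            error = "pairwise")
  expect_true(all(ph0$statistic == 0))
  expect_true(all(ph0$p.value_adj == 1))
})

test_that("trend contrasts isolate linear and quadratic structure", {
  # exact arithmetic progression per subject (dyadic values, so the
  # contrast scores vanish identically in floating point)
  a <- seq(10, 12.5, by = 0.5); d <- 0.5
  Y <- cbind(a, a + d, a + 2 * d)
  tr <- linear_trend(rm_table(Y), dv = "value", factor = "k",
                     error = "per_subject")
  expect_equal(tr$statistic[tr$contrast == "quadratic"], 0, tolerance = 1e-9)
  expect_equal(tr$estimate[tr$contrast == "linear"], 2 * d, tolerance = 1e-12)
  # noisy table whose column means are an exact progression: pooled-error
  # quadratic t is exactly 0 while the linear t is finite and positive
  Yn <- withr::with_seed(41, matrix(rnorm(18, 12), 6, 3))
  Yn <- sweep(Yn, 2, colMeans(Yn)) + matrix(rep(12 + d * (0:2), each = 6), 6, 3)
  trn <- linear_trend(rm_table(Yn), dv = "value", factor = "k")
  expect_equal(trn$statistic[trn$contrast == "quadratic"], 0, tolerance = 1e-9)
  expect_gt(trn$statistic[trn$contrast == "linear"], 0)
  # flat data -> linear t = 0
  Yf <- cbind(a, a, a)
  trf <- linear_trend(rm_table(Yf), dv = "value", factor = "k")
  expect_equal(trf$statistic, c(0, 0))
  # per-subject error: linear contrast equals the paired t of level3 - level1
  Yr <- withr::with_seed(31, matrix(rnorm(18, 12), 6, 3))
  trr <- linear_trend(rm_table(Yr), dv = "value", factor = "k",
                      error = "per_subject")
  tt <- stats::t.test(Yr[, 3] - Yr[, 1])
  expect_equal(trr$statistic[trr$contrast == "linear"],
               unname(tt$statistic), tolerance = 1e-12)
  expect_equal(trr$p.value[trr$contrast == "linear"], tt$p.value,
               tolerance = 1e-12)
  # pooled error reproduces the post hoc equivalence t_trend = -t(0 vs 4)
  trp <- linear_trend(rm_table(Yr), dv = "value", factor = "k")
  php <- bonferroni_posthoc(rm_table(Yr), dv = "value", factor = "k")
  expect_equal(trp$statistic[trp$contrast == "linear"],
               -php$statistic[php$pair == "0 vs 4"], tolerance = 1e-12)
  expect_error(linear_trend(rm_table(Yr)[rm_table(Yr)$k < 4, ],
                            dv = "value", factor = "k"), "3 levels")
})
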