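# Independent oracles used across the suite. These deliberately re-derive
# quantities through different routes than the package internals.

# Brute-force alignment oracle: for every unordered pair, test with plain
# vector algebra (unit notch vectors, dot products, acos) whether both
# notches open towards each other within tol degrees at distance <= dmax.
oracle_aligned_pairs <- function(pattern, tol = 10, dmax = 40) {
  ind <- pattern$inducers
  n <- nrow(ind)
  hits <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, length.out = n - i)) {
      v <- c(ind$x[j] - ind$x[i], ind$y[j] - ind$y[i])
      d <- sqrt(sum(v^2))
      if (d > dmax) next
      u <- v / d
      ui <- c(cos(ind$orientation[i] * pi / 180),
              sin(ind$orientation[i] * pi / 180))
      uj <- c(cos(ind$orientation[j] * pi / 180),
              sin(ind$orientation[j] * pi / 180))
      ang_i <- acos(pmin(pmax(sum(ui * u), -1), 1)) * 180 / pi
      ang_j <- acos(pmin(pmax(sum(uj * -u), -1), 1)) * 180 / pi
      if (ang_i <= tol && ang_j <= tol) hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (length(hits) == 0) matrix(integer(0), ncol = 2) else do.call(rbind, hits)
}

# All pairwise centre distances (exhaustive, no dist())
oracle_pairwise_distances <- function(pattern) {
  ind <- pattern$inducers
  n <- nrow(ind)
  out <- numeric(0)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, length.out = n - i)) {
      out <- c(out, sqrt((ind$x[i] - ind$x[j])^2 + (ind$y[i] - ind$y[j])^2))
    }
  }
  out
}

# O(n^3) convex hull area: a point pair is a hull edge iff all other
# points lie on one side of its line; assemble the hull polygon and
# take the shoelace area.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      nx <- -(pts[j, 2] - pts[i, 2])
      ny <- pts[j, 1] - pts[i, 1]
      s <- (pts[, 1] - pts[i, 1]) * nx + (pts[, 2] - pts[i, 2]) * ny
      if (all(s <= 1e-9) || all(s >= -1e-9)) {
        edges[[length(edges) + 1]] <- c(i, j)
      }
    }
  }
  verts <- unique(unlist(edges))
  hp <- pts[verts, , drop = FALSE]
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Grid-search MLE oracle: exhaustive lattice over (gamma, lambda, mu,
# sigma), repeatedly refined around the incumbent until the lattice
# pitch makes the quadratic loglik error negligible. The (mu, sigma)
# sheet is evaluated vectorised for each (gamma, lambda) lattice point.
oracle_grid_mle <- function(counts, n_points = 30, stages = 5) {
  hard <- list(
    gamma = c(0, 0.05), lambda = c(0, 0.05),
    mu = range(counts$x) + c(-1, 1) * max(diff(range(counts$x)), 1),
    sigma = c(0.05, 30)
  )
  lims <- hard
  best <- rep(NA_real_, 4); best_ll <- -Inf
  nc <- counts$n_chosen; nt <- counts$n_total; x <- counts$x
  for (stage in seq_len(stages)) {
    gs <- lapply(lims, function(r) seq(r[1], r[2], length.out = n_points))
    ms_grid <- expand.grid(m = gs$mu, s = gs$sigma)
    z <- outer(seq_len(nrow(ms_grid)), seq_along(x),
               function(i, j) (x[j] - ms_grid$m[i]) / ms_grid$s[i])
    Phi <- pnorm(z)
    for (g in gs$gamma) {
      for (l in gs$lambda) {
        p <- g + (1 - g - l) * Phi
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        ll <- as.vector(log(p) %*% nc + log(1 - p) %*% (nt - nc))
        k <- which.max(ll)
        if (ll[k] > best_ll) {
          best_ll <- ll[k]
          best <- c(g, l, ms_grid$m[k], ms_grid$s[k])
        }
      }
    }
    # shrink each axis to +/- 2 lattice steps around the incumbent
    width <- vapply(lims, function(r) diff(r), numeric(1)) / (n_points - 1) * 2
    lims <- lapply(1:4, function(d) {
      c(max(hard[[d]][1], best[d] - width[d]),
        min(hard[[d]][2], best[d] + width[d]))
    })
    names(lims) <- names(hard)
  }
  # coordinate-wise lattice polish: per-axis fine grids (full hard range
  # for the tiny gamma/lambda axes, local for mu/sigma) iterated until
  # the lattice stops improving; frees boundary-attracted parameters
  # that the shrinking box can strand mid-range.
  ll_at <- function(par) {
    p <- par[1] + (1 - par[1] - par[2]) * pnorm((x - par[3]) / par[4])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(nc * log(p) + (nt - nc) * log(1 - p))
  }
  for (cycle in 1:20) {
    improved <- FALSE
    for (d in 1:4) {
      axis <- if (d <= 2) {
        seq(hard[[d]][1], hard[[d]][2], length.out = 2001)
      } else {
        seq(max(hard[[d]][1], best[d] - 0.5),
            min(hard[[d]][2], best[d] + 0.5), length.out = 2001)
      }
      lls <- vapply(axis, function(v) {
        par <- best; par[d] <- v; ll_at(par)
      }, numeric(1))
      k <- which.max(lls)
      if (lls[k] > best_ll + 1e-12) {
        best_ll <- lls[k]
        best[d] <- axis[k]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(loglik = best_ll, par = best)
}

# From-scratch one-way RM-ANOVA oracle with plain loops, plus the
# classic Box formula for the Greenhouse-Geisser epsilon.
oracle_rm_anova_oneway <- function(Y) {
  n <- nrow(Y); a <- ncol(Y)
  grand <- mean(Y)
  ss_a <- 0
  for (j in 1:a) ss_a <- ss_a + n * (mean(Y[, j]) - grand)^2
  ss_err <- 0
  for (i in 1:n) {
    for (j in 1:a) {
      ss_err <- ss_err +
        (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + grand)^2
    }
  }
  S <- cov(Y)
  sbar <- mean(S)
  row_means <- rowMeans(S)
  eps <- (a * (mean(diag(S)) - sbar))^2 /
    ((a - 1) * (sum(S^2) - 2 * a * sum(row_means^2) + a^2 * sbar^2))
  Fv <- (ss_a / (a - 1)) / (ss_err / ((a - 1) * (n - 1)))
  list(ss_effect = ss_a, ss_error = ss_err, F = Fv, epsilon = eps,
       pes = ss_a / (ss_a + ss_err),
       p = pf(Fv, a - 1, (a - 1) * (n - 1), lower.tail = FALSE))
}

# simulated 2AFC counts for a known psychometric function
make_counts <- function(mu, sigma, gamma = 0, lambda = 0,
                        x = 9:15, n_total = 16, seed = 1) {
  withr::with_seed(seed, {
    p <- gamma + (1 - gamma - lambda) * pnorm((x - mu) / sigma)
    tibble::tibble(x = x, n_chosen = rbinom(length(x), n_total, p),
                   n_total = n_total)
  })
}

# minimal hand-built pattern for edge-case tests
make_manual_pattern <- function(xs, ys, orientations,
                                polarity = -1, closed = FALSE,
                                ic_pairs = NULL, planted_pairs = NULL) {
  ind <- tibble::tibble(
    x = xs, y = ys, diameter = 20, notch_width = 4, notch_length = 10,
    orientation = orientations, polarity = polarity, closed = closed
  )
  icnum:::new_stimulus_pattern(
    ind, ic_pairs = ic_pairs, planted_pairs = planted_pairs,
    role = "test", base_id = "manual", color_scheme = "all_black"
  )
}
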