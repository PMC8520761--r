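#' Geometry of a stimulus panel
#'
#' Bundles the spatial constraints used when scattering Pac-Man inducers
#' over a square panel. The defaults reproduce the construction used for
#' the dot-array discrimination experiments this package models: a
#' 240 x 240 px panel, 20 px-diameter inducers with a 4 x 10 px notch,
#' a minimum centre-to-centre distance of 22 px, a 20 px margin from the
#' panel edges, and candidate illusory-contour pair distances of
#' 22, 25, 28 or 31 px.
#'
#' The alignment predicate used throughout (two inducers "face" each
#' other and would complete an illusory contour) requires their centre
#' distance to be at most `align_dmax` and both notch axes to lie within
#' `align_tol` degrees of the line joining the centres, each opening
#' towards the other.
#'
#' @param panel_size Side of the square panel, px.
#' @param margin Minimum distance from an inducer centre to any panel
#'   edge, px.
#' @param min_dist Minimum centre-to-centre distance between any two
#'   inducers, px.
#' @param pair_distances Candidate centre-to-centre distances for planted
#'   illusory-contour pairs, px.
#' @param diameter,notch_width,notch_length Inducer disc diameter, notch
#'   width, and notch length from the centre, px.
#' @param align_tol Angular tolerance of the alignment predicate, degrees.
#' @param align_dmax Maximum centre distance at which two facing inducers
#'   count as aligned, px.
#' @param n_planted_pairs Disjoint candidate pairs planted in every base
#'   pattern so that 2- and 4-contour clones can be carved from it.
#' @param max_proposals,max_restarts Rejection-sampling budgets: point
#'   proposals per item and full restarts per pattern.
#' @return A list of class `pattern_geometry`.
#' @export
#' @examples
#' pattern_geometry()
pattern_geometry <- function(panel_size = 240,
                             margin = 20,
                             min_dist = 22,
                             pair_distances = c(22, 25, 28, 31),
                             diameter = 20,
                             notch_width = 4,
                             notch_length = 10,
                             align_tol = 10,
                             align_dmax = 40,
                             n_planted_pairs = 4,
                             max_proposals = 10000,
                             max_restarts = 100) {
  assert_number(panel_size, "panel_size", lower = 1)
  assert_number(margin, "margin", lower = 0)
  assert_number(min_dist, "min_dist", lower = 0)
  assert_number(diameter, "diameter", lower = 1e-9)
  assert_number(notch_width, "notch_width", lower = 1e-9)
  assert_number(notch_length, "notch_length", lower = 1e-9, upper = diameter / 2)
  geom <- list(
    panel_size = panel_size, margin = margin, min_dist = min_dist,
    pair_distances = pair_distances, diameter = diameter,
    notch_width = notch_width, notch_length = notch_length,
    align_tol = align_tol, align_dmax = align_dmax,
    n_planted_pairs = as.integer(n_planted_pairs),
    max_proposals = as.integer(max_proposals),
    max_restarts = as.integer(max_restarts)
  )
  structure(geom, class = "pattern_geometry")
}

new_stimulus_pattern <- function(inducers, ic_pairs, planted_pairs,
                                 role, base_id, color_scheme,
                                 geometry = pattern_geometry()) {
  stopifnot(is.data.frame(inducers))
  structure(
    list(
      inducers = as_tibble(inducers),
      n = nrow(inducers),
      ic_pairs = as_pair_matrix(ic_pairs),
      planted_pairs = as_pair_matrix(planted_pairs),
      role = role,
      base_id = base_id,
      color_scheme = color_scheme,
      geometry = geometry
    ),
    class = "stimulus_pattern"
  )
}

as_pair_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  m <- matrix(as.integer(x), ncol = 2)
  colnames(m) <- c("i", "j")
  m
}

#' @export
print.stimulus_pattern <- function(x, ...) {
  cat(sprintf(
    "<stimulus_pattern> N = %d (%s), %d aligned pair(s), %d planted pair(s), scheme = %s\n",
    x$n, x$role, nrow(x$ic_pairs), nrow(x$planted_pairs), x$color_scheme
  ))
  print(x$inducers, n = 4)
  invisible(x)
}

#' Tidy an inducer pattern into a tibble
#'
#' Returns one row per inducer with its geometry, polarity and (when the
#' inducer belongs to an aligned illusory-contour pair) the pair index.
#'
#' @param x A `stimulus_pattern`.
#' @param ... Unused.
#' @return A tibble with one row per inducer.
#' @export
tidy.stimulus_pattern <- function(x, ...) {
  out <- x$inducers
  out$inducer <- seq_len(nrow(out))
  out$ic_pair <- NA_integer_
  if (nrow(x$ic_pairs) > 0) {
    for (p in seq_len(nrow(x$ic_pairs))) {
      out$ic_pair[x$ic_pairs[p, ]] <- p
    }
  }
  select(out, "inducer", "x", "y", "diameter", "notch_width", "notch_length",
         "orientation", "polarity", "closed", "ic_pair")
}

# ---- alignment predicate ---------------------------------------------------

# Do inducers i and j face each other along the joining line?
# Vectorised over equal-length i, j index vectors.
faces_each_other <- function(inducers, i, j, geometry) {
  dx <- inducers$x[j] - inducers$x[i]
  dy <- inducers$y[j] - inducers$y[i]
  d <- sqrt(dx^2 + dy^2)
  phi <- norm_deg(atan2(dy, dx) * 180 / pi)
  ok_d <- d <= geometry$align_dmax
  ok_i <- ang_diff(inducers$orientation[i], phi) <= geometry$align_tol
  ok_j <- ang_diff(inducers$orientation[j], phi + 180) <= geometry$align_tol
  ok_d & ok_i & ok_j
}

# All pairs (i < j) passing the alignment predicate; exhaustive over C(N, 2).
aligned_pairs <- function(inducers, geometry) {
  n <- nrow(inducers)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- utils::combn(n, 2)
  hit <- faces_each_other(inducers, idx[1, ], idx[2, ], geometry)
  as_pair_matrix(t(idx[, hit, drop = FALSE]))
}

pair_distances_of <- function(inducers, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  sqrt((inducers$x[pairs[, 1]] - inducers$x[pairs[, 2]])^2 +
         (inducers$y[pairs[, 1]] - inducers$y[pairs[, 2]])^2)
}

canonical_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  m <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

same_pair_set <- function(a, b) {
  a <- canonical_pairs(as_pair_matrix(a))
  b <- canonical_pairs(as_pair_matrix(b))
  nrow(a) == nrow(b) && all(a == b)
}

# ---- validation ------------------------------------------------------------

#' Audit a stimulus pattern against its construction constraints
#'
#' Exhaustively checks the spatial and alignment invariants of a pattern:
#' minimum centre-to-centre distance, edge margin, planted-pair distances
#' drawn from the allowed set, and exact agreement between the pairs that
#' pass the alignment predicate and the pattern's declared
#' illusory-contour roster (a zero-contour pattern must contain no
#' accidentally aligned pair).
#'
#' @param pattern A `stimulus_pattern`.
#' @param tol Numeric slack (px) on the distance comparisons.
#' @return A tibble of violations with columns `check` and `detail`;
#'   zero rows means the pattern is valid.
#' @export
validate_pattern <- function(pattern, tol = 1e-9) {
  g <- pattern$geometry
  ind <- pattern$inducers
  out <- list()
  bad <- function(check, detail) tibble(check = check, detail = detail)

  if (nrow(ind) != pattern$n) {
    out <- c(out, list(bad("count", sprintf(
      "pattern declares N = %d but holds %d inducers", pattern$n, nrow(ind)))))
  }
  if (any(ind$notch_length > ind$diameter / 2 + tol)) {
    out <- c(out, list(bad("notch", "notch_length exceeds radius")))
  }
  if (any(ind$orientation < 0 | ind$orientation >= 360)) {
    out <- c(out, list(bad("orientation", "orientation outside [0, 360)")))
  }
  if (any(!ind$polarity %in% c(-1, 1))) {
    out <- c(out, list(bad("polarity", "polarity not in {-1, +1}")))
  }

  # margin: centre-to-edge
  off <- ind$x < g$margin - tol | ind$x > g$panel_size - g$margin + tol |
    ind$y < g$margin - tol | ind$y > g$panel_size - g$margin + tol
  if (any(off)) {
    out <- c(out, list(bad("margin", sprintf(
      "%d inducer(s) closer than %g px to a panel edge", sum(off), g$margin))))
  }

  # exhaustive min-distance check over all C(N, 2) pairs
  if (nrow(ind) >= 2) {
    dmat <- as.matrix(stats::dist(cbind(ind$x, ind$y)))
    dmin <- min(dmat[upper.tri(dmat)])
    if (dmin < g$min_dist - tol) {
      out <- c(out, list(bad("min_distance", sprintf(
        "minimum centre distance %.3f px < %g px", dmin, g$min_dist))))
    }
  }

  # planted pair distances must come from the allowed set
  pd <- pair_distances_of(ind, pattern$planted_pairs)
  if (length(pd) > 0) {
    ok <- vapply(pd, function(d) any(abs(d - g$pair_distances) <= 1e-6 + tol),
                 logical(1))
    if (!all(ok)) {
      out <- c(out, list(bad("planted_distance", sprintf(
        "planted pair distance(s) %s not in {%s}",
        paste(round(pd[!ok], 3), collapse = ", "),
        paste(g$pair_distances, collapse = ", ")))))
    }
  }

  # index sanity for rosters
  all_idx <- c(pattern$ic_pairs, pattern$planted_pairs)
  if (length(all_idx) > 0 && (any(all_idx < 1) || any(all_idx > pattern$n))) {
    out <- c(out, list(bad("pair_index", "pair roster indexes outside 1..N")))
  }
  if (nrow(pattern$ic_pairs) > 0 &&
      anyDuplicated(as.vector(pattern$ic_pairs)) > 0) {
    out <- c(out, list(bad("pair_index", "aligned pairs share an inducer")))
  }

  # aligned pairs found by brute force must equal the declared roster.
  # Closed inducers cannot complete an illusory contour, but the roster is
  # retained for condition bookkeeping, so the geometric predicate is
  # still what is checked.
  found <- aligned_pairs(ind, g)
  if (!same_pair_set(found, pattern$ic_pairs)) {
    out <- c(out, list(bad("alignment", sprintf(
      "%d pair(s) pass the alignment predicate but %d are declared",
      nrow(found), nrow(pattern$ic_pairs)))))
  }

  if (length(out) == 0) {
    tibble(check = character(0), detail = character(0))
  } else {
    bind_rows(out)
  }
}
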