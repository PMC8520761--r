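#' Generate a zero-contour base pattern of Pac-Man inducers
#'
#' Scatters `n` Pac-Man inducers over the panel by rejection sampling.
#' Four disjoint candidate pairs are planted first at centre-to-centre
#' distances drawn from the allowed set (22, 25, 28 or 31 px by
#' default), so that the same base supports the two- and four-contour
#' clones produced by [clone_with_ics()]; the remaining items are placed
#' uniformly. All inducers respect the minimum centre distance and the
#' edge margin. Orientations are drawn uniformly over 360 degrees and
#' re-drawn until no two inducers face each other — in the base pattern
#' and in every clone configuration — so a pattern never contains an
#' accidental illusory contour.
#'
#' @param n Number of inducers (9-15 for test patterns, 12 for
#'   reference patterns). Must be at least twice the number of planted
#'   pairs.
#' @param role `"test"` or `"reference"`. Reference patterns are built
#'   under the same spatial constraints as test patterns.
#' @param seed Integer seed; the same seed always yields the same
#'   pattern.
#' @param geometry A [pattern_geometry()].
#' @return A `stimulus_pattern` with zero aligned pairs and
#'   `geometry$n_planted_pairs` planted candidate pairs. All inducers
#'   are black (`polarity = -1`) and open; recolour with
#'   [assign_polarity()].
#' @export
#' @examples
#' p <- generate_base_pattern(12, "test", seed = 1)
#' nrow(validate_pattern(p))  # 0
generate_base_pattern <- function(n, role = c("test", "reference"),
                                  seed = 1L,
                                  geometry = pattern_geometry()) {
  role <- match.arg(role)
  g <- geometry
  n <- as.integer(n)
  if (n < 2L * g$n_planted_pairs) {
    abort(sprintf(
      "n = %d cannot host %d planted pairs (need n >= %d).",
      n, g$n_planted_pairs, 2L * g$n_planted_pairs
    ))
  }
  withr::with_seed(as.integer(seed), {
    for (restart in seq_len(g$max_restarts)) {
      placed <- place_centers(n, g)
      if (is.null(placed)) next
      ori <- resolve_orientations(placed$centers, placed$pairs, g)
      if (is.null(ori)) next
      inducers <- tibble(
        x = placed$centers[, 1], y = placed$centers[, 2],
        diameter = g$diameter, notch_width = g$notch_width,
        notch_length = g$notch_length,
        orientation = ori,
        polarity = -1, closed = FALSE
      )
      return(new_stimulus_pattern(
        inducers,
        ic_pairs = NULL, planted_pairs = placed$pairs,
        role = role,
        base_id = sprintf("%s-N%02d-s%d", role, n, as.integer(seed)),
        color_scheme = "all_black", geometry = g
      ))
    }
  })
  abort(sprintf(
    "pattern generation failed after %d restarts (n = %d, seed = %d).",
    g$max_restarts, n, as.integer(seed)
  ))
}

# Propose centres: planted pairs first, then free items. NULL on failure.
place_centers <- function(n, g) {
  lo <- g$margin
  hi <- g$panel_size - g$margin
  centers <- matrix(numeric(0), ncol = 2)
  ok_dist <- function(p) {
    nrow(centers) == 0 ||
      min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >= g$min_dist
  }
  pairs <- matrix(integer(0), ncol = 2)
  for (p in seq_len(g$n_planted_pairs)) {
    placed <- FALSE
    for (try in seq_len(g$max_proposals)) {
      d <- sample(g$pair_distances, 1)
      phi <- runif(1, 0, 2 * pi)
      a <- c(runif(1, lo, hi), runif(1, lo, hi))
      b <- a + d * c(cos(phi), sin(phi))
      if (b[1] < lo || b[1] > hi || b[2] < lo || b[2] > hi) next
      if (!ok_dist(a)) next
      centers_try <- rbind(centers, a)
      if (min(sqrt((centers_try[, 1] - b[1])^2 +
                     (centers_try[, 2] - b[2])^2)) < g$min_dist) next
      centers <- rbind(centers_try, b)
      pairs <- rbind(pairs, c(nrow(centers) - 1L, nrow(centers)))
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  for (item in seq_len(n - 2L * g$n_planted_pairs)) {
    placed <- FALSE
    for (try in seq_len(g$max_proposals)) {
      a <- c(runif(1, lo, hi), runif(1, lo, hi))
      if (!ok_dist(a)) next
      centers <- rbind(centers, a)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  rownames(centers) <- NULL
  list(centers = centers, pairs = as_pair_matrix(pairs))
}

# Orientation at which inducer i opens towards j (and vice versa).
facing_orientations <- function(centers, pair) {
  dx <- centers[pair[2], 1] - centers[pair[1], 1]
  dy <- centers[pair[2], 2] - centers[pair[1], 2]
  phi <- norm_deg(atan2(dy, dx) * 180 / pi)
  c(phi, norm_deg(phi + 180))
}

# Draw base orientations such that the base (k = 0) pattern and its k = 2
# and k = 4 clones each contain exactly the intended aligned pairs.
# Returns the base orientation vector, or NULL if free resampling cannot
# fix a clash between two axis-locked inducers.
resolve_orientations <- function(centers, pairs, g) {
  n <- nrow(centers)
  ori <- runif(n, 0, 360)
  locked_ori <- rep(NA_real_, n)
  for (p in seq_len(nrow(pairs))) {
    fo <- facing_orientations(centers, pairs[p, ])
    locked_ori[pairs[p, 1]] <- fo[1]
    locked_ori[pairs[p, 2]] <- fo[2]
  }
  # clone configurations: which planted pairs are realigned
  configs <- list(integer(0))
  if (nrow(pairs) >= 2) configs <- c(configs, list(1:2))
  if (nrow(pairs) >= 1) configs <- c(configs, list(seq_len(nrow(pairs))))

  fake <- tibble(x = centers[, 1], y = centers[, 2], orientation = ori)
  for (attempt in seq_len(500)) {
    clash <- FALSE
    offenders <- integer(0)
    for (cfg in configs) {
      locked <- sort(as.vector(pairs[cfg, , drop = FALSE]))
      fake$orientation <- ori
      fake$orientation[locked] <- locked_ori[locked]
      found <- aligned_pairs(fake, g)
      expected <- pairs[cfg, , drop = FALSE]
      for (r in seq_len(nrow(found))) {
        pr <- found[r, ]
        is_expected <- nrow(expected) > 0 &&
          any(expected[, 1] == min(pr) & expected[, 2] == max(pr))
        if (is_expected) next
        free <- setdiff(pr, locked)
        if (length(free) == 0) {
          clash <- TRUE
        } else {
          offenders <- c(offenders, free)
        }
      }
    }
    if (clash) return(NULL)
    if (length(offenders) == 0) return(ori)
    offenders <- unique(offenders)
    ori[offenders] <- runif(length(offenders), 0, 360)
  }
  NULL
}

#' Clone a base pattern at a given illusory-contour level
#'
#' Copies a zero-contour base pattern and re-orients the members of its
#' first `k` planted candidate pairs so that each pair's notch openings
#' face each other exactly along the pair axis (antiparallel
#' orientations), completing `k` illusory contours. Centres, sizes,
#' notch dimensions and the orientations of all other inducers are kept
#' bit-identical, so the clone shares the base pattern's convex hull,
#' density and total surface.
#'
#' @param base A zero-contour `stimulus_pattern` from
#'   [generate_base_pattern()].
#' @param k Number of illusory-contour pairs: 0, 2 or 4.
#' @return A `stimulus_pattern` with `k` aligned pairs listed in
#'   `ic_pairs`.
#' @export
#' @examples
#' base <- generate_base_pattern(12, "test", seed = 3)
#' four <- clone_with_ics(base, 4)
#' all(four$inducers$x == base$inducers$x)
clone_with_ics <- function(base, k) {
  if (!inherits(base, "stimulus_pattern")) abort("`base` must be a stimulus_pattern.")
  if (!k %in% c(0, 2, 4)) abort("`k` must be 0, 2 or 4.")
  if (nrow(base$ic_pairs) != 0) abort("`base` must be a zero-contour pattern.")
  if (nrow(base$planted_pairs) < k) {
    abort(sprintf("base has %d planted pairs; %d required.",
                  nrow(base$planted_pairs), k))
  }
  out <- base
  if (k == 0) return(out)
  sel <- base$planted_pairs[seq_len(k), , drop = FALSE]
  centers <- cbind(base$inducers$x, base$inducers$y)
  for (p in seq_len(nrow(sel))) {
    fo <- facing_orientations(centers, sel[p, ])
    out$inducers$orientation[sel[p, 1]] <- fo[1]
    out$inducers$orientation[sel[p, 2]] <- fo[2]
  }
  out$ic_pairs <- as_pair_matrix(sel)
  out
}

#' Assign contrast polarity to the inducers of a pattern
#'
#' Colours each inducer black (`polarity = -1`) or white (`+1`) relative
#' to the mid-grey background. The `"mixed"` (reverse-contrast) scheme
#' gives every candidate illusory-contour pair one black and one white
#' member, balances the remaining inducers so that an even-numerosity
#' pattern has exactly N/2 of each colour, and colours the single excess
#' inducer of an odd-numerosity pattern according to `odd_excess` (the
#' stimulus-set builder counterbalances the excess colour across
#' patterns).
#'
#' @param pattern A `stimulus_pattern` (clone the contour level first).
#' @param scheme `"all_black"`, `"all_white"` or `"mixed"`.
#' @param seed Integer seed for the random black/white allocation within
#'   the mixed scheme.
#' @param odd_excess Colour of the single unpaired excess inducer for
#'   odd numerosities, `"black"` or `"white"`.
#' @return The pattern with polarities and `color_scheme` set.
#' @export
assign_polarity <- function(pattern, scheme = c("all_black", "all_white", "mixed"),
                            seed = 1L, odd_excess = c("black", "white")) {
  scheme <- match.arg(scheme)
  odd_excess <- match.arg(odd_excess)
  out <- pattern
  if (scheme == "all_black") {
    out$inducers$polarity <- -1
  } else if (scheme == "all_white") {
    out$inducers$polarity <- 1
  } else {
    n <- pattern$n
    pairs <- if (nrow(pattern$planted_pairs) > 0) pattern$planted_pairs else pattern$ic_pairs
    n_black <- if (n %% 2 == 0) n %/% 2 else (n + (odd_excess == "black")) %/% 2
    npair <- nrow(pairs)
    paired_idx <- as.vector(pairs)
    free_idx <- setdiff(seq_len(n), paired_idx)
    need_free_black <- n_black - npair
    if (need_free_black < 0 || need_free_black > length(free_idx)) {
      abort("mixed polarity: pair structure makes the half/half split impossible.")
    }
    pol <- rep(NA_real_, n)
    withr::with_seed(as.integer(seed), {
      for (p in seq_len(npair)) {
        black_member <- sample(pairs[p, ], 1)
        pol[pairs[p, ]] <- ifelse(pairs[p, ] == black_member, -1, 1)
      }
      pol[free_idx] <- 1
      if (need_free_black > 0) {
        blk <- if (length(free_idx) == 1) free_idx else sample(free_idx, need_free_black)
        pol[blk[seq_len(need_free_black)]] <- -1
      }
    })
    out$inducers$polarity <- pol
  }
  out$color_scheme <- scheme
  out
}

#' Close the inducer notches with a thin arc
#'
#' Marks every inducer as closed: rendering seals the notch mouth with a
#' curved line (`line_px` thick, 1 px by default) along the disc rim,
#' completing each item's circular outline and preventing illusory
#' contour formation. Centres, orientations, polarities and the pair
#' roster (kept for condition bookkeeping) are unchanged.
#'
#' @param pattern A `stimulus_pattern`.
#' @param line_px Thickness of the sealing arc, px; must be positive.
#' @return The pattern with `closed = TRUE` on every inducer.
#' @export
close_inducers <- function(pattern, line_px = 1) {
  if (!is.numeric(line_px) || length(line_px) != 1 || line_px <= 0) {
    abort("`line_px` must be a positive number.")
  }
  out <- pattern
  out$inducers$closed <- TRUE
  out$closure_px <- line_px
  out
}

# ---- full stimulus sets ----------------------------------------------------

#' Build the complete stimulus set of one experiment
#'
#' Generates the full test and reference stimulus inventory for one of
#' the three experiments: 8 base test patterns per numerosity 9-15 (56
#' bases), each cloned at 0, 2 and 4 illusory contours (168 test
#' stimuli), plus 56 reference patterns of 12 items built under the same
#' spatial constraints, each presented once per contour level (168
#' reference presentations). Experiment 1 draws half the pattern pairs
#' all-black and half all-white; experiments 2 and 3 use the mixed
#' (reverse-contrast) scheme with the odd-numerosity excess colour
#' counterbalanced four/four across the 8 patterns of each numerosity;
#' experiment 3 additionally closes every inducer, cloning the
#' experiment-2 spatial patterns unchanged.
#'
#' @param experiment 1, 2 or 3.
#' @param seed Integer master seed.
#' @param geometry A [pattern_geometry()].
#' @return A list with `patterns` (named list of `stimulus_pattern`s)
#'   and `manifest` (a tibble with one row per stimulus presentation:
#'   `pattern_id`, `role`, `numerosity`, `n_ic`, `scheme`, `base_id`,
#'   `ref_id`).
#' @export
generate_stimulus_set <- function(experiment, seed = 1L,
                                  geometry = pattern_geometry()) {
  if (!experiment %in% 1:3) abort("`experiment` must be 1, 2 or 3.")
  numerosities <- 9:15
  n_base <- 8L
  seeds <- derive_seeds(seed, length(numerosities) * n_base * 2L + 1000L)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  patterns <- list()
  rows <- list()

  mixed <- experiment %in% c(2, 3)
  for (ni in seq_along(numerosities)) {
    nv <- numerosities[ni]
    for (b in seq_len(n_base)) {
      base <- generate_base_pattern(nv, "test", seed = next_seed(),
                                    geometry = geometry)
      # colour plan: exp 1 splits patterns half black / half white;
      # exp 2/3 counterbalance the odd-numerosity excess colour 4/4.
      scheme <- if (mixed) "mixed" else if (b <= n_base / 2) "all_black" else "all_white"
      excess <- if (b <= n_base / 2) "black" else "white"
      pol_seed <- next_seed()
      ref <- generate_base_pattern(12L, "reference", seed = next_seed(),
                                   geometry = geometry)
      ref_scheme <- if (mixed) "mixed" else scheme
      ref <- assign_polarity(ref, ref_scheme, seed = pol_seed)
      if (experiment == 3) ref <- close_inducers(ref)
      ref_id <- sprintf("e%d-ref-N12-%02d-%d", experiment, b, nv)
      patterns[[ref_id]] <- ref
      for (k in c(0L, 2L, 4L)) {
        pat <- clone_with_ics(base, k)
        pat <- assign_polarity(pat, scheme, seed = pol_seed, odd_excess = excess)
        if (experiment == 3) pat <- close_inducers(pat)
        pid <- sprintf("e%d-test-N%02d-%02d-k%d", experiment, nv, b, k)
        patterns[[pid]] <- pat
        rows <- c(rows, list(
          tibble(pattern_id = pid, role = "test", numerosity = nv,
                 n_ic = k, scheme = scheme, base_id = pat$base_id,
                 ref_id = ref_id),
          tibble(pattern_id = ref_id, role = "reference", numerosity = 12L,
                 n_ic = k, scheme = ref_scheme, base_id = ref$base_id,
                 ref_id = ref_id)
        ))
      }
    }
  }
  list(patterns = patterns, manifest = bind_rows(rows))
}

# ---- serialization ---------------------------------------------------------

#' Serialize or restore a stimulus pattern as JSON
#'
#' Writes all inducer fields, the pair rosters, role, base id, colour
#' scheme and geometry to a JSON string (or file); `pattern_from_json()`
#' restores an identical pattern. Serialisation is deterministic, so
#' identical patterns always produce byte-identical JSON.
#'
#' @param pattern A `stimulus_pattern`.
#' @param path Optional file path; when given the JSON is written there.
#' @return `pattern_to_json()`: the JSON string, invisibly when `path`
#'   is given. `pattern_from_json()`: a `stimulus_pattern`.
#' @export
pattern_to_json <- function(pattern, path = NULL) {
  payload <- list(
    inducers = as.data.frame(pattern$inducers),
    ic_pairs = pattern$ic_pairs,
    planted_pairs = pattern$planted_pairs,
    role = pattern$role,
    base_id = pattern$base_id,
    color_scheme = pattern$color_scheme,
    closure_px = pattern$closure_px,
    geometry = unclass(pattern$geometry)
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname pattern_to_json
#' @param json A JSON string or file path produced by `pattern_to_json()`.
#' @export
pattern_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  g <- do.call(pattern_geometry, x$geometry[setdiff(names(x$geometry), character(0))])
  out <- new_stimulus_pattern(
    as_tibble(x$inducers),
    ic_pairs = x$ic_pairs, planted_pairs = x$planted_pairs,
    role = x$role, base_id = x$base_id, color_scheme = x$color_scheme,
    geometry = g
  )
  if (!is.null(x$closure_px)) out$closure_px <- x$closure_px
  out
}
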