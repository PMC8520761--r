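# Analytic area of one Pac-Man item: disc minus the part of the notch
# rectangle (width w, extending L px from the centre) that lies inside
# the disc. For the default geometry (r = 10, L = 10, w = 4) the notch
# removes the full chord integral 2 * int_0^{w/2} sqrt(r^2 - y^2) dy.
inducer_area <- function(diameter, notch_width, notch_length) {
  r <- diameter / 2
  w2 <- notch_width / 2
  L <- notch_length
  if (w2 > r) w2 <- r
  antider <- function(y) (y * sqrt(pmax(r^2 - y^2, 0)) + r^2 * asin(pmin(y / r, 1))) / 2
  y0 <- min(w2, sqrt(max(r^2 - L^2, 0)))
  rect_part <- 2 * L * y0
  cap_part <- if (w2 > y0) 2 * (antider(w2) - antider(y0)) else 0
  pi * r^2 - (rect_part + cap_part)
}

# Sample points on each inducer's circular rim (the hull-relevant part
# of the item boundary; the notch is a concave cavity).
boundary_points <- function(pattern, points_per_item = 64) {
  th <- seq(0, 2 * pi, length.out = points_per_item + 1)[-1]
  ind <- pattern$inducers
  r <- ind$diameter / 2
  x <- as.vector(outer(cos(th), r) + rep(ind$x, each = length(th)))
  y <- as.vector(outer(sin(th), r) + rep(ind$y, each = length(th)))
  cbind(x = x, y = y)
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Continuous visual features of a pattern
#'
#' Computes the non-numerical image features that the stimulus design
#' holds constant across illusory-contour levels: convex hull area
#' (over sampled points of each item's circular rim), total item surface
#' (analytic disc-minus-notch area times N), density (N per hull area)
#' and panel occupancy (total surface over panel area). Because
#' [clone_with_ics()] only rotates inducers, a base pattern and its
#' clones share these features exactly.
#'
#' @param pattern A `stimulus_pattern` with at least 3 inducers.
#' @param points_per_item Rim points sampled per inducer for the hull.
#' @return A one-row tibble with `convex_hull_area` (px^2),
#'   `total_surface` (px^2), `density` (items/px^2) and `occupancy`
#'   (dimensionless).
#' @export
#' @examples
#' p <- generate_base_pattern(12, "test", seed = 2)
#' continuous_features(p)
continuous_features <- function(pattern, points_per_item = 64) {
  if (pattern$n < 3) {
    abort("convex hull undefined for fewer than 3 inducers.")
  }
  pts <- boundary_points(pattern, points_per_item)
  hull_idx <- grDevices::chull(pts)
  hull_area <- polygon_area(pts[hull_idx, , drop = FALSE])
  ind <- pattern$inducers
  areas <- mapply(inducer_area, ind$diameter, ind$notch_width, ind$notch_length)
  total_surface <- sum(areas)
  tibble(
    convex_hull_area = hull_area,
    total_surface = total_surface,
    density = pattern$n / hull_area,
    occupancy = total_surface / pattern$geometry$panel_size^2
  )
}
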