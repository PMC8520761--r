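#' Rasterise a stimulus pattern to a ternary luminance grid
#'
#' Renders the pattern onto its panel without anti-aliasing: a pixel
#' takes an inducer's polarity value (-1 black, +1 white) iff the pixel
#' centre lies inside that inducer's disc and outside its notch
#' rectangle; when the inducer is closed, pixels of the notch mouth
#' within the sealing arc's thickness of the rim also take the polarity.
#' All other pixels are mid-grey background (0). Pixel centres sit at
#' integer + 0.5 coordinates, origin at the top-left, x rightward,
#' y downward.
#'
#' @param pattern A valid `stimulus_pattern`.
#' @return An `image_grid`: a `panel_size` x `panel_size` numeric matrix
#'   (rows = y, columns = x) with values in {-1, 0, +1}.
#' @export
#' @examples
#' img <- render_pattern(generate_base_pattern(9, "test", seed = 5))
#' dim(img)
render_pattern <- function(pattern) {
  g <- pattern$geometry
  ind <- pattern$inducers
  size <- as.integer(g$panel_size)
  img <- matrix(0, nrow = size, ncol = size)
  if (nrow(ind) >= 2) {
    dmat <- stats::dist(cbind(ind$x, ind$y))
    if (min(dmat) < max(ind$diameter)) {
      abort("inducers overlap; refusing to render an invalid pattern.")
    }
  }
  xc <- seq_len(size) - 0.5
  yc <- seq_len(size) - 0.5
  line_px <- pattern$closure_px %||% 1
  for (i in seq_len(nrow(ind))) {
    r <- ind$diameter[i] / 2
    # bounding box of the disc keeps the per-inducer work O(d^2)
    cols <- which(xc >= ind$x[i] - r - 1 & xc <= ind$x[i] + r + 1)
    rows <- which(yc >= ind$y[i] - r - 1 & yc <= ind$y[i] + r + 1)
    dx <- outer(rep(1, length(rows)), xc[cols] - ind$x[i])
    dy <- outer(yc[rows] - ind$y[i], rep(1, length(cols)))
    dist2 <- dx^2 + dy^2
    in_disc <- dist2 <= r^2
    th <- ind$orientation[i] * pi / 180
    along <- dx * cos(th) + dy * sin(th)
    perp <- -dx * sin(th) + dy * cos(th)
    in_notch <- along > 0 & along <= ind$notch_length[i] &
      abs(perp) <= ind$notch_width[i] / 2
    vis <- in_disc & !in_notch
    if (isTRUE(ind$closed[i])) {
      on_arc <- in_disc & in_notch & dist2 >= (r - line_px)^2
      vis <- vis | on_arc
    }
    sub <- img[rows, cols]
    sub[vis] <- ind$polarity[i]
    img[rows, cols] <- sub
  }
  structure(img, class = c("image_grid", class(img)))
}

#' Export a rendered pattern as an 8-bit grayscale PNG
#'
#' Maps the ternary luminance grid to 8-bit gray: -1 (black) to 0,
#' 0 (mid-grey background) to 128, +1 (white) to 255.
#'
#' @param x A `stimulus_pattern` or `image_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_png <- function(x, path) {
  img <- if (inherits(x, "stimulus_pattern")) render_pattern(x) else x
  gray <- (unclass(img) + 1) / 2          # -1,0,1 -> 0, .5, 1
  gray[unclass(img) == 0] <- 128 / 255
  gray[unclass(img) == 1] <- 1
  gray[unclass(img) == -1] <- 0
  png::writePNG(gray, target = path)
  invisible(path)
}

#' Plot a stimulus pattern
#'
#' Displays the rendered panel as a raster image (black inducers, white
#' inducers, mid-grey background), optionally marking aligned
#' illusory-contour pairs.
#'
#' @param object A `stimulus_pattern`.
#' @param mark_pairs Draw a dashed segment between aligned pair centres.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stimulus_pattern <- function(object, mark_pairs = TRUE, ...) {
  img <- render_pattern(object)
  size <- nrow(img)
  df <- tidyr::expand_grid(y = seq_len(size) - 0.5, x = seq_len(size) - 0.5)
  df$value <- as.vector(t(unclass(img)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white", midpoint = 0,
                                  limits = c(-1, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      title = sprintf("%s pattern, N = %d, %d illusory contour(s)",
                      object$role, object$n, nrow(object$ic_pairs))
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
  if (mark_pairs && nrow(object$ic_pairs) > 0) {
    ic <- object$ic_pairs
    seg <- tibble(
      x = object$inducers$x[ic[, 1]], y = object$inducers$y[ic[, 1]],
      xend = object$inducers$x[ic[, 2]], yend = object$inducers$y[ic[, 2]]
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      linetype = "dashed", colour = "red", linewidth = 0.3
    )
  }
  p
}
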