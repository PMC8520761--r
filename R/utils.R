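#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across
#' @importFrom stats pnorm qnorm optim rnorm runif rbinom pt pf sd
NULL

# normalize angles (degrees) to [0, 360)
norm_deg <- function(theta) {
  theta %% 360
}

# absolute angular difference in degrees, in [0, 180]
ang_diff <- function(a, b) {
  d <- abs(norm_deg(a) - norm_deg(b)) %% 360
  pmin(d, 360 - d)
}

# derive a stream of sub-seeds from one master seed, kept inside 32-bit range
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
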