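Package: icnum
Title: Illusory-Contour Numerosity: Stimulus Synthesis, Observer Simulation
    and Psychophysical Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how Kanizsa-type illusory-contour
    connections bias nonsymbolic numerosity judgments. Synthesises
    Pac-Man inducer dot arrays whose illusory-contour connectedness is
    manipulated while continuous features (convex hull, density, total
    surface) stay fixed; simulates two-alternative forced-choice
    numerosity judgments by a Weber-noise observer with an
    illusory-contour grouping bias; fits cumulative-Gaussian
    psychometric functions by maximum likelihood with bounded guess and
    lapse rates; derives points of subjective equality, coefficients of
    variation and bootstrap confidence intervals; and runs
    repeated-measures ANOVA with Greenhouse-Geisser correction,
    Bonferroni post hocs and polynomial trend contrasts. All functions
    take and return tidy data frames so full simulated experiments can
    be piped end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
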