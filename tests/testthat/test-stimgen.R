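test_that("base patterns respect all spatial constraints", {
  cases <- expand.grid(n = c(9, 12, 15), seed = c(1, 7, 42))
  for (r in seq_len(nrow(cases))) {
    p <- generate_base_pattern(cases$n[r], "test", seed = cases$seed[r])
    expect_equal(p$n, cases$n[r])
    expect_equal(nrow(p$inducers), cases$n[r])
    d <- oracle_pairwise_distances(p)
    expect_true(all(d >= 22 - 1e-9))
    expect_true(all(p$inducers$x >= 20 & p$inducers$x <= 220))
    expect_true(all(p$inducers$y >= 20 & p$inducers$y <= 220))
    pd <- icnum:::pair_distances_of(p$inducers, p$planted_pairs)
    expect_length(pd, 4)
    expect_true(all(vapply(pd, function(x)
      any(abs(x - c(22, 25, 28, 31)) < 1e-6), logical(1))))
    # zero-contour base: no pair passes the alignment predicate
    expect_equal(nrow(oracle_aligned_pairs(p)), 0)
    expect_equal(nrow(validate_pattern(p)), 0)
  }
})

test_that("generation is deterministic and serialisation round-trips byte-identically", {
  a <- generate_base_pattern(11, "test", seed = 99)
  b <- generate_base_pattern(11, "test", seed = 99)
  expect_identical(a, b)
  expect_identical(pattern_to_json(a), pattern_to_json(b))
  back <- pattern_from_json(pattern_to_json(a))
  expect_equal(back$inducers, a$inducers)
  expect_equal(back$planted_pairs, a$planted_pairs)
  c <- generate_base_pattern(11, "test", seed = 100)
  expect_false(identical(a$inducers, c$inducers))
})

test_that("too-small patterns cannot host the planted pairs", {
  expect_error(generate_base_pattern(7, "test", seed = 1), "planted pairs")
})

test_that("clones keep geometry bit-identical and align exactly k pairs", {
  for (seed in c(2, 13)) {
    base <- generate_base_pattern(12, "test", seed = seed)
    f_base <- continuous_features(base)
    expect_identical(clone_with_ics(base, 0), base)
    for (k in c(2, 4)) {
      cl <- clone_with_ics(base, k)
      expect_identical(cl$inducers$x, base$inducers$x)
      expect_identical(cl$inducers$y, base$inducers$y)
      expect_identical(cl$inducers$diameter, base$inducers$diameter)
      expect_identical(cl$inducers$notch_width, base$inducers$notch_width)
      expect_identical(cl$inducers$notch_length, base$inducers$notch_length)
      f_cl <- continuous_features(cl)
      expect_equal(unlist(f_cl), unlist(f_base), tolerance = 1e-9)
      found <- oracle_aligned_pairs(cl)
      expect_equal(nrow(found), k)
      expect_true(icnum:::same_pair_set(found, cl$ic_pairs))
      expect_equal(nrow(validate_pattern(cl)), 0)
    }
  }
  base <- generate_base_pattern(12, "test", seed = 2)
  expect_error(clone_with_ics(base, 3), "0, 2 or 4")
  expect_error(clone_with_ics(clone_with_ics(base, 2), 2), "zero-contour")
})

test_that("validate_pattern reports planted violations", {
  p <- generate_base_pattern(12, "test", seed = 5)
  # two centres forced 15 px apart -> min-distance violation
  q <- p
  q$inducers$x[2] <- q$inducers$x[1] + 15
  q$inducers$y[2] <- q$inducers$y[1]
  expect_true("min_distance" %in% validate_pattern(q)$check)
  # mutate one planted pair to face each other -> spurious alignment
  r <- p
  pr <- r$planted_pairs[1, ]
  fo <- icnum:::facing_orientations(cbind(r$inducers$x, r$inducers$y), pr)
  r$inducers$orientation[pr[1]] <- fo[1]
  r$inducers$orientation[pr[2]] <- fo[2]
  expect_true("alignment" %in% validate_pattern(r)$check)
  expect_true(nrow(oracle_aligned_pairs(r)) >= 1)
})

test_that("mixed polarity balances colours and splits every pair", {
  base <- clone_with_ics(generate_base_pattern(12, "test", seed = 3), 4)
  m <- assign_polarity(base, "mixed", seed = 4)
  expect_equal(sum(m$inducers$polarity == -1), 6)
  expect_equal(sum(m$inducers$polarity == 1), 6)
  for (p in seq_len(nrow(m$ic_pairs))) {
    expect_equal(sum(m$inducers$polarity[m$ic_pairs[p, ]]), 0)
  }
  blk <- assign_polarity(base, "all_black")
  expect_true(all(blk$inducers$polarity == -1))
  wht <- assign_polarity(base, "all_white")
  expect_true(all(wht$inducers$polarity == 1))
  # odd numerosity: excess colour as requested
  odd <- generate_base_pattern(13, "test", seed = 6)
  mb <- assign_polarity(odd, "mixed", seed = 1, odd_excess = "black")
  expect_equal(sum(mb$inducers$polarity == -1), 7)
  mw <- assign_polarity(odd, "mixed", seed = 1, odd_excess = "white")
  expect_equal(sum(mw$inducers$polarity == 1), 7)
  # impossible half/half split: 10 items all locked in 5 pairs plus
  # pair structure demanding more blacks than available
  bad <- make_manual_pattern(
    xs = seq(30, 210, length.out = 8), ys = rep(c(40, 200), 4),
    orientations = rep(0, 8),
    planted_pairs = cbind(1:7, c(2:8))  # overlapping roster
  )
  expect_error(assign_polarity(bad, "mixed"), "impossible")
})

test_that("closing inducers preserves geometry and seals the notch mouth", {
  base <- assign_polarity(
    clone_with_ics(generate_base_pattern(12, "test", seed = 8), 4),
    "mixed", seed = 2
  )
  cl <- close_inducers(base)
  expect_identical(cl$inducers$x, base$inducers$x)
  expect_identical(cl$inducers$orientation, base$inducers$orientation)
  expect_identical(cl$inducers$polarity, base$inducers$polarity)
  expect_true(all(cl$inducers$closed))
  expect_true(icnum:::same_pair_set(cl$ic_pairs, base$ic_pairs))
  expect_error(close_inducers(base, line_px = 0), "positive")

  # point-in-stroke: pixel at the notch mouth on the rim
  single <- make_manual_pattern(120.5, 120.5, orientations = 0)
  open_img <- render_pattern(single)
  closed_img <- render_pattern(close_inducers(single))
  # pixel centre (129.5, 120.5): 9 px along the notch axis, inside the
  # 1-px sealing arc (distance 9 >= r - 1)
  expect_equal(open_img[121, 130], 0)
  expect_equal(closed_img[121, 130], -1)
})

test_that("continuous features match analytic and brute-force oracles", {
  # analytic item area vs 2-D numeric integration
  area_pkg <- icnum:::inducer_area(20, 4, 10)
  g <- seq(-10 + 0.005, 10 - 0.005, by = 0.01)
  xy <- expand.grid(x = g, y = g)
  inside <- xy$x^2 + xy$y^2 <= 100 &
    !(xy$x > 0 & xy$x <= 10 & abs(xy$y) <= 2)
  area_num <- sum(inside) * 0.01^2
  expect_equal(area_pkg, area_num, tolerance = 2e-3)

  p <- generate_base_pattern(12, "test", seed = 10)
  feats <- continuous_features(p)
  expect_equal(feats$total_surface, 12 * area_pkg)
  expect_equal(feats$density, 12 / feats$convex_hull_area)
  expect_equal(feats$occupancy, feats$total_surface / 240^2)
  # hull vs O(n^3) oracle on a sparser rim sampling
  pts <- icnum:::boundary_points(p, points_per_item = 12)
  feats12 <- continuous_features(p, points_per_item = 12)
  expect_equal(feats12$convex_hull_area, oracle_hull_area(pts),
               tolerance = 1e-9)
  expect_error(
    continuous_features(make_manual_pattern(c(50, 100), c(50, 50), c(0, 0))),
    "fewer than 3"
  )
})

test_that("rendering is ternary, panel-sized and consistent with the analytic surface", {
  p <- assign_polarity(generate_base_pattern(10, "test", seed = 12), "mixed",
                       seed = 3)
  img <- render_pattern(p)
  expect_equal(dim(img), c(240, 240))
  expect_true(all(img %in% c(-1, 0, 1)))
  # pixel at an inducer centre carries its polarity; 5 px down the notch
  # axis is carved out
  single <- make_manual_pattern(120.5, 120.5, orientations = 90)  # notch +y
  simg <- render_pattern(single)
  expect_equal(simg[121, 121], -1)
  expect_equal(simg[126, 121], 0)  # 5 px along +y
  # empty pattern renders pure background
  empty <- make_manual_pattern(numeric(0), numeric(0), numeric(0))
  expect_true(all(render_pattern(empty) == 0))
  # rasterised area within 5% of the analytic total surface
  feats <- continuous_features(p)
  expect_equal(sum(img != 0), feats$total_surface, tolerance = 0.05)
  # closed rendering stays within the same tolerance
  cimg <- render_pattern(close_inducers(p))
  expect_equal(sum(cimg != 0), feats$total_surface, tolerance = 0.05)
  expect_true(sum(cimg != 0) > sum(img != 0))  # arcs add pixels
})

test_that("png export maps the ternary scale to 8-bit gray", {
  p <- assign_polarity(generate_base_pattern(9, "test", seed = 20), "mixed",
                       seed = 1)
  path <- withr::local_tempfile(fileext = ".png")
  write_pattern_png(p, path)
  back <- png::readPNG(path)
  expect_equal(dim(back), c(240, 240))
  expect_setequal(unique(round(as.vector(back) * 255)), c(0, 128, 255))
})
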