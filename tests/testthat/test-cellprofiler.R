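test_that("rectangle masks measure to their exact pixel extents", {
  ps <- 0.1
  m <- make_rect_mask(20, 8, pixel_size_um = ps)
  img <- matrix(3, 60, 60)
  g <- measure_cell(m, img, background = 0)
  expect_equal(g$length_um, 20 * ps, tolerance = 1e-9)
  expect_equal(g$width_um, 8 * ps, tolerance = 1e-9)
  expect_equal(g$area_um2, 160 * ps^2)
  # uniform fluorescence f over N pixels, zero background
  expect_equal(g$total_fluor, 160 * 3)
  expect_equal(g$concentration, g$total_fluor / g$volume_um3)
  expect_error(measure_cell(make_rect_mask(2, 2), img), "fewer than 5")
})

test_that("rod-model volume has the closed form and sphere fallback", {
  l <- 2; w <- 1
  expect_equal(rod_volume(l, w),
               pi * 0.5^2 * (l - w) + 4 / 3 * pi * 0.5^3)
  # l = w degenerates to the sphere, continuously
  expect_equal(rod_volume(1, 1), 4 / 3 * pi * 0.5^3)
  expect_equal(rod_volume(0.8, 1), 4 / 3 * pi * 0.5^3)
})

test_that("axis profiles are unit-sum and place signal where it belongs", {
  ps <- 0.1
  m <- make_rect_mask(40, 8, pixel_size_um = ps)
  img <- matrix(2, 80, 80)
  p <- axis_profile(m, img, background = 0, axis = "long", n_bins = 20)
  expect_equal(sum(p$values), 1, tolerance = 1e-9)
  expect_equal(length(p$values), 20)
  # uniform intensity: each bin near 1/n_bins
  expect_lt(max(abs(p$values - 1 / 20)), 0.015)

  # all fluorescence in one end pixel: single nonzero bin at position ~0
  img2 <- matrix(0, 80, 80)
  img2[10, 12] <- 50  # top end of the mask (lowest row)
  p2 <- axis_profile(m, img2, axis = "long", n_bins = 20)
  expect_equal(sum(p2$values > 0), 1)
  expect_equal(which(p2$values > 0), 1)  # low-row end is position 0

  # a 1-pixel-wide line has zero variance across the short axis
  line <- make_rect_mask(30, 1, pixel_size_um = ps)
  expect_error(axis_profile(line, img, axis = "short"), "degenerate")
})

test_that("group sizes follow quota rounding with the last group absorbing", {
  expect_equal(group_sizes(10, c(0.6, 0.2, 0.1, 0.1)), c(6L, 2L, 1L, 1L))
  expect_equal(group_sizes(1258, c(0.6, 0.2, 0.1, 0.1)),
               c(755L, 252L, 126L, 125L))
  expect_equal(sum(group_sizes(997, c(0.32, 0.27, 0.22, 0.19))), 997)
  expect_error(group_sizes(3, rep(0.25, 4)), "more groups|empty group")
  expect_error(group_sizes(10, c(0.5, 0.4)), "sum to 1")
  expect_error(group_sizes(10, c(-0.1, 1.1)), "> 0")
})

test_that("identical cells give identical group mean profiles", {
  ps <- 0.1
  masks <- lapply(1:6, function(i) make_rect_mask(30, 10, pixel_size_um = ps,
                                                  label = i))
  img <- matrix(5, 60, 60)
  cells <- lapply(masks, measure_cell, fluor_image = img, background = 0)
  profs <- lapply(masks, axis_profile, fluor_image = img, background = 0)
  gp <- group_cells(cells, profs, "width", c(0.5, 0.5))
  expect_equal(gp$groups[[1]]$profile$values, gp$groups[[2]]$profile$values)
})

test_that("fluorescence-width regression handles exact and degenerate input", {
  mk <- function(w, f) structure(list(width_um = w, area_um2 = w,
                                      total_fluor = f), class = "cell_geometry")
  cells <- Map(mk, c(1, 2, 3, 4), c(10, 20, 30, 40))
  fit <- fluor_vs_width_fit(cells)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 10, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_error(fluor_vs_width_fit(cells[1:2]), "at least 3")
  same <- Map(mk, c(1, 1, 1), c(1, 2, 3))
  expect_error(fluor_vs_width_fit(same), "variance")
})

test_that("peak counting distinguishes flat, single and double profiles", {
  mkprof <- function(v) structure(
    list(axis = "long", n_bins = length(v),
         positions = (seq_along(v) - 0.5) / length(v),
         values = v / sum(v)), class = "axis_profile")
  flat <- mkprof(rep(1, 100))
  expect_equal(count_profile_peaks(flat), 0L)
  x <- seq(0, 1, length.out = 100)
  two <- mkprof(dnorm(x, 0.1, 0.06) + dnorm(x, 0.9, 0.06) + 0.01)
  expect_equal(count_profile_peaks(two), 2L)
  one <- mkprof(dnorm(x, 0.5, 0.1) + 0.01)
  expect_equal(count_profile_peaks(one), 1L)
})

test_that("segmentation finds capsules, skips small and border objects", {
  blank <- matrix(100, 64, 64)
  expect_equal(length(segment_cells(blank, 0.1)), 0)

  sim <- gen_cell_images(10, image_size = c(384, 384), seed = 21)
  expect_equal(nrow(sim$truth), 10)
  masks <- segment_cells(sim$images[[1]]$phase, sim$pixel_size_um)
  expect_equal(length(masks), 10)

  # an object touching the border is dropped
  img <- matrix(1000, 64, 64)
  img[1:10, 20:30] <- 100
  img[40:50, 40:50] <- 100
  masks2 <- segment_cells(img, 0.1)
  expect_equal(length(masks2), 1)
  expect_true(min(masks2[[1]]$pixels[, 1]) >= 40)
  # and min_area filtering removes specks
  img[20, 5] <- 100
  expect_equal(length(segment_cells(img, 0.1, min_area_px = 50)), 1)
})

test_that("synthetic-cell geometry is recovered within one pixel", {
  sim <- gen_cell_images(6, image_size = c(384, 384), seed = 31)
  res <- analyze_image_pair(sim$images[[1]]$phase, sim$images[[1]]$fluor,
                            sim$pixel_size_um)
  expect_equal(length(res$cells), 6)
  gt <- geometry_table(res$cells)
  # match measured to truth by nearest center? order by width instead
  tr <- sim$truth[order(sim$truth$width_um), ]
  got <- gt[order(gt$width_um), ]
  ps <- sim$pixel_size_um
  expect_lt(max(abs(got$width_um - tr$width_um)), ps)
  expect_lt(max(abs(got$length_um - tr$length_um)), 2 * ps)
})

test_that("measurements and profiles are invariant to 90-degree rotation", {
  sim <- gen_cell_images(1, image_size = c(256, 256), seed = 41)
  ph <- sim$images[[1]]$phase; fl <- sim$images[[1]]$fluor
  a <- analyze_image_pair(ph, fl, sim$pixel_size_um)
  b <- analyze_image_pair(rot90(ph), rot90(fl), sim$pixel_size_um)
  expect_equal(length(b$cells), 1)
  expect_equal(b$cells[[1]]$length_um, a$cells[[1]]$length_um, tolerance = 1e-6)
  expect_equal(b$cells[[1]]$width_um, a$cells[[1]]$width_um, tolerance = 1e-6)
  expect_equal(b$cells[[1]]$total_fluor, a$cells[[1]]$total_fluor,
               tolerance = 1e-6)
  pa <- a$profiles[[1]]$values
  pb <- b$profiles[[1]]$values
  # axis direction may flip under rotation; accept either orientation
  expect_lt(min(max(abs(pa - pb)), max(abs(pa - rev(pb)))), 0.02)
})

test_that("background estimation recovers the mode of non-cell pixels", {
  img <- matrix(100, 50, 50)
  expect_equal(estimate_background(img), 100)
  set.seed(1)
  img <- img + matrix(rnorm(2500, 0, 3), 50, 50)
  expect_lt(abs(estimate_background(img) - 100), 2)
})
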