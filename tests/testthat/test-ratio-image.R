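# Pixel-wise A/D ratio images and pseudocolor rendering.

test_that("pixel-wise division and floor invalidation behave as specified", {
  a <- uniform_frame(200, "acceptor")
  d <- uniform_frame(100, "donor")
  ri <- compute_ratio_image(a, d, intensity_floor = 10)
  expect_true(all(ri$valid))
  expect_true(all(ri$ratio == 2))
  # zero-donor pixels are invalid, never divided
  dd <- d
  dd$data[1, 1] <- 0
  ri2 <- compute_ratio_image(a, dd, intensity_floor = 0)
  expect_false(ri2$valid[1, 1])
  expect_true(is.na(ri2$ratio[1, 1]))
  # floor marks low-signal pixels invalid in either channel
  aa <- a
  aa$data[2, 2] <- 5
  ri3 <- compute_ratio_image(aa, d, intensity_floor = 10)
  expect_false(ri3$valid[2, 2])
})

test_that("shape and tag mismatches are errors", {
  a <- uniform_frame(200, "acceptor")
  d <- uniform_frame(100, "donor", dim = c(4L, 4L))
  expect_error(compute_ratio_image(a, d), "shape")
  expect_error(compute_ratio_image(uniform_frame(1, "donor"),
                                   uniform_frame(1, "donor")), "tag")
  d2 <- uniform_frame(100, "donor", time_h = 5)
  expect_error(compute_ratio_image(a, d2), "timepoints")
})

test_that("ratio times donor reproduces acceptor on valid pixels", {
  set.seed(31)
  for (i in 1:5) {
    ad <- matrix(runif(256, 0, 4000), 16, 16)
    dd <- matrix(runif(256, 1, 4000), 16, 16)
    a <- channel_frame(ad, "acceptor", 1)
    d <- channel_frame(dd, "donor", 1)
    ri <- compute_ratio_image(a, d, intensity_floor = 50)
    v <- ri$valid
    expect_true(any(v))
    expect_equal(ri$ratio[v] * dd[v], ad[v], tolerance = 1e-9)
  }
})

test_that("uniform split frames give the constant ratio R/(1-R)", {
  R <- 0.8659053635
  S <- 5000
  a <- uniform_frame(R * S, "acceptor")
  d <- uniform_frame((1 - R) * S, "donor")
  ri <- compute_ratio_image(a, d, intensity_floor = 10)
  expect_equal(unique(as.vector(ri$ratio)), R / (1 - R), tolerance = 1e-9)
})

test_that("default display range maps calibration extremes to hue endpoints", {
  rng <- default_display_range(printed_cal())
  expect_equal(rng[1], 0.27112 / (1 - 0.27112), tolerance = 1e-9)
  expect_equal(rng[2], 0.8659053635 / (1 - 0.8659053635), tolerance = 1e-6)
})

test_that("all-invalid ratio images render black", {
  a <- uniform_frame(1, "acceptor")
  d <- uniform_frame(1, "donor")
  ri <- compute_ratio_image(a, d, intensity_floor = 100)
  rgb <- render_pseudocolor(ri, d, a)
  expect_true(all(rgb == 0))
})

test_that("rendering is intensity-equivariant in brightness, invariant in hue", {
  R <- 0.6
  S1 <- 500
  mk <- function(S) {
    list(a = uniform_frame(R * S, "acceptor"), d = uniform_frame((1 - R) * S,
                                                                 "donor"))
  }
  f1 <- mk(S1); f10 <- mk(10 * S1)
  r1 <- compute_ratio_image(f1$a, f1$d, 1)
  r10 <- compute_ratio_image(f10$a, f10$d, 1)
  # equal ratio -> equal hue: RGB proportions identical
  g1 <- render_pseudocolor(r1, f1$d, f1$a)
  g10 <- render_pseudocolor(r10, f10$d, f10$a)
  # uniform images normalize to the same brightness; hue equality shows as
  # identical normalized RGB
  expect_equal(g1, g10, tolerance = 1e-7)
  # a mixed image keeps relative brightness: below the normalization
  # percentile, a 10x intensity pixel is 10x brighter
  ad <- matrix(R * 100, 10, 10); dd <- matrix((1 - R) * 100, 10, 10)
  ad[1, 1] <- R * 2000; dd[1, 1] <- (1 - R) * 2000   # anchor sets the p99
  ad[2, 2] <- R * 1000; dd[2, 2] <- (1 - R) * 1000
  a <- channel_frame(ad, "acceptor", 1); d <- channel_frame(dd, "donor", 1)
  ri <- compute_ratio_image(a, d, 1)
  rgb <- render_pseudocolor(ri, d, a)
  bright <- apply(rgb, c(1, 2), max)
  expect_equal(bright[2, 2] / bright[3, 3], 10, tolerance = 0.01)
})

test_that("degenerate display range is rejected", {
  a <- uniform_frame(200, "acceptor")
  d <- uniform_frame(100, "donor")
  ri <- compute_ratio_image(a, d, 1)
  expect_error(render_pseudocolor(ri, d, a, display_range = c(1, 1)),
               "degenerate")
})

test_that("intact phantoms render red, disintegrated blue", {
  cal <- printed_cal()
  S <- 2000
  mk <- function(integ) {
    R <- eval_calibration(cal, integ)
    list(a = uniform_frame(R * S, "acceptor"),
         d = uniform_frame((1 - R) * S, "donor"))
  }
  hi <- mk(100)
  ri <- compute_ratio_image(hi$a, hi$d, 1)
  rgb <- render_pseudocolor(ri, hi$d, hi$a)
  expect_gt(rgb[1, 1, 1], 0.9)           # red channel dominant
  expect_lt(rgb[1, 1, 3], 0.1)
  lo <- mk(0)
  ri0 <- compute_ratio_image(lo$a, lo$d, 1)
  rgb0 <- render_pseudocolor(ri0, lo$d, lo$a)
  expect_gt(rgb0[1, 1, 3], 0.9)          # blue channel dominant
  expect_lt(rgb0[1, 1, 1], 0.1)
})

test_that("intensity floor estimate tracks pre-injection background", {
  set.seed(8)
  pre <- channel_frame(matrix(rpois(4096, 40) + 0.0, 64, 64), "donor", 0)
  floor_ <- estimate_intensity_floor(pre)
  expect_gt(floor_, 40)
  expect_lt(floor_, 60)
})

test_that("median filter smooths an impulse but preserves uniform frames", {
  d <- matrix(100, 8, 8)
  fr <- channel_frame(d, "donor", 1)
  expect_equal(median_filter3(fr)$data, d)
  d[4, 4] <- 10000
  fr2 <- channel_frame(d, "donor", 1)
  expect_equal(median_filter3(fr2)$data[4, 4], 100)
})
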