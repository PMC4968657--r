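# ROI statistics, background correction, proximity ratio, time courses.

test_that("roi_mean averages the delimited region", {
  mask <- matrix(0L, 8, 8)
  mask[1:4, ] <- 1L
  rois <- roi_set(mask, c(top = 1L))
  fr <- uniform_frame(7)
  expect_equal(roi_mean(fr, rois, "top")$mean, 7)
  expect_equal(roi_mean(fr, rois, "top")$n_pixels, 32)
  # checkerboard averages to the midpoint
  cb <- matrix(c(0, 100), 8, 8)
  expect_equal(roi_mean(channel_frame(cb, "donor", 1), rois, "top")$mean, 50)
  expect_error(roi_mean(fr, rois, "liver"), "unknown region")
})

test_that("background correction floors at zero with a flag", {
  expect_equal(background_correct(150, 50),
               list(corrected = 100, insufficient_signal = FALSE))
  expect_equal(background_correct(50, 50),
               list(corrected = 0, insufficient_signal = TRUE))
  expect_equal(background_correct(40, 50),
               list(corrected = 0, insufficient_signal = TRUE))
  expect_error(background_correct(-1, 0))
})

test_that("proximity ratio follows A/(A+D) and is bounded and monotone", {
  expect_equal(proximity_ratio(3, 1), 0.75)
  expect_equal(proximity_ratio(0, 5), 0)
  expect_equal(proximity_ratio(865.9054, 134.0946), 0.8659054,
               tolerance = 1e-7)
  expect_error(proximity_ratio(0, 0), "undefined")
  # bounded in [0,1], monotone in A at fixed A+D
  total <- 100
  As <- seq(0, total, by = 10)
  Es <- vapply(As, function(A) proximity_ratio(A, total - A), numeric(1))
  expect_true(all(Es >= 0 & Es <= 1))
  expect_true(all(diff(Es) > 0))
})

test_that("noiseless pipeline recovers every scheduled integrity to < 0.1 point", {
  for (name in c("healthy", "tumor_bearing")) {
    scn <- builtin_scenario(name, noise = noise_off())
    study <- simulate_study(scn, seed = 1)
    tc <- integrity_timecourse(study)
    for (i in seq_len(nrow(tc))) {
      sched <- schedule_integrity(scn$regions[[tc$region[i]]], tc$time_h[i])
      if (tc$flag[i] == "ok")
        expect_lt(abs(tc$value[i] - sched), 0.1)
    }
  }
})

test_that("donor-only studies give zero ratio clamped with below-floor flags", {
  scn <- builtin_scenario("donor_only", noise = noise_off())
  tc <- integrity_timecourse(simulate_study(scn, seed = 1),
                             regions = "tail_vein")
  expect_true(all(tc$value == 0))
  expect_true(all(tc$ratio == 0))
  expect_true(all(grepl("below_floor", tc$flag)))
})

test_that("missing pre-injection frames are an error", {
  scn <- builtin_scenario("healthy", noise = noise_off())
  study <- simulate_study(scn, seed = 1)
  study$times <- setdiff(study$times, 0)
  expect_error(integrity_timecourse(study), "pre-injection")
  expect_error(intensity_timecourse(study, "liver"), "pre-injection")
})

test_that("replicate summaries report SEM over subjects", {
  tc1 <- data.frame(region = "liver", quantity = "integrity",
                    time_h = c(1, 6), value = c(99, 65))
  tc2 <- data.frame(region = "liver", quantity = "integrity",
                    time_h = c(1, 6), value = c(98, 67))
  tc3 <- data.frame(region = "liver", quantity = "integrity",
                    time_h = c(1, 6), value = c(100, 66))
  s <- summarize_replicates(list(tc1, tc2, tc3))
  expect_equal(s$n, c(3, 3))
  at6 <- s[s$time_h == 6, ]
  expect_equal(at6$value, 66)
  expect_equal(at6$sem, sd(c(65, 67, 66)) / sqrt(3))
})

test_that("two-sample comparison matches the t-distribution", {
  g <- c(5, 6, 7)
  res <- compare_groups(g, g)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  # independent oracle: pooled t computed by hand against pt()
  a <- c(93, 95, 91); b <- c(66, 64, 68)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  res2 <- compare_groups(a, b)
  expect_equal(res2$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res2$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(res2$p_value, 0.001)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  # Welch flag changes the degrees of freedom
  a2 <- c(1, 2, 3, 4); b2 <- c(10, 30, 50)
  expect_false(isTRUE(all.equal(compare_groups(a2, b2)$df,
                                compare_groups(a2, b2, welch = TRUE)$df)))
})

test_that("noisy healthy recovery stays within 3 points of schedule", {
  # liver at 6 h, default noise, n = 3 phantoms, a handful of seed sets
  set.seed(1)
  scn <- builtin_scenario("healthy")
  hits <- replicate(10, {
    seeds <- sample.int(1e6, 3)
    vals <- vapply(seeds, function(s) {
      tc <- integrity_timecourse(simulate_study(scn, seed = s),
                                 regions = "liver")
      tc$value[tc$time_h == 6]
    }, numeric(1))
    abs(mean(vals) - 66) <= 3
  })
  expect_gte(mean(hits), 0.9)
})
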