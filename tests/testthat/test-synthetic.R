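# Phantom generator: forward model, noise, built-in scenarios.

test_that("expected signal splits total brightness by the calibration ratio", {
  cal <- printed_cal()
  mask <- matrix(TRUE, 4, 4)
  mk <- function(integ) region_spec("r", mask,
    integrity = list(a1 = integ, a2 = integ, x0 = 1, p = 1),
    concentration = list(type = "constant", level = 1), brightness = 1000)
  # constant-integrity schedule: a1 = a2 pins the logistic at that level
  s100 <- expected_signal(mk(100), t = 1, cal)
  expect_equal(s100[["donor"]], 134.0946, tolerance = 1e-4)
  expect_equal(s100[["acceptor"]], 865.9054, tolerance = 1e-4)
  s0 <- expected_signal(mk(0), t = 1, cal)
  expect_equal(s0[["donor"]], 728.88, tolerance = 1e-4)
  expect_equal(s0[["acceptor"]], 271.12, tolerance = 1e-4)
})

test_that("zero concentration gives zero signal in both channels", {
  mask <- matrix(TRUE, 4, 4)
  reg <- region_spec("r", mask,
                     integrity = list(a1 = 100, a2 = 0, x0 = 8, p = 2),
                     concentration = list(type = "constant", level = 0),
                     brightness = 1000)
  expect_equal(unname(expected_signal(reg, 1)), c(0, 0))
})

test_that("donor + acceptor expected signal conserves total brightness", {
  set.seed(11)
  mask <- matrix(TRUE, 4, 4)
  for (i in 1:20) {
    cal <- random_valid_cal()
    br <- runif(1, 100, 5000)
    reg <- region_spec("r", mask,
                       integrity = list(a1 = 100, a2 = 0,
                                        x0 = runif(1, 1, 20),
                                        p = runif(1, 0.5, 4)),
                       concentration = list(type = "exp_decay",
                                            half_time = runif(1, 1, 6)),
                       brightness = br)
    t <- runif(1, 0, 24)
    sig <- expected_signal(reg, t, cal)
    expect_equal(sum(sig), br * schedule_concentration(reg, t),
                 tolerance = 1e-12)
  }
})

test_that("pre-injection frames carry background and noise only", {
  scn <- builtin_scenario("healthy")
  set.seed(5)
  fr <- generate_frame(scn, 0, "acceptor")
  # acceptor background is 4 counts; shot + read noise (with clipping of
  # negative counts at zero) leave the mean within ~1 count
  expect_lt(abs(mean(fr$data) - scn$background_acceptor), 1)
  # no trace of the region schedules: liver pixels same mean as body
  m_liver <- region_mask(scenario_rois(scn), "liver")
  expect_lt(abs(mean(fr$data[m_liver]) - mean(fr$data[!m_liver])), 1)
})

test_that("identical seeds give bit-identical studies", {
  scn <- builtin_scenario("healthy", times = c(0, 1, 6))
  a <- simulate_study(scn, seed = 99)
  b <- simulate_study(scn, seed = 99)
  expect_identical(lapply(a$frames, `[[`, "data"),
                   lapply(b$frames, `[[`, "data"))
  c_ <- simulate_study(scn, seed = 100)
  expect_false(identical(a$frames[["1h_donor"]]$data,
                         c_$frames[["1h_donor"]]$data))
})

test_that("unknown channel tag is rejected", {
  scn <- builtin_scenario("healthy")
  expect_error(generate_frame(scn, 0, "fret"))
  expect_error(generate_frame(scn, 0.5, "donor"), "time grid")
})

test_that("built-in schedules pass through their encoded endpoints", {
  healthy <- builtin_scenario("healthy")
  expect_equal(schedule_integrity(healthy$regions[["liver"]], 6), 66,
               tolerance = 1e-6)
  expect_equal(schedule_integrity(healthy$regions[["liver"]], 8.2), 50,
               tolerance = 1e-6)
  expect_equal(schedule_integrity(healthy$regions[["tail_vein"]], 6), 93,
               tolerance = 1e-6)
  tb <- builtin_scenario("tumor_bearing")
  expect_equal(schedule_integrity(tb$regions[["tumor"]], 2), 77,
               tolerance = 1e-6)
  expect_equal(schedule_integrity(tb$regions[["tumor"]], 4.4), 50,
               tolerance = 1e-6)
  # frozen from the independent root-solve: tumor integrity at 6 h
  expect_equal(schedule_integrity(tb$regions[["tumor"]], 6), 38.335961,
               tolerance = 1e-5)
  expect_equal(schedule_integrity(tb$regions[["tail_vein"]], 6), 71,
               tolerance = 1e-6)
})

test_that("steepness values stored in scenarios solve the endpoint equations", {
  # independent oracle: root-find the logistic steepness through the
  # encoded endpoint and compare to the stored constant
  logi <- function(t, x0, p) 100 / (1 + (t / x0)^p)
  p_liver <- uniroot(function(p) logi(6, 8.2, p) - 66, c(0.1, 10),
                     tol = 1e-12)$root
  p_tumor <- uniroot(function(p) logi(2, 4.4, p) - 77, c(0.1, 10),
                     tol = 1e-12)$root
  healthy <- builtin_scenario("healthy")
  tb <- builtin_scenario("tumor_bearing")
  expect_equal(healthy$regions[["liver"]]$integrity$p, p_liver,
               tolerance = 1e-8)
  expect_equal(tb$regions[["tumor"]]$integrity$p, p_tumor,
               tolerance = 1e-8)
})

test_that("donor-only scenario puts no carrier signal in the acceptor channel", {
  scn <- builtin_scenario("donor_only", noise = noise_off())
  fr_a <- generate_frame(scn, 1, "acceptor")
  expect_true(all(fr_a$data == scn$background_acceptor))
  fr_d <- generate_frame(scn, 1, "donor")
  m <- region_mask(scenario_rois(scn), "tail_vein")
  expect_gt(mean(fr_d$data[m]), scn$background_donor + 100)
})

test_that("calibration plate generator matches the law and validates levels", {
  cal <- printed_cal()
  plate <- generate_calibration_plate(cal, c(0, 100), sd = 0)
  expect_equal(sort(unique(plate$ratio)), c(0.27112, 0.8659053635),
               tolerance = 1e-9)
  expect_equal(nrow(plate), 6)  # triplicate
  set.seed(21)
  p1 <- generate_calibration_plate(cal, seq(0, 100, 10), sd = 0.005)
  set.seed(21)
  p2 <- generate_calibration_plate(cal, seq(0, 100, 10), sd = 0.005)
  expect_identical(p1$ratio, p2$ratio)
  expect_error(generate_calibration_plate(cal, c(0, 150)), "\\[0, 100\\]")
})

test_that("scenario validation catches bad time grids and overlapping regions", {
  mask <- matrix(TRUE, 8, 8)
  reg <- region_spec("a", mask, integrity = NULL,
                     concentration = list(type = "constant", level = 1),
                     brightness = 10)
  expect_error(scenario("x", list(reg), times = c(1, 2), dim = c(8L, 8L)),
               "pre-injection")
  expect_error(scenario("x", list(reg), times = c(0, 2, 2), dim = c(8L, 8L)),
               "strictly increasing")
  reg2 <- region_spec("b", mask, integrity = NULL,
                      concentration = list(type = "constant", level = 1),
                      brightness = 10)
  expect_error(scenario("x", list(reg, reg2), times = c(0, 1),
                        dim = c(8L, 8L)),
               "disjoint")
})
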