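# Shared fixtures: small scenarios and frames built in code.

printed_cal <- function() calibration_params(a = 0.14572, b = 0.1254,
                                             c = 0.01748)

# a tiny scenario (fast to simulate) with one uniform square region
tiny_scenario <- function(noise = noise_off(), brightness = 1000,
                          integrity = list(a1 = 100, a2 = 0, x0 = 8.2,
                                           p = 2.1233929930),
                          times = c(0, 1, 2, 3, 6, 24)) {
  mask <- matrix(FALSE, 32L, 32L)
  mask[8:24, 8:24] <- TRUE
  reg <- region_spec("patch", mask, integrity = integrity,
                     concentration = list(type = "constant", level = 1),
                     brightness = brightness)
  scenario("tiny", list(reg), noise = noise, times = times,
           dim = c(32L, 32L))
}

uniform_frame <- function(value, channel = "donor", time_h = 1,
                          dim = c(8L, 8L)) {
  channel_frame(matrix(value, dim[1], dim[2]), channel, time_h)
}

random_valid_cal <- function() {
  a <- runif(1, 0.05, 0.3)
  b <- runif(1, 0.05, min(0.5, 0.95 - a))
  c <- runif(1, 0.005, 0.025)
  calibration_params(a = a, b = b, c = c)
}
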