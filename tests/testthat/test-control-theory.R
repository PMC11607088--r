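test_that("open-loop transfer is the product of its printed factors", {
  cfg <- ultrafast_config()
  f <- 20
  # term-by-term oracle
  s <- 2i * pi * f
  expo <- (1 - exp(-s * cfg$t_integration)) / (s * cfg$t_integration)
  delay <- exp(-s * cfg$t_delay) / s
  dm <- 1 / (1 + cfg$t_dm * f)
  g <- open_loop_transfer(cfg, f)
  expect_equal(g, expo * delay * dm * 233, tolerance = 1e-12)
  expect_equal(Mod(g), Mod(expo) * Mod(delay) * dm * 233,
               tolerance = 1e-12)
  # integrator pole: |G| ~ rate*gain/(2 pi f) as f -> 0
  expect_equal(Mod(open_loop_transfer(cfg, 1e-4)),
               233 / (2 * pi * 1e-4), tolerance = 1e-3)
  # sinc limit: vanishing integration time
  cfg0 <- loop_config(0, 2.42e-3, 0.55e-3, 233, 1)
  s10 <- 2i * pi * 10
  expect_equal(open_loop_transfer(cfg0, 10),
               exp(-s10 * cfg0$t_delay) / s10 / (1 + cfg0$t_dm * 10) * 233,
               tolerance = 1e-6)
  expect_error(open_loop_transfer(cfg, -1), "positive")
})

test_that("rejection curve has perfect DC rejection and the low-f asymptote", {
  cfg <- ultrafast_config()
  rc <- rejection_power_curve(cfg, c(1e-4, 1, 10))
  expect_lt(rc$power_rejection[1], 1e-11)
  # (2 pi f / (rate*gain))^2 asymptote at 1 Hz, rate*gain = 233
  expect_equal(rc$power_rejection[2], (2 * pi / 233)^2, tolerance = 0.05)
  expect_equal(round(rc$power_rejection[2], 5), 7.3e-4, tolerance = 1e-4)
  expect_error(rejection_power_curve(cfg, c(2, 1)), "increasing")
})

test_that("bandwidth equation root and unity crossing agree", {
  for (cfg in list(ultrafast_config(), continuous_config(),
                   conventional_config())) {
    f1 <- ao_bandwidth(cfg, "unity_crossing")$f_c
    f2 <- ao_bandwidth(cfg, "eq2_root")$f_c
    expect_lt(abs(f1 - f2), 0.1)
    # at f_c the rejection reaches unity
    rc <- rejection_power_curve(cfg, f1)
    expect_equal(rc$power_rejection, 1, tolerance = 1e-3)
  }
})

test_that("bandwidths match the reference configurations", {
  expect_equal(ao_bandwidth(ultrafast_config())$f_c, 35.0,
               tolerance = 0.001)
  expect_equal(ao_bandwidth(continuous_config())$f_c, 28.2,
               tolerance = 0.003)
  expect_equal(ao_bandwidth(conventional_config())$f_c, 1.4,
               tolerance = 0.005)
})

test_that("bandwidth increases strictly with the rate-gain product", {
  curve <- bandwidth_vs_rate_gain(ultrafast_config(),
                                  seq(10, 500, length.out = 10))
  expect_true(all(diff(curve$f_c_hz) > 0))
  # doubling the product increases f_c
  two <- bandwidth_vs_rate_gain(ultrafast_config(), c(233, 466))
  expect_gt(two$f_c_hz[2], two$f_c_hz[1])
  # the printed products reproduce the printed bandwidths
  pp <- bandwidth_vs_rate_gain(ultrafast_config(), c(153.9, 233))
  expect_equal(pp$f_c_hz, c(28.2, 35.0), tolerance = 0.005)
})

test_that("delay-free loop reduces to the pure-integrator closed form", {
  cfg <- loop_config(0, 0, 0, 100, 1)
  f <- c(0.5, 2, 10, 40)
  rc <- rejection_power_curve(cfg, f)
  s <- 2i * pi * f
  expect_equal(rc$power_rejection, Mod(s / (s + 100))^2, tolerance = 1e-6)
})

test_that("rejection and noise transfer sum to one as complex functions", {
  cfg <- ultrafast_config()
  f <- c(0.1, 1, 10, 35, 80)
  g <- open_loop_transfer(cfg, f)
  h_rej <- 1 / (1 + g)
  h_noise <- g / (1 + g)
  expect_equal(h_rej + h_noise, rep(1 + 0i, length(f)), tolerance = 1e-12)
  rc <- rejection_power_curve(cfg, f)
  nc <- noise_transfer_power_curve(cfg, f)
  expect_equal(rc$power_rejection, Mod(h_rej)^2, tolerance = 1e-12)
  expect_equal(nc$power_noise, Mod(h_noise)^2, tolerance = 1e-12)
})

test_that("noise transfer barely amplifies for the ultrafast loop", {
  f <- seq(0.05, 116, length.out = 2000)
  nc <- noise_transfer_power_curve(ultrafast_config(), f)
  expect_equal(nc$power_noise[1], 1, tolerance = 0.01)   # follows noise at DC
  expect_lte(max(nc$power_noise), 1.2)
  # a continuous two-frame-delay loop at gain 1 amplifies strongly
  two_frame <- loop_config(1 / 342, 1 / 342, 0.55e-3, 342, 1, "continuous")
  f2 <- seq(0.05, 171, length.out = 2000)
  nc2 <- noise_transfer_power_curve(two_frame, f2)
  expect_gt(max(nc2$power_noise), max(nc$power_noise))
})

test_that("low-frequency rejection ratios reproduce the improvement factors", {
  expect_equal(low_frequency_rejection_ratio(conventional_config(),
                                             ultrafast_config()),
               (233 / 10)^2, tolerance = 0.01)
  expect_gte(low_frequency_rejection_ratio(conventional_config(),
                                           ultrafast_config()), 500)
  # standard-family loops at 10 vs 200 Hz: low-f limit (200/10)^2 = 400
  slow <- loop_config(0.05, 0.05, 0.55e-3, 10, 1)
  fast <- loop_config(2.5e-3, 2.5e-3, 0.55e-3, 200, 1)
  r10 <- rejection_power_curve(slow, 1e-3)$power_rejection
  r200 <- rejection_power_curve(fast, 1e-3)$power_rejection
  expect_equal(r10 / r200, 400, tolerance = 0.001)
  # identical configs -> 1
  expect_equal(low_frequency_rejection_ratio(ultrafast_config(),
                                             ultrafast_config()), 1,
               tolerance = 1e-9)
})

test_that("noise propagation through the ultrafast loop is near-unity", {
  out_um <- noise_propagated_rms(0.100, ultrafast_config(), 0.790)
  expect_equal(1e3 * out_um, 12.6, tolerance = 0.02 * 12.6)
  expect_identical(noise_propagated_rms(0, ultrafast_config()), 0)
  expect_equal(noise_propagated_rms(0.2, ultrafast_config()), 2 * out_um,
               tolerance = 1e-9)
  expect_error(noise_propagated_rms(-0.1, ultrafast_config()),
               "non-negative")
})
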