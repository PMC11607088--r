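test_that("PSD estimation follows the stated DFT convention", {
  fs <- 342; n <- 1024
  tt <- (0:(n - 1)) / fs
  f0 <- 32 * fs / n                       # a Fourier bin frequency
  x <- ao_series(tt, matrix(sin(2 * pi * f0 * tt), ncol = 1), fs)
  sp <- estimate_psd(x)
  # one-sided power of a unit sinusoid is A^2/2 = 0.5, all in one bin
  expect_equal(sum(sp$psd) * sp$spectral_resolution, 0.5, tolerance = 1e-9)
  expect_equal(sp$frequencies[which.max(sp$psd)], f0)
  expect_equal(sp$spectral_resolution, fs / n)
  # zero series -> zero PSD
  z <- estimate_psd(ao_series(tt, matrix(0, n, 1), fs))
  expect_true(all(z$psd == 0))
  expect_error(estimate_psd(ao_series((0:99) / fs, matrix(0, 100, 1), fs)),
               "128")
})

test_that("white noise yields a flat spectrum at the expected level", {
  fs <- 342; n <- 4096
  set.seed(31)
  x <- ao_series((0:(n - 1)) / fs, matrix(stats::rnorm(n * 20, 0, 0.5),
                                          n, 20), fs)
  sp <- estimate_psd(x)
  # E[PSD] = sigma^2 / Nyquist everywhere
  expect_equal(mean(sp$psd), 0.25 / (fs / 2), tolerance = 0.05)
  lo <- mean(sp$psd[sp$frequencies < 50])
  hi <- mean(sp$psd[sp$frequencies > 120])
  expect_equal(lo / hi, 1, tolerance = 0.1)
})

test_that("Parseval holds exactly for deterministic inputs", {
  fs <- 233; n <- 2048
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 3.2 * tt) + 0.3 * cos(2 * pi * 40.7 * tt + 1)
  sp <- estimate_psd(ao_series(tt, matrix(x, ncol = 1), fs))
  expect_equal(sum(sp$psd) * sp$spectral_resolution,
               mean((x - mean(x))^2), tolerance = 0.01)
})

test_that("rejection measurement is the closed/open PSD ratio", {
  fs <- 233; n <- 1024
  set.seed(17)
  x <- matrix(stats::rnorm(n), ncol = 1)
  a <- estimate_psd(ao_series((0:(n - 1)) / fs, x, fs))
  expect_equal(measure_rejection_curve(a, a)$power_rejection,
               rep(1, length(a$psd)))
  zero <- estimate_psd(ao_series((0:(n - 1)) / fs, 0 * x, fs))
  expect_true(all(measure_rejection_curve(a, zero)$power_rejection == 0))
  short <- estimate_psd(ao_series((0:(n / 2 - 1)) / fs,
                                  x[1:(n / 2), , drop = FALSE], fs))
  expect_error(measure_rejection_curve(a, short), "grids")
})

test_that("temporal error integrates the filtered spectrum", {
  mdl <- scenario_psd_model("no_cycloplegia")
  ser <- synthesize_series_from_psd(mdl, duration = 5, n_channels = 5,
                                    seed = 12)
  spec <- estimate_psd(ser)
  # identity rejection returns the series RMS
  ones <- structure(list(frequencies = spec$frequencies,
                         power_rejection = rep(1, length(spec$psd))),
                    class = "rejection_curve")
  sig <- temporal_error(spec, ones)$sigma_temporal
  rms <- sqrt(mean(apply(ser$values, 2,
                         function(x) mean((x - mean(x))^2))))
  expect_equal(sig, rms, tolerance = 0.01)
  # zero spectrum -> zero error
  zspec <- spec; zspec$psd <- 0 * zspec$psd
  expect_equal(temporal_error(zspec, ones)$sigma_temporal, 0)
  # a faster loop always leaves less residual
  slow <- rejection_power_curve(loop_config(0.05, 0.05, 0.55e-3, 10, 1),
                                spec$frequencies)
  fast <- rejection_power_curve(loop_config(2.5e-3, 2.5e-3, 0.55e-3, 200, 1),
                                spec$frequencies)
  expect_lt(temporal_error(spec, fast)$sigma_temporal,
            temporal_error(spec, slow)$sigma_temporal)
})

test_that("required loop rate is found on the grid and is monotone", {
  thr <- diffraction_limit_rms(optical_config())
  grid <- c(5, 10, 20, 40, 80, 160, 342)
  # a spectrum built to sit exactly at the 10 Hz threshold requires 10 Hz
  cfg10 <- loop_config(0.05, 0.05, 0.55e-3, 10, 1)
  at10 <- diffraction_threshold_psd(cfg10, template_exponent = 1,
                                    threshold = thr)
  expect_equal(required_loop_rate(at10, thr * 1.0000001, grid), 10)
  # zero spectrum: the smallest rate suffices
  z <- at10; z$psd <- 0 * z$psd
  expect_equal(required_loop_rate(z, thr, grid), 5)
  # scaling the spectrum up never lowers the requirement
  big <- at10; big$psd <- 100 * big$psd
  expect_gte(required_loop_rate(big, thr, grid),
             required_loop_rate(at10, thr, grid))
  expect_identical(required_loop_rate(big, 1e-9, grid), Inf)
  expect_error(required_loop_rate(at10, thr, numeric(0)), "non-empty")
})

test_that("diffraction-threshold spectra are self-consistent and ordered", {
  thr <- diffraction_limit_rms(optical_config())
  conv <- diffraction_threshold_psd(conventional_config(), 1, thr)
  uf <- diffraction_threshold_psd(ultrafast_config(), 1, thr)
  # feeding the curve back through the filter returns the threshold
  rej <- rejection_power_curve(conventional_config(), conv$frequencies)
  expect_equal(temporal_error(conv, rej)$sigma_temporal, thr,
               tolerance = 1e-3)
  # the ultrafast threshold lies strictly above the conventional one
  expect_true(all(uf$psd > conv$psd))
  # doubling the threshold quadruples the template scale
  conv2 <- diffraction_threshold_psd(conventional_config(), 1, 2 * thr)
  expect_equal(conv2$psd / conv$psd, rep(4, length(conv$psd)),
               tolerance = 1e-9)
})
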