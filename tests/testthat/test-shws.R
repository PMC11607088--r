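test_that("default lenslet geometry has 300 active lenslets", {
  g <- lenslet_geometry()
  expect_equal(g$n_active, 300L)
  expect_equal(g$grid, 20L)
  expect_equal(g$superpixel_um, 500 / 45)
  # shrinking the pupil reduces the active count
  g2 <- lenslet_geometry(magnification = 1)
  expect_lt(g2$n_active, 300L)
})

test_that("flat wavefront renders spots at the reference positions", {
  geom <- small_geom(); cfg <- sensor_config()
  basis <- small_basis()
  wf <- wavefront_state(rep(0, basis$mode_count), basis)
  fr <- render_frame(wf, geom, cfg, noise = FALSE)
  sl <- centroid_tcog(fr, geom, cfg)
  expect_true(all(sl$table$valid))
  expect_lt(max(abs(c(sl$table$dx_px, sl$table$dy_px))), 0.05)
})

test_that("pure tilt displaces spots by focal length times slope", {
  geom <- small_geom()
  cfg <- sensor_config()
  basis <- build_zernike_basis(2, exclude_piston_tip_tilt = FALSE)
  # x-tilt mode (n = 1, m = 1): W = 2 c rho cos(theta), slope = 2c / R
  r_um <- geom$pupil_radius_at_array_mm * 1e3
  slope <- 1e-3                      # 1 mrad of wavefront tilt at the array
  coef <- rep(0, basis$mode_count)
  coef[basis$n == 1 & basis$m == 1] <- slope * r_um / 2
  wf <- wavefront_state(coef, basis)
  fr <- render_frame(wf, geom, cfg, noise = FALSE)
  sl <- centroid_tcog(fr, geom, cfg)
  disp_um <- mean(sl$table$dx_px) * geom$superpixel_um
  # TCoG carries a small sub-pixel bias; geometry agreement within 5%
  expect_equal(disp_um, geom$focal_mm * 1e3 * slope, tolerance = 0.05)
  expect_lt(max(abs(sl$table$dy_px)), 0.05)
})

test_that("photon statistics match the configured expectation", {
  # read noise is clipped at zero and would bias a whole-frame photon sum;
  # count photons with the read-noise-free sensor
  geom <- small_geom(); cfg <- sensor_config(read_noise_e = 0)
  basis <- small_basis()
  wf <- wavefront_state(rep(0, basis$mode_count), basis)
  counts <- numeric(0)
  for (s in 1:25) {
    fr <- render_frame(wf, geom, cfg, seed = s)
    counts <- c(counts, sum(fr$pixels) / cfg$adu_per_electron /
                  geom$n_active)
  }
  n_lenslet_frames <- 25 * geom$n_active
  se <- sqrt(cfg$photons_per_lenslet / n_lenslet_frames)
  expect_lt(abs(mean(counts) - cfg$photons_per_lenslet), 3 * se + 0.5)
  # identical seed reproduces the identical frame
  f1 <- render_frame(wf, geom, cfg, seed = 9)
  f2 <- render_frame(wf, geom, cfg, seed = 9)
  expect_identical(f1$pixels, f2$pixels)
})

test_that("centroiding recovers known sub-pixel offsets", {
  geom <- small_geom(); cfg <- sensor_config()
  basis <- build_zernike_basis(2, exclude_piston_tip_tilt = FALSE)
  r_um <- geom$pupil_radius_at_array_mm * 1e3
  px_to_coef <- geom$superpixel_um / (geom$focal_mm * 1e3) * r_um / 2
  coef <- rep(0, basis$mode_count)
  coef[basis$n == 1 & basis$m == 1] <- 0.30 * px_to_coef
  coef[basis$n == 1 & basis$m == -1] <- -0.20 * px_to_coef
  wf <- wavefront_state(coef, basis)
  fr <- render_frame(wf, geom, cfg, noise = FALSE)
  sl <- centroid_tcog(fr, geom, cfg)
  expect_lt(abs(mean(sl$table$dx_px) - 0.30), 0.05)
  expect_lt(abs(mean(sl$table$dy_px) + 0.20), 0.05)
})

test_that("a dark sub-aperture is marked invalid without affecting others", {
  geom <- small_geom(); cfg <- sensor_config()
  basis <- small_basis()
  wf <- wavefront_state(rep(0, basis$mode_count), basis)
  fr <- render_frame(wf, geom, cfg, noise = FALSE)
  spn <- geom$superpixels
  fr$pixels[1:spn, 1:spn] <- 0   # darken the first tile
  sl <- centroid_tcog(fr, geom, cfg)
  dark <- sl$table$row == 1 & sl$table$col == 1
  expect_false(any(sl$table$valid[dark]))
  expect_true(all(sl$table$valid[!dark]))
  expect_lt(max(abs(sl$table$dx_px[!dark])), 0.05)
})

test_that("blink detection applies the inclusive 50% rule", {
  geom <- lenslet_geometry(); cfg <- sensor_config()
  fake <- function(peaks) {
    tab <- data.frame(row = 1, col = seq_along(peaks), dx_px = 0, dy_px = 0,
                      slope_x = 0, slope_y = 0, peak = peaks, valid = TRUE)
    structure(list(table = tab, geom = geom), class = "slope_set")
  }
  expect_false(detect_blink(fake(rep(800, 300)), cfg))
  expect_true(detect_blink(fake(c(rep(600, 151), rep(800, 149))), cfg))
  expect_true(detect_blink(fake(c(rep(600, 150), rep(800, 150))), cfg))
  expect_false(detect_blink(fake(c(rep(600, 149), rep(800, 151))), cfg))
  # monotone: dimming more lenslets never un-flags a blink
  base <- c(rep(600, 150), rep(800, 150))
  expect_true(detect_blink(fake(base), cfg))
  expect_true(detect_blink(fake(pmin(base, 500)), cfg))
})

test_that("reconstruction inverts the slope forward model", {
  geom <- small_geom(); basis <- small_basis()
  # zero slopes -> zero wavefront
  tab <- data.frame(row = 1, col = 1:geom$n_active, dx_px = 0, dy_px = 0,
                    slope_x = 0, slope_y = 0, peak = 1000, valid = TRUE)
  zero <- structure(list(table = tab, geom = geom), class = "slope_set")
  wf0 <- reconstruct_wavefront(zero, basis, geom)
  expect_equal(wf0$rms, 0)
  # slopes generated from known coefficients recover them
  set.seed(3)
  coef <- stats::rnorm(basis$mode_count, 0, 0.05)
  G <- aoloop:::subap_gradient_matrix(geom, basis)
  tab$slope_x <- as.numeric(G$gx %*% coef)
  tab$slope_y <- as.numeric(G$gy %*% coef)
  sl <- structure(list(table = tab, geom = geom), class = "slope_set")
  rec <- reconstruct_wavefront(sl, basis, geom)
  expect_lt(sqrt(sum((rec$coefficients - coef)^2)) / sqrt(sum(coef^2)),
            0.01)
  # a single mode's coefficient is the reported RMS (RMS-normalized basis)
  c1 <- rep(0, basis$mode_count); c1[1] <- 0.123   # defocus
  tab$slope_x <- as.numeric(G$gx %*% c1)
  tab$slope_y <- as.numeric(G$gy %*% c1)
  sl1 <- structure(list(table = tab, geom = geom), class = "slope_set")
  expect_equal(reconstruct_wavefront(sl1, basis, geom)$rms, 0.123,
               tolerance = 1e-6)
})

test_that("full render-centroid-reconstruct round trip is accurate", {
  geom <- full_geom(); basis <- full_basis(); cfg <- sensor_config()
  set.seed(21)
  coef <- stats::rnorm(basis$mode_count, 0, 0.3 / sqrt(basis$mode_count))
  wf <- wavefront_state(coef, basis)
  fr <- render_frame(wf, geom, cfg, noise = FALSE)
  rec <- reconstruct_wavefront(centroid_tcog(fr, geom, cfg), basis, geom)
  expect_lt(sqrt(sum((rec$coefficients - coef)^2)) / wf$rms, 0.02)
})

test_that("noise budget reproduces the calibrated sensing errors", {
  nb <- sensing_noise_budget(sensor_config(), lenslet_geometry())
  expect_equal(nb$sigma_photon, 0.100, tolerance = 0.001)
  expect_equal(nb$sigma_readout, 0.010, tolerance = 0.0005)
  expect_equal(nb$sigma_total,
               sqrt(nb$sigma_photon^2 + nb$sigma_readout^2))
  # 4x photons halve the shot-noise term
  nb4 <- sensing_noise_budget(sensor_config(photons_per_lenslet = 4 * 1962))
  expect_equal(nb4$sigma_photon, nb$sigma_photon / 2)
  # zero read noise removes the readout term
  nb0 <- sensing_noise_budget(sensor_config(read_noise_e = 0))
  expect_equal(nb0$sigma_readout, 0)
  expect_error(sensing_noise_budget(sensor_config(photons_per_lenslet = 0)))
})

test_that("centroid error scales as one over root photon count", {
  geom <- small_geom(); basis <- small_basis()
  wf <- wavefront_state(rep(0, basis$mode_count), basis)
  # photon-count scaling: read noise off so shot noise is the only source
  photons <- c(150, 1000, 8000)
  sds <- vapply(photons, function(np) {
    cfg <- sensor_config(photons_per_lenslet = np, read_noise_e = 0,
                         global_threshold = 0)
    disp <- numeric(0)
    for (s in 1:6) {
      sl <- centroid_tcog(render_frame(wf, geom, cfg, seed = s), geom, cfg)
      disp <- c(disp, sl$table$dx_px[sl$table$valid])
    }
    stats::sd(disp)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(photons)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.12)
})

test_that("frames and slopes round-trip through their file formats", {
  geom <- small_geom(); cfg <- sensor_config()
  wf <- wavefront_state(rep(0, small_basis()$mode_count), small_basis())
  fr <- render_frame(wf, geom, cfg, seed = 1)
  sl <- centroid_tcog(fr, geom, cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_slopes_csv(sl, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$slope_x, sl$table$slope_x)
  skip_if_not_installed("tiff")
  tf <- withr::local_tempfile(fileext = ".tif")
  write_frame_tiff(fr, tf)
  img <- tiff::readTIFF(tf)
  expect_equal(dim(img), dim(fr$pixels))
  expect_equal(max(img) * (2^cfg$bit_depth - 1), max(fr$pixels),
               tolerance = 1e-3)
})
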