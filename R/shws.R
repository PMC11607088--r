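#' Shack-Hartmann lenslet array geometry
#'
#' A square microlens array sampling a magnified image of the eye pupil.
#' Active lenslets are those whose centers fall inside the pupil circle at
#' the array; with the defaults (20 x 20 array, 0.5 mm pitch, 6.7 mm eye
#' pupil relayed at 1.4627x magnification, i.e. 9.8 mm at the array) there
#' are exactly 300 active lenslets. Each sub-aperture image is sampled by
#' 45 x 45 super-pixels.
#'
#' @param grid Lenslets per side (default 20).
#' @param pitch_mm Lenslet pitch, millimetres (default 0.5).
#' @param focal_mm Lenslet focal length, millimetres (default 13.9).
#' @param eye_pupil_mm Eye pupil diameter, millimetres (default 6.7).
#' @param magnification Pupil relay magnification eye -> array
#'   (default 9.8/6.7).
#' @param superpixels Super-pixels per sub-aperture side (default 45).
#' @return Object of class `lenslet_geometry` with center coordinates (mm
#'   at the array and unit-pupil), the active mask, and derived pixel sizes.
#' @export
lenslet_geometry <- function(grid = 20L, pitch_mm = 0.5, focal_mm = 13.9,
                             eye_pupil_mm = 6.7,
                             magnification = 9.8 / 6.7,
                             superpixels = 45L) {
  if (grid < 2 || pitch_mm <= 0 || focal_mm <= 0 || eye_pupil_mm <= 0)
    stop("invalid lenslet geometry")
  idx <- expand.grid(col = seq_len(grid), row = seq_len(grid))
  off <- (seq_len(grid) - (grid + 1) / 2) * pitch_mm
  cx <- off[idx$col]; cy <- off[idx$row]
  r_arr <- eye_pupil_mm * magnification / 2
  active <- sqrt(cx^2 + cy^2) <= r_arr
  structure(list(grid = as.integer(grid), pitch_mm = pitch_mm,
                 focal_mm = focal_mm, eye_pupil_mm = eye_pupil_mm,
                 magnification = magnification,
                 superpixels = as.integer(superpixels),
                 pupil_radius_at_array_mm = r_arr,
                 centers_mm = cbind(x = cx, y = cy),
                 rowcol = cbind(row = idx$row, col = idx$col),
                 active = active,
                 n_active = sum(active),
                 superpixel_um = pitch_mm * 1e3 / superpixels),
            class = "lenslet_geometry")
}

#' @export
print.lenslet_geometry <- function(x, ...) {
  cat(sprintf(
    "lenslet_geometry: %dx%d, pitch %.3g mm, f %.3g mm, %d active lenslets\n",
    x$grid, x$grid, x$pitch_mm, x$focal_mm, x$n_active))
  invisible(x)
}

#' Shack-Hartmann sensor and centroiding configuration
#'
#' Signal, noise and centroiding parameters for the synthetic sensor.
#' `diffraction_spot_px` and `read_noise_area_px2` are the geometric
#' constants of the noise-budget formulas, calibrated so that the default
#' photon count and read noise reproduce sensing errors of 0.100 rad
#' (photon) and 0.010 rad (readout).
#'
#' @param integration_time Exposure, seconds (default 0.126 ms).
#' @param photons_per_lenslet Expected detected photons per lenslet per
#'   frame (default 1962).
#' @param read_noise_e RMS read noise, electrons (default 2).
#' @param bit_depth Digitization depth (default 12).
#' @param adu_per_electron Digital counts per electron (default 8).
#' @param global_threshold Counts subtracted frame-wide with the calibration
#'   image (default 12).
#' @param adaptive_fraction Fraction of the window peak subtracted as the
#'   adaptive threshold (default 0.30).
#' @param window_superpixels Centroiding window side, odd (default 11).
#' @param blink_peak_threshold Counts below which a focal spot is "dim"
#'   (default 700).
#' @param blink_fraction Fraction of dim spots that flags a blink
#'   (default 0.5).
#' @param spot_sigma Gaussian focal-spot sigma, super-pixels (default 1.5).
#' @param diffraction_spot_px Diffraction-limited spot size constant used by
#'   the noise budget, super-pixels.
#' @param read_noise_area_px2 Effective readout-noise area, super-pixels^2.
#' @return Object of class `sensor_config`.
#' @export
sensor_config <- function(integration_time = 0.126e-3,
                          photons_per_lenslet = 1962,
                          read_noise_e = 2, bit_depth = 12L,
                          adu_per_electron = 8,
                          global_threshold = 12,
                          adaptive_fraction = 0.30,
                          window_superpixels = 11L,
                          blink_peak_threshold = 700,
                          blink_fraction = 0.5,
                          spot_sigma = 1.5,
                          diffraction_spot_px = 1.771483,
                          read_noise_area_px2 = 9.58060) {
  if (adaptive_fraction <= 0 || adaptive_fraction >= 1)
    stop("'adaptive_fraction' must be in (0, 1)")
  if (window_superpixels %% 2 != 1) stop("'window_superpixels' must be odd")
  structure(list(integration_time = integration_time,
                 photons_per_lenslet = photons_per_lenslet,
                 read_noise_e = read_noise_e,
                 bit_depth = as.integer(bit_depth),
                 adu_per_electron = adu_per_electron,
                 global_threshold = global_threshold,
                 adaptive_fraction = adaptive_fraction,
                 window_superpixels = as.integer(window_superpixels),
                 blink_peak_threshold = blink_peak_threshold,
                 blink_fraction = blink_fraction,
                 spot_sigma = spot_sigma,
                 diffraction_spot_px = diffraction_spot_px,
                 read_noise_area_px2 = read_noise_area_px2),
            class = "sensor_config")
}

# quadrature points spanning each active sub-aperture (unit-pupil coords)
subap_points <- function(geom, nq = 5L) {
  r_arr <- geom$pupil_radius_at_array_mm
  offs <- ((seq_len(nq) - 0.5) / nq - 0.5) * geom$pitch_mm
  act <- which(geom$active)
  px <- outer(geom$centers_mm[act, "x"], offs, "+") / r_arr
  py <- outer(geom$centers_mm[act, "y"], offs, "+") / r_arr
  list(px = px, py = py, n = length(act), nq = nq)
}

.grad_cache <- new.env(parent = emptyenv())

# mean Zernike gradients over each active sub-aperture; slope units
# (dimensionless wavefront slope at the array per um of coefficient);
# memoized on the geometry/basis signature
subap_gradient_matrix <- function(geom, basis, nq = 5L) {
  key <- paste(geom$grid, geom$pitch_mm, geom$magnification,
               geom$eye_pupil_mm, basis$mode_count,
               basis$max_radial_order, nq, sep = "|")
  hit <- .grad_cache[[key]]
  if (!is.null(hit)) return(hit)
  sp <- subap_points(geom, nq)
  gx <- matrix(0, sp$n, basis$mode_count)
  gy <- matrix(0, sp$n, basis$mode_count)
  for (i in seq_len(nq)) for (j in seq_len(nq)) {
    g <- zernike_gradient(basis, sp$px[, i], sp$py[, j])
    gx <- gx + g$dx; gy <- gy + g$dy
  }
  r_um <- geom$pupil_radius_at_array_mm * 1e3
  out <- list(gx = gx / (nq^2 * r_um), gy = gy / (nq^2 * r_um))
  .grad_cache[[key]] <- out
  out
}

#' Render a synthetic Shack-Hartmann frame
#'
#' Forward model of the sensor: for each active lenslet a Gaussian focal
#' spot is displaced from its reference position by
#' `focal_length x (mean wavefront slope over the sub-aperture)`; the spot
#' energy is Poisson-distributed around the expected photon count, Gaussian
#' read noise is added per super-pixel, and the image is digitized and
#' clipped to the sensor bit depth. Deterministic for a given seed.
#'
#' @param wavefront A [wavefront_state()] (its basis is used for slopes).
#' @param geom A [lenslet_geometry()].
#' @param cfg A [sensor_config()].
#' @param seed Integer seed (default 0).
#' @param noise Include photon/read noise and quantization (default TRUE);
#'   `FALSE` renders the noiseless expected image.
#' @return Object of class `sensor_frame`: integer `pixels` matrix
#'   (rows = y) plus the configuration used.
#' @export
render_frame <- function(wavefront, geom, cfg = sensor_config(), seed = 0L,
                         noise = TRUE) {
  stopifnot(inherits(wavefront, "wavefront_state"),
            inherits(geom, "lenslet_geometry"))
  basis <- wavefront$basis
  if (is.null(basis)) stop("wavefront state carries no basis")
  G <- subap_gradient_matrix(geom, basis)
  sx <- as.numeric(G$gx %*% wavefront$coefficients)   # dimensionless slope
  sy <- as.numeric(G$gy %*% wavefront$coefficients)
  dx_px <- sx * geom$focal_mm * 1e3 / geom$superpixel_um
  dy_px <- sy * geom$focal_mm * 1e3 / geom$superpixel_um

  spn <- geom$superpixels
  npix <- geom$grid * spn
  frame <- matrix(0, npix, npix)
  act <- which(geom$active)
  edges <- 0:spn
  render_one <- function(k) {
    cx <- spn / 2 + dx_px[k]; cy <- spn / 2 + dy_px[k]
    wx <- diff(stats::pnorm(edges, mean = cx, sd = cfg$spot_sigma))
    wy <- diff(stats::pnorm(edges, mean = cy, sd = cfg$spot_sigma))
    outer(wy, wx)
  }
  run <- function() {
    for (k in seq_along(act)) {
      w <- render_one(k) * cfg$photons_per_lenslet
      if (noise) w[] <- stats::rpois(length(w), w)
      rc <- geom$rowcol[act[k], ]
      rows <- (rc["row"] - 1) * spn + seq_len(spn)
      cols <- (rc["col"] - 1) * spn + seq_len(spn)
      frame[rows, cols] <<- frame[rows, cols] + w
    }
    if (noise)
      frame[] <- frame + stats::rnorm(length(frame), 0, cfg$read_noise_e)
    dn <- frame * cfg$adu_per_electron
    dn <- round(pmin(pmax(dn, 0), 2^cfg$bit_depth - 1))
    dn
  }
  pix <- if (noise) with_seed(seed, run()) else run()
  structure(list(pixels = pix, timestamp = wavefront$timestamp,
                 geom = geom, cfg = cfg, noise = noise),
            class = "sensor_frame")
}

#' Two-step thresholding center-of-gravity (TCoG) centroiding
#'
#' Implements the four-step spot localization used for fast wavefront
#' sensing: (1) subtract the calibration image plus a global threshold,
#' clipping at zero; (2) locate the highest-intensity super-pixel in each
#' sub-aperture (ties broken by first occurrence in row-major order);
#' (3) within an 11 x 11 super-pixel window centered on that pixel (clipped
#' at the sub-aperture border), subtract an adaptive threshold of 30% of the
#' window peak, clipping negatives to zero; (4) take the center of gravity
#' of the window as the spot centroid. Displacements are relative to the
#' sub-aperture center; slopes are displacement / focal length. A
#' sub-aperture that is empty after thresholding is marked invalid.
#'
#' @param frame A [render_frame()] result (or a compatible pixel matrix
#'   wrapped in one).
#' @param geom A [lenslet_geometry()].
#' @param cfg A [sensor_config()].
#' @param calibration Optional calibration (dark) frame: matrix of the same
#'   size; default zero.
#' @return Object of class `slope_set`: data frame with one row per active
#'   lenslet (`row`, `col`, `dx_px`, `dy_px`, `slope_x`, `slope_y`, `peak`,
#'   `valid`), stored with the geometry.
#' @export
centroid_tcog <- function(frame, geom, cfg = sensor_config(),
                          calibration = NULL) {
  stopifnot(inherits(frame, "sensor_frame"),
            inherits(geom, "lenslet_geometry"))
  pix <- frame$pixels
  if (!is.null(calibration)) {
    cal <- if (inherits(calibration, "sensor_frame")) calibration$pixels
           else calibration
    if (!all(dim(cal) == dim(pix))) stop("calibration frame shape mismatch")
    pix <- pix - cal
  }
  pix <- pmax(pix - cfg$global_threshold, 0)

  spn <- geom$superpixels
  half <- (cfg$window_superpixels - 1L) / 2L
  act <- which(geom$active)
  n <- length(act)
  out <- data.frame(row = geom$rowcol[act, "row"],
                    col = geom$rowcol[act, "col"],
                    dx_px = NA_real_, dy_px = NA_real_,
                    slope_x = NA_real_, slope_y = NA_real_,
                    peak = 0, valid = FALSE)
  for (k in seq_len(n)) {
    rc <- geom$rowcol[act[k], ]
    rows <- (rc["row"] - 1) * spn + seq_len(spn)
    cols <- (rc["col"] - 1) * spn + seq_len(spn)
    sub <- pix[rows, cols]
    pk <- which.max(sub)   # column-major; first occurrence on ties
    out$peak[k] <- sub[pk]
    if (sub[pk] <= 0) next
    pi_ <- ((pk - 1) %% spn) + 1L      # row (y)
    pj <- ((pk - 1) %/% spn) + 1L      # col (x)
    ri <- max(1L, pi_ - half):min(spn, pi_ + half)
    rj <- max(1L, pj - half):min(spn, pj + half)
    w <- sub[ri, rj]
    w <- pmax(w - cfg$adaptive_fraction * max(w), 0)
    s <- sum(w)
    if (s <= 0) next
    # pixel k covers [k-1, k); its center is k - 0.5
    cy <- sum(rowSums(w) * (ri - 0.5)) / s
    cx <- sum(colSums(w) * (rj - 0.5)) / s
    out$dx_px[k] <- cx - spn / 2
    out$dy_px[k] <- cy - spn / 2
    out$valid[k] <- TRUE
  }
  d_um <- geom$superpixel_um
  out$slope_x <- out$dx_px * d_um / (geom$focal_mm * 1e3)
  out$slope_y <- out$dy_px * d_um / (geom$focal_mm * 1e3)
  structure(list(table = out, geom = geom), class = "slope_set")
}

#' @export
print.slope_set <- function(x, ...) {
  cat(sprintf("slope_set: %d lenslets, %d valid, mean |disp| %.3f px\n",
              nrow(x$table), sum(x$table$valid),
              mean(abs(c(x$table$dx_px, x$table$dy_px)), na.rm = TRUE)))
  invisible(x)
}

#' Blink detection from focal-spot peak intensities
#'
#' A blink is flagged when at least `blink_fraction` (default 50%) of the
#' active lenslet spots have peak intensities below
#' `blink_peak_threshold` (default 700 counts). The comparison at the
#' fraction boundary is inclusive. During a blink the controller holds the
#' DM shape from the last non-blink frame (see [control_update()]).
#'
#' @param slopes A [centroid_tcog()] result.
#' @param cfg A [sensor_config()].
#' @return Logical flag.
#' @export
detect_blink <- function(slopes, cfg = sensor_config()) {
  stopifnot(inherits(slopes, "slope_set"))
  mean(slopes$table$peak < cfg$blink_peak_threshold) >= cfg$blink_fraction
}

#' Least-squares Zernike reconstruction from measured slopes
#'
#' Fits the analytic per-sub-aperture mean Zernike gradients to the measured
#' slopes of all valid lenslets (ordinary least squares). Coefficients come
#' out in micrometres on the RMS-normalized basis, so the reported RMS is
#' the coefficient norm.
#'
#' @param slopes A [centroid_tcog()] result.
#' @param basis A [build_zernike_basis()].
#' @param geom The [lenslet_geometry()] the slopes came from.
#' @return A [wavefront_state()].
#' @export
reconstruct_wavefront <- function(slopes, basis, geom) {
  stopifnot(inherits(slopes, "slope_set"), inherits(basis, "zernike_basis"))
  tab <- slopes$table
  valid <- which(tab$valid)
  if (2 * length(valid) < 2 * basis$mode_count)
    stop("not enough valid slope measurements for ", basis$mode_count,
         " modes")
  G <- subap_gradient_matrix(geom, basis)
  D <- rbind(G$gx[valid, , drop = FALSE], G$gy[valid, , drop = FALSE])
  b <- c(tab$slope_x[valid], tab$slope_y[valid])
  qrD <- qr(D)
  if (qrD$rank < basis$mode_count)
    stop("rank-deficient reconstruction system")
  coef <- qr.coef(qrD, b)
  wavefront_state(coef, basis, timestamp = 0)
}

#' Wavefront sensing noise budget
#'
#' Standard Shack-Hartmann error estimates converted to phase radians:
#' the photon-shot-noise term
#' `sigma_photon = (pi / sqrt(2)) (N_T / N_D) / sqrt(N_ph)`
#' (N_T = spot FWHM in super-pixels, N_D the diffraction-limited spot-size
#' constant) and the readout term
#' `sigma_read = (pi / sqrt(3)) (sigma_e / N_ph) (A_eff / N_D)`
#' with A_eff the effective readout-noise area. N_D and A_eff are
#' calibration constants whose defaults reproduce 0.100 rad and 0.010 rad
#' for 1962 photons and 2 e- read noise. The total adds in quadrature.
#'
#' @param cfg A [sensor_config()].
#' @param geom A [lenslet_geometry()] (kept for interface symmetry).
#' @return List of class `noise_budget` with `sigma_photon`,
#'   `sigma_readout`, `sigma_total` (radians).
#' @export
sensing_noise_budget <- function(cfg = sensor_config(),
                                 geom = lenslet_geometry()) {
  if (cfg$photons_per_lenslet <= 0)
    stop("'photons_per_lenslet' must be positive")
  n_t <- 2 * sqrt(2 * log(2)) * cfg$spot_sigma
  sigma_photon <- (pi / sqrt(2)) * (n_t / cfg$diffraction_spot_px) /
    sqrt(cfg$photons_per_lenslet)
  sigma_read <- (pi / sqrt(3)) *
    (cfg$read_noise_e / cfg$photons_per_lenslet) *
    (cfg$read_noise_area_px2 / cfg$diffraction_spot_px)
  structure(list(sigma_photon = sigma_photon, sigma_readout = sigma_read,
                 sigma_total = sqrt(sigma_photon^2 + sigma_read^2)),
            class = "noise_budget")
}

#' Write a sensor frame as TIFF / a slope set as CSV
#'
#' @param frame A [render_frame()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF frames")
  tiff::writeTIFF(frame$pixels / (2^frame$cfg$bit_depth - 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @param slopes A [centroid_tcog()] result.
#' @export
write_slopes_csv <- function(slopes, path) {
  utils::write.csv(slopes$table, path, row.names = FALSE)
  invisible(path)
}
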