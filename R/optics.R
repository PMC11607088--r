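#' Optical system configuration
#'
#' Wavelengths and eye-model constants used by the closed-form optical
#' metrics. Defaults describe a near-infrared retinal imaging beacon
#' (790 nm center, 42 nm bandwidth) over a 6.7 mm dilated pupil, with the
#' reduced-eye model (focal length 16.67 mm, vitreous index 1.336) used for
#' angle-to-retina and diopter-to-micron conversions.
#'
#' @param wavelength_um Central wavelength, micrometres (default 0.790).
#' @param source_bandwidth_um Source spectral bandwidth, micrometres
#'   (default 0.042).
#' @param pupil_diameter_mm Eye pupil diameter, millimetres (default 6.7).
#' @param eye_focal_length_mm Reduced-eye focal length, millimetres
#'   (default 16.67).
#' @param tissue_index Refractive index of retinal tissue (default 1.38).
#' @param vitreous_index Refractive index of the vitreous (default 1.336).
#' @return Object of class `optical_config`.
#' @export
optical_config <- function(wavelength_um = 0.790,
                           source_bandwidth_um = 0.042,
                           pupil_diameter_mm = 6.7,
                           eye_focal_length_mm = 16.67,
                           tissue_index = 1.38,
                           vitreous_index = 1.336) {
  lens <- c(wavelength_um, source_bandwidth_um, pupil_diameter_mm,
            eye_focal_length_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths in optical_config must be positive")
  if (tissue_index < 1 || vitreous_index < 1)
    stop("refractive indices must be >= 1")
  structure(list(wavelength_um = wavelength_um,
                 source_bandwidth_um = source_bandwidth_um,
                 pupil_diameter_mm = pupil_diameter_mm,
                 eye_focal_length_mm = eye_focal_length_mm,
                 tissue_index = tissue_index,
                 vitreous_index = vitreous_index),
            class = "optical_config")
}

#' Diffraction-limited residual wavefront error (Marechal criterion)
#'
#' Correction is conventionally called diffraction-limited once the residual
#' RMS wavefront error is at or below lambda/14. At 0.790 um this is
#' 0.0564 um (56 nm).
#'
#' @param cfg An [optical_config()] (or a wavelength in micrometres).
#' @return RMS threshold in micrometres.
#' @export
diffraction_limit_rms <- function(cfg = optical_config()) {
  lambda <- if (inherits(cfg, "optical_config")) cfg$wavelength_um else cfg
  if (lambda <= 0) stop("wavelength must be positive")
  lambda / 14
}

#' Strehl ratio from residual RMS (extended Marechal approximation)
#'
#' S = exp(-(2 pi sigma / lambda)^2). Strictly decreasing in sigma and equal
#' to 1 only for a perfect wavefront.
#'
#' @param rms_um Residual RMS wavefront error, micrometres.
#' @param wavelength_um Wavelength, micrometres.
#' @return Strehl ratio in (0, 1].
#' @export
strehl_from_rms <- function(rms_um, wavelength_um = 0.790) {
  if (any(rms_um < 0)) stop("'rms_um' must be non-negative")
  exp(-(2 * pi * rms_um / wavelength_um)^2)
}

#' Closed-form resolution metrics of the AO imaging system
#'
#' * lateral: Rayleigh criterion 1.22 lambda f_eye / D;
#' * axial: coherence-length resolution (2 ln 2 / pi) lambda^2 /
#'   (bandwidth * n_tissue) for a broadband source;
#' * microns_per_diopter: axial focal shift in the eye per diopter of
#'   defocus, n_vitreous * f_eye^2 (reduced-eye model).
#'
#' @param cfg An [optical_config()].
#' @return List with `lateral_um`, `axial_um`, `microns_per_diopter`.
#' @examples
#' m <- resolution_metrics(optical_config())
#' round(m$lateral_um, 1)                    # 2.4 um
#' round(m$axial_um, 2)                      # 4.75 um in tissue
#' round(0.02 * m$microns_per_diopter, 1)    # 7.4 um for a 0.02 D step
#' @export
resolution_metrics <- function(cfg = optical_config()) {
  stopifnot(inherits(cfg, "optical_config"))
  if (cfg$pupil_diameter_mm <= 0) stop("pupil diameter must be positive")
  lateral <- 1.22 * cfg$wavelength_um *
    (cfg$eye_focal_length_mm / cfg$pupil_diameter_mm)
  axial <- (2 * log(2) / pi) * cfg$wavelength_um^2 /
    (cfg$source_bandwidth_um * cfg$tissue_index)
  # f in metres: n * f^2 [m] per diopter -> micrometres
  f_m <- cfg$eye_focal_length_mm * 1e-3
  upd <- cfg$vitreous_index * f_m^2 * 1e6
  list(lateral_um = lateral, axial_um = axial, microns_per_diopter = upd)
}

#' Convert wavefront phase to optical path difference
#'
#' @param phase_rad Phase in radians.
#' @param wavelength_um Wavelength in micrometres.
#' @return Optical path length, micrometres (`phase * lambda / (2 pi)`).
#' @export
phase_to_opd <- function(phase_rad, wavelength_um = 0.790) {
  if (wavelength_um <= 0) stop("wavelength must be positive")
  phase_rad * wavelength_um / (2 * pi)
}
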