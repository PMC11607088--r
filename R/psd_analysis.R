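#' One-sided temporal power spectral density of a wavefront series
#'
#' Plain-DFT periodogram in the convention used for wavefront time series:
#' the squared magnitude of the discrete Fourier transform divided by the
#' spectral resolution (the inverse of the total measurement time), one
#' sided, DC excluded, averaged over channels. No window is applied by
#' default; Parseval holds exactly: `sum(psd) * delta_f` equals the series
#' variance (averaged over channels).
#'
#' @param series An [ao_series()] with at least 128 samples.
#' @param window `"none"` (default) or `"hann"`.
#' @return Object of class `spectrum_record`: `frequencies` (Hz), `psd`
#'   (units^2/Hz), `spectral_resolution` (Hz), `n_channels_averaged`.
#' @export
estimate_psd <- function(series, window = c("none", "hann")) {
  stopifnot(inherits(series, "ao_series"))
  window <- match.arg(window)
  x <- series$values
  n <- nrow(x)
  if (n < 128) stop("need at least 128 samples")
  fs <- series$sample_rate
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
    w <- w / sqrt(mean(w^2))
    x <- x * w
  }
  nf <- (n - 1) %/% 2
  f <- (1:nf) * fs / n
  psd_ch <- apply(x, 2, function(col) {
    X <- stats::fft(col - mean(col))
    2 * Mod(X[2:(nf + 1)])^2 / (n * fs)
  })
  psd <- rowMeans(as.matrix(psd_ch))
  structure(list(frequencies = f, psd = psd,
                 spectral_resolution = fs / n,
                 n_channels_averaged = ncol(x)),
            class = "spectrum_record")
}

#' Empirical power rejection curve from open/closed spectra
#'
#' Element-wise ratio of the closed-loop to the open-loop PSD, measured with
#' the identical injected aberration sequence in both branches.
#'
#' @param open_spec,closed_spec [estimate_psd()] records on the same
#'   frequency grid.
#' @return A `rejection_curve` (frequencies, power_rejection).
#' @export
measure_rejection_curve <- function(open_spec, closed_spec) {
  stopifnot(inherits(open_spec, "spectrum_record"),
            inherits(closed_spec, "spectrum_record"))
  if (length(open_spec$frequencies) != length(closed_spec$frequencies) ||
      max(abs(open_spec$frequencies - closed_spec$frequencies)) >
        1e-9 * max(open_spec$frequencies))
    stop("frequency grids do not match")
  ratio <- ifelse(open_spec$psd > 0, closed_spec$psd / open_spec$psd, 0)
  structure(list(frequencies = open_spec$frequencies,
                 power_rejection = ratio),
            class = "rejection_curve")
}

#' Residual temporal wavefront error after AO filtering
#'
#' Band integral of the input aberration PSD filtered by a loop's power
#' rejection curve: sigma_temporal = sqrt(sum PSD(f) |H_reject(f)|^2 df)
#' over the common band (from the lowest nonzero bin). With identity
#' rejection this is just the RMS of the input series.
#'
#' @param eye_spec A [estimate_psd()] record (or any `spectrum_record`).
#' @param rejection A `rejection_curve`; interpolated (linearly in log f)
#'   onto the spectrum's grid if the grids differ.
#' @return List of class `temporal_error_result` with `sigma_temporal`
#'   (same amplitude units as the spectrum), `loop_rate` (if known) and
#'   `rejection_source`.
#' @export
temporal_error <- function(eye_spec, rejection) {
  stopifnot(inherits(eye_spec, "spectrum_record"),
            inherits(rejection, "rejection_curve"))
  f <- eye_spec$frequencies
  keep <- f >= min(rejection$frequencies) & f <= max(rejection$frequencies)
  rej <- stats::approx(log(rejection$frequencies),
                       rejection$power_rejection, xout = log(f[keep]),
                       rule = 2)$y
  df <- eye_spec$spectral_resolution
  sigma <- sqrt(sum(eye_spec$psd[keep] * rej * df))
  structure(list(sigma_temporal = sigma,
                 loop_rate = attr(rejection, "loop_rate"),
                 rejection_source = "rejection_curve"),
            class = "temporal_error_result")
}

# the standard fast-loop family: discontinuous exposure, gain 1, exposure
# filling half the loop period and readout/processing the other half
fig_rate_config <- function(rate, t_dm = 0.55e-3) {
  loop_config(0.5 / rate, 0.5 / rate, t_dm, rate, 1, "discontinuous")
}

#' Loop rate required for diffraction-limited correction of a spectrum
#'
#' For each candidate loop rate, builds the standard loop parameterization
#' (discontinuous exposure, gain 1, integration time equal to half the loop
#' period with the other half used by readout/transfer/processing), filters
#' the input spectrum by its analytic rejection curve, and returns the
#' smallest rate whose residual temporal error is at or below `threshold`.
#'
#' @param eye_spec A `spectrum_record` of the input aberration.
#' @param threshold Residual RMS target, same units as the spectrum
#'   amplitude (e.g. `diffraction_limit_rms()`).
#' @param rate_grid Increasing candidate loop rates, Hz.
#' @param t_dm DM time constant for the loop family, seconds.
#' @return Required rate in Hz, or `Inf` if no grid rate suffices.
#' @export
required_loop_rate <- function(eye_spec, threshold, rate_grid,
                               t_dm = 0.55e-3) {
  if (!length(rate_grid)) stop("'rate_grid' must be non-empty")
  if (is.unsorted(rate_grid)) stop("'rate_grid' must be increasing")
  for (r in rate_grid) {
    cfg <- fig_rate_config(r, t_dm)
    rej <- rejection_power_curve(cfg, eye_spec$frequencies)
    if (temporal_error(eye_spec, rej)$sigma_temporal <= threshold)
      return(r)
  }
  Inf
}

#' Diffraction-limit threshold PSD for a given loop
#'
#' The power-law input spectrum that a given loop can just barely correct to
#' a target residual: a template `f^(-exponent)` scaled so that filtering it
#' by the loop's rejection curve yields exactly `threshold`. Input spectra
#' above this curve cannot be corrected to the target by that loop; spectra
#' below it can.
#'
#' @param cfg A [loop_config()].
#' @param template_exponent Power-law slope of the template (default 1,
#'   matching the pink-noise stimulus convention).
#' @param threshold Residual RMS target (e.g. `diffraction_limit_rms()`).
#' @param frequencies Frequency grid, Hz (default 0.2 to 171 in 0.2 Hz
#'   steps).
#' @return A `spectrum_record` of the threshold PSD.
#' @export
diffraction_threshold_psd <- function(cfg, template_exponent = 1,
                                      threshold = 0.790 / 14,
                                      frequencies = seq(0.2, 171,
                                                        by = 0.2)) {
  stopifnot(inherits(cfg, "loop_config"))
  tmpl <- frequencies^(-template_exponent)
  df <- frequencies[2] - frequencies[1]
  base <- structure(list(frequencies = frequencies, psd = tmpl,
                         spectral_resolution = df,
                         n_channels_averaged = 1L),
                    class = "spectrum_record")
  rej <- rejection_power_curve(cfg, frequencies)
  sigma_unit <- temporal_error(base, rej)$sigma_temporal
  scale <- (threshold / sigma_unit)^2
  base$psd <- tmpl * scale
  base
}
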