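#' Uniformly sampled wavefront time series
#'
#' Container for one or more channels (modal coefficients, per-lenslet
#' wavefront values, or DM command sequences) on a uniform time base.
#'
#' @param times Sample times, seconds (uniform, starting anywhere).
#' @param values Numeric vector or matrix (rows = samples, columns =
#'   channels), micrometres.
#' @param sample_rate Sampling rate, Hz; default inferred from `times`.
#' @return Object of class `ao_series`.
#' @export
ao_series <- function(times, values, sample_rate = NULL) {
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop("'times' and 'values' lengths differ")
  if (length(times) >= 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      stop("'times' must be uniformly sampled")
    if (is.null(sample_rate)) sample_rate <- 1 / dt[1]
  }
  if (any(!is.finite(values))) stop("'values' must be finite")
  structure(list(times = times, values = values, sample_rate = sample_rate),
            class = "ao_series")
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# spectral synthesis: hermitian spectrum with prescribed one-sided bin
# powers (deterministic amplitudes, uniform random phases); bin_power[k] is
# the variance contributed by frequency bin k (= PSD(f_k) * delta_f)
synth_from_psd_bins <- function(bin_power, n, n_channels) {
  nf <- length(bin_power)                   # bins 1 .. floor((n-1)/2)
  df_scale <- n * sqrt(bin_power / 2)
  out <- matrix(0, n, n_channels)
  for (ch in seq_len(n_channels)) {
    ph <- stats::runif(nf, 0, 2 * pi)
    X <- complex(length.out = n)
    X[2:(nf + 1)] <- df_scale * exp(1i * ph)
    X[n - (1:nf) + 1] <- Conj(X[2:(nf + 1)])
    out[, ch] <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  out
}

#' Generate pink-noise (1/f) pseudo-random command sequences
#'
#' Frequency-domain synthesis of pink noise -- the stimulus used to measure
#' empirical power rejection curves by replaying the same pseudo-random
#' aberration sequence with the loop open and closed. Spectral amplitudes
#' are proportional to f^(-1/2) (so power follows 1/f), phases are uniform
#' random, the DC bin is zero (the loop removes DC and 1/f diverges there),
#' and each channel is rescaled to exactly `amplitude_rms`.
#'
#' @param n_steps Number of samples (>= 64).
#' @param sample_rate Sampling rate, Hz.
#' @param amplitude_rms Target RMS per channel (micrometres, say).
#' @param seed Integer seed; identical seeds reproduce identical sequences.
#' @param n_channels Number of independent channels (default 1).
#' @param f_max Optional band limit, Hz: spectral content above it is zero.
#'   Useful when the stimulus will drive a loop slower than the sample rate.
#' @return An [ao_series()] starting at t = 0.
#' @export
gen_pink_noise <- function(n_steps, sample_rate, amplitude_rms, seed = 0L,
                           n_channels = 1L, f_max = NULL) {
  if (n_steps < 64) stop("'n_steps' must be at least 64")
  if (amplitude_rms < 0) stop("'amplitude_rms' must be non-negative")
  n <- as.integer(n_steps)
  nf <- (n - 1) %/% 2
  f <- (1:nf) * sample_rate / n
  psd <- 1 / f
  if (!is.null(f_max)) psd[f > f_max] <- 0
  x <- with_seed(seed, synth_from_psd_bins(psd, n, n_channels))
  for (ch in seq_len(n_channels)) {
    s <- stats::sd(x[, ch]) * sqrt((n - 1) / n)
    x[, ch] <- if (s > 0) x[, ch] * amplitude_rms / s else x[, ch]
  }
  ao_series((0:(n - 1)) / sample_rate, x, sample_rate)
}

#' Parameterized ocular-aberration PSD scenario model
#'
#' One-sided temporal PSD model for ocular wavefront dynamics:
#' `PSD(f) = amplitude * f^(-exponent) + bump(f) + noise_floor`, a power law
#' falling to a flat measurement-noise plateau, optionally with a Gaussian
#' spectral bump in the 3-8 Hz band emulating the oscillatory eye motion of
#' nystagmus. Presets cover a normal cyclopleged eye plus six
#' clinically-relevant scenarios whose spectra sit 10-100x above normal;
#' the preset amplitudes are illustrative defaults (the per-scenario spectra
#' of real eyes are not published) and every field can be overridden.
#'
#' @param scenario One of `"normal"`, `"artificial_tears"`,
#'   `"no_cycloplegia"`, `"sequential_fixation"`, `"keratoconus_cl"`,
#'   `"myopia_cl"`, `"nystagmus"`.
#' @param amplitude Power-law amplitude at 1 Hz, um^2/Hz.
#' @param exponent Power-law slope (default 1.5).
#' @param noise_floor Flat plateau, um^2/Hz (default: the level whose
#'   band-integrated RMS at a 342 Hz sampling rate is ~23 nm).
#' @param bump_center,bump_width,bump_height Gaussian bump parameters
#'   (Hz, Hz, um^2/Hz); height 0 disables it.
#' @param sample_rate Sampling rate the model describes, Hz (default 342).
#' @return Object of class `scenario_psd_model` with a `psd(f)` evaluator.
#' @export
scenario_psd_model <- function(scenario = c("normal", "artificial_tears",
                                            "no_cycloplegia",
                                            "sequential_fixation",
                                            "keratoconus_cl", "myopia_cl",
                                            "nystagmus"),
                               amplitude = NULL, exponent = 1.5,
                               noise_floor = (0.0233)^2 / 171,
                               bump_center = NULL, bump_width = 1.5,
                               bump_height = NULL, sample_rate = 342) {
  scenario <- match.arg(scenario)
  base_amp <- 2e-4   # um^2/Hz at 1 Hz for the normal preset
  mult <- c(normal = 1, artificial_tears = 30, no_cycloplegia = 10,
            sequential_fixation = 20, keratoconus_cl = 100, myopia_cl = 60,
            nystagmus = 40)[[scenario]]
  if (is.null(amplitude)) amplitude <- base_amp * mult
  if (scenario == "nystagmus") {
    if (is.null(bump_center)) bump_center <- 5
    if (is.null(bump_height)) bump_height <- 25 * base_amp
  } else {
    if (is.null(bump_height)) bump_height <- 0
    if (is.null(bump_center)) bump_center <- 5
  }
  if (amplitude < 0 || noise_floor < 0)
    stop("'amplitude' and 'noise_floor' must be non-negative")
  obj <- list(scenario = scenario, amplitude = amplitude,
              exponent = exponent, noise_floor = noise_floor,
              bump_center = bump_center, bump_width = bump_width,
              bump_height = bump_height, sample_rate = sample_rate)
  obj$psd <- function(f) {
    amplitude * f^(-exponent) + noise_floor +
      bump_height * exp(-(f - bump_center)^2 / (2 * bump_width^2))
  }
  structure(obj, class = "scenario_psd_model")
}

#' Synthesize wavefront time series from a scenario PSD model
#'
#' Each channel is an independent realization (deterministic spectral
#' amplitudes, uniform random phases) whose expected one-sided PSD equals
#' the model PSD exactly, so the realized variance matches the
#' band-integrated PSD up to sampling effects.
#'
#' @param model A [scenario_psd_model()].
#' @param duration Length of the series, seconds
#'   (`duration * sample_rate >= 128`).
#' @param n_channels Number of independent channels.
#' @param seed Integer seed.
#' @return An [ao_series()] in micrometres.
#' @export
synthesize_series_from_psd <- function(model, duration, n_channels = 1L,
                                       seed = 0L) {
  stopifnot(inherits(model, "scenario_psd_model"))
  n <- floor(duration * model$sample_rate)
  if (n < 128) stop("duration * sample_rate must be at least 128")
  nf <- (n - 1) %/% 2
  f <- (1:nf) * model$sample_rate / n
  bin_power <- model$psd(f) * model$sample_rate / n   # PSD * delta_f
  x <- with_seed(seed, synth_from_psd_bins(bin_power, n, n_channels))
  ao_series((0:(n - 1)) / model$sample_rate, x, model$sample_rate)
}

#' Noise-floor RMS from a PSD plateau
#'
#' The RMS wavefront error implied by a flat measurement-noise plateau:
#' sigma_W = sqrt(PSD_noise x BW), where BW = sample_rate / 2 is the
#' one-sided spectral bandwidth of the sampled measurement.
#'
#' @param psd_noise Plateau level (units^2 per Hz).
#' @param sample_rate Sampling rate, Hz.
#' @return RMS in the PSD's amplitude units.
#' @export
noise_floor_rms <- function(psd_noise, sample_rate = 342) {
  if (psd_noise < 0) stop("'psd_noise' must be non-negative")
  sqrt(psd_noise * sample_rate / 2)
}
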