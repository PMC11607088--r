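# Small fixtures used across tests: an 8x8 lenslet array whose pupil covers
# the whole array (64 active lenslets, 360x360-pixel frames -- ~6x faster to
# render than the full 20x20 geometry) and a compact Zernike basis.

small_geom <- function() {
  lenslet_geometry(grid = 8L, magnification = 2 * 4.0 / 6.7)
}

small_basis <- function() build_zernike_basis(4)   # 12 modes

full_geom <- function() lenslet_geometry()
full_basis <- function() build_zernike_basis(10)   # 63 modes

# ultrafast discontinuous timing and its loop_config counterpart
uf_timing <- function() timing_config("discontinuous")

uf_loop_from_timing <- function(tc = uf_timing()) {
  loop_config(tc$t_integration, tc$t_readout_transfer_process,
              tc$t_dm_settle, derive_timing(tc)$loop_rate, 1,
              "discontinuous")
}

# empirical rejection curve of a simulated pink-noise tracking run,
# median-binned in log frequency over [1, rate/4]
measured_vs_theory_rejection <- function(n_steps = 2048L, n_channels = 3L,
                                         seed = 1L, n_bins = 20L) {
  tc <- uf_timing()
  rate <- derive_timing(tc)$loop_rate
  stim <- gen_pink_noise(n_steps, rate, 0.1, seed = seed,
                         n_channels = n_channels)
  tr <- simulate_tracking(tc, 1.0, stim)
  m <- tr$measurement
  keep <- 65:length(m$times)   # drop the closing transient
  open_spec <- estimate_psd(ao_series(m$times[keep],
                                      m$open[keep, , drop = FALSE],
                                      m$sample_rate), window = "hann")
  closed_spec <- estimate_psd(ao_series(m$times[keep],
                                        m$closed[keep, , drop = FALSE],
                                        m$sample_rate), window = "hann")
  emp <- measure_rejection_curve(open_spec, closed_spec)
  band <- emp$frequencies >= 1 & emp$frequencies <= rate / 4
  f <- emp$frequencies[band]
  r <- emp$power_rejection[band]
  bins <- cut(log(f), n_bins)
  f_med <- as.numeric(tapply(f, bins, stats::median))
  r_med <- as.numeric(tapply(r, bins, stats::median))
  theo <- rejection_power_curve(uf_loop_from_timing(tc), f_med)
  list(frequencies = f_med, measured = r_med,
       theory = theo$power_rejection, raw = emp)
}

# brute-force thresholded-CoG oracle on one isolated spot: direct
# simulation of spot statistics, independent of the package pipeline
tcog_spot_oracle_sd <- function(n_photons, sigma = 1.5, reps = 300L,
                                thr_frac = 0.3, half = 5L) {
  edges <- 0:45
  wx <- diff(stats::pnorm(edges, 22.5, sigma))
  ww <- outer(wx, wx) * n_photons
  cent <- replicate(reps, {
    img <- matrix(stats::rpois(length(ww), ww), 45, 45)
    pk <- which.max(img)
    pi_ <- (pk - 1) %% 45 + 1
    pj <- (pk - 1) %/% 45 + 1
    rj <- max(1, pj - half):min(45, pj + half)
    ri <- max(1, pi_ - half):min(45, pi_ + half)
    w <- img[ri, rj]
    w <- pmax(w - thr_frac * max(w), 0)
    sum(colSums(w) * (rj - 0.5)) / sum(w)
  })
  stats::sd(cent)
}
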