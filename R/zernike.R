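#' Zernike polynomial basis on the unit pupil
#'
#' Builds an ANSI/OSA single-indexed Zernike basis up to a maximum radial
#' order. Modes are RMS-normalized (unit variance over the unit disk), so the
#' Euclidean norm of a coefficient vector equals the RMS wavefront error it
#' represents. The basis supports analytic evaluation of each mode and of its
#' Cartesian gradients, which is what both the sensor forward model and the
#' least-squares slope reconstructor use.
#'
#' With piston, tip and tilt excluded and `max_radial_order = 10` the basis
#' has 63 modes, the standard mode set for real-time ophthalmic wavefront
#' monitoring.
#'
#' @param max_radial_order Highest radial order `n` to include (default 10).
#' @param exclude_piston_tip_tilt Drop the first three modes (piston and the
#'   two tilts), which a closed AO loop does not monitor (default `TRUE`).
#' @return An object of class `zernike_basis` with elements `n`, `m`
#'   (radial/azimuthal orders per mode), `mode_count`, `ordering` ("ansi"),
#'   and internal radial-polynomial coefficient tables.
#' @examples
#' b <- build_zernike_basis(10)
#' b$mode_count  # 63
#' @export
build_zernike_basis <- function(max_radial_order = 10L,
                                exclude_piston_tip_tilt = TRUE) {
  if (!is.numeric(max_radial_order) || length(max_radial_order) != 1L ||
      max_radial_order < 1 || max_radial_order != round(max_radial_order))
    stop("'max_radial_order' must be a positive integer")
  N <- as.integer(max_radial_order)

  n_all <- integer(0); m_all <- integer(0)
  for (n in 0:N) for (m in seq(-n, n, by = 2L)) {
    n_all <- c(n_all, n); m_all <- c(m_all, m)
  }
  # ANSI single index j = (n(n+2)+m)/2 is already the enumeration order above
  keep <- if (exclude_piston_tip_tilt) -(1:3) else seq_along(n_all)
  n_all <- n_all[keep]; m_all <- m_all[keep]

  # radial polynomial coefficients: R_n^{|m|}(rho) = sum_k c_k rho^(n-2k)
  radial <- lapply(seq_along(n_all), function(i) {
    n <- n_all[i]; am <- abs(m_all[i])
    k <- 0:((n - am) / 2)
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k))
    list(pow = n - 2 * k, coef = coef)
  })
  norm <- sqrt(2 * (n_all + 1) / ifelse(m_all == 0, 2, 1))

  structure(list(n = n_all, m = m_all, mode_count = length(n_all),
                 max_radial_order = N,
                 exclude_piston_tip_tilt = exclude_piston_tip_tilt,
                 ordering = "ansi", radial = radial, norm = norm),
            class = "zernike_basis")
}

#' @export
print.zernike_basis <- function(x, ...) {
  cat("Zernike basis (ANSI ordering, RMS-normalized):",
      x$mode_count, "modes up to radial order", x$max_radial_order,
      if (x$exclude_piston_tip_tilt) "(piston/tip/tilt excluded)" else "",
      "\n")
  invisible(x)
}

poly_eval <- function(pow, coef, r) {
  out <- 0
  for (i in seq_along(pow)) out <- out + coef[i] * r^pow[i]
  out
}

#' Evaluate Zernike modes at Cartesian pupil points
#'
#' Points are in unit-pupil coordinates (the pupil edge at radius 1); the
#' polynomials extend smoothly beyond the unit disk, which is convenient for
#' sub-apertures whose corners protrude slightly.
#'
#' @param basis A [build_zernike_basis()] object.
#' @param x,y Numeric vectors of pupil coordinates.
#' @param modes Optional integer vector of mode indices (default all).
#' @return Matrix `length(x)` by `length(modes)` of mode values.
#' @export
zernike_eval <- function(basis, x, y, modes = seq_len(basis$mode_count)) {
  stopifnot(inherits(basis, "zernike_basis"), length(x) == length(y))
  r <- sqrt(x^2 + y^2); th <- atan2(y, x)
  out <- matrix(0, length(x), length(modes))
  for (k in seq_along(modes)) {
    j <- modes[k]
    rp <- basis$radial[[j]]
    R <- poly_eval(rp$pow, rp$coef, r)
    m <- basis$m[j]
    ang <- if (m >= 0) cos(m * th) else sin(-m * th)
    out[, k] <- basis$norm[j] * R * ang
  }
  out
}

#' Analytic Cartesian gradients of Zernike modes
#'
#' Returns the x- and y-derivatives of each requested mode, in wavefront
#' units per unit-pupil radius. The angular 1/rho term is absorbed into a
#' reduced radial polynomial so the gradient is finite on the whole pupil.
#'
#' @inheritParams zernike_eval
#' @return List with matrices `dx` and `dy`.
#' @export
zernike_gradient <- function(basis, x, y, modes = seq_len(basis$mode_count)) {
  stopifnot(inherits(basis, "zernike_basis"), length(x) == length(y))
  r <- sqrt(x^2 + y^2); th <- atan2(y, x)
  ct <- cos(th); st <- sin(th)
  dx <- matrix(0, length(x), length(modes))
  dy <- matrix(0, length(x), length(modes))
  for (k in seq_along(modes)) {
    j <- modes[k]
    rp <- basis$radial[[j]]
    m <- basis$m[j]; am <- abs(m); nn <- basis$norm[j]
    dR <- poly_eval(rp$pow[rp$pow > 0] - 1,
                    rp$coef[rp$pow > 0] * rp$pow[rp$pow > 0], r)
    if (m == 0) {
      dx[, k] <- nn * dR * ct
      dy[, k] <- nn * dR * st
    } else {
      # R/rho is a polynomial because the lowest power of R is |m| >= 1
      Rr <- poly_eval(rp$pow - 1, rp$coef, pmax(r, .Machine$double.eps))
      Rr[r == 0] <- if (am == 1) rp$coef[rp$pow == 1] else 0
      if (m > 0) {        # cos(m theta) mode
        cmt <- cos(m * th); smt <- sin(m * th)
        dx[, k] <- nn * (dR * ct * cmt + m * Rr * st * smt)
        dy[, k] <- nn * (dR * st * cmt - m * Rr * ct * smt)
      } else {            # sin(|m| theta) mode
        cmt <- cos(am * th); smt <- sin(am * th)
        dx[, k] <- nn * (dR * ct * smt - am * Rr * st * cmt)
        dy[, k] <- nn * (dR * st * smt + am * Rr * ct * cmt)
      }
    }
  }
  list(dx = dx, dy = dy)
}

#' Wavefront state: Zernike coefficients with derived RMS
#'
#' A wavefront over the pupil, represented by a coefficient vector (in
#' micrometres) on an RMS-normalized Zernike basis. Because the basis is
#' orthonormal over the pupil, the RMS wavefront error equals the Euclidean
#' norm of the coefficients.
#'
#' @param coefficients Numeric vector of mode coefficients, micrometres.
#' @param basis The [build_zernike_basis()] the coefficients refer to.
#' @param timestamp Time stamp in seconds (default 0).
#' @return Object of class `wavefront_state` with `coefficients`, `rms`
#'   (micrometres), `timestamp` and `basis`.
#' @export
wavefront_state <- function(coefficients, basis, timestamp = 0) {
  stopifnot(inherits(basis, "zernike_basis"))
  if (length(coefficients) != basis$mode_count)
    stop("coefficient length (", length(coefficients),
         ") does not match basis mode count (", basis$mode_count, ")")
  structure(list(coefficients = as.numeric(coefficients),
                 rms = sqrt(sum(coefficients^2)),
                 timestamp = timestamp, basis = basis),
            class = "wavefront_state")
}

#' @export
print.wavefront_state <- function(x, ...) {
  cat(sprintf("wavefront_state: %d modes, RMS %.4f um (t = %g s)\n",
              length(x$coefficients), x$rms, x$timestamp))
  invisible(x)
}

#' Render a wavefront map over the pupil
#'
#' Evaluates the modal wavefront on a square grid; pixels whose centers fall
#' outside the unit disk are `NA`. The spatial RMS over the disk approximates
#' the coefficient-norm RMS (they agree as the grid is refined).
#'
#' @param basis A [build_zernike_basis()] object.
#' @param state A [wavefront_state()] whose coefficients match `basis`.
#' @param grid_resolution Pixels per side (default 256).
#' @return `grid_resolution` x `grid_resolution` numeric matrix (micrometres).
#' @export
evaluate_wavefront <- function(basis, state, grid_resolution = 256L) {
  stopifnot(inherits(state, "wavefront_state"))
  if (length(state$coefficients) != basis$mode_count)
    stop("coefficient length does not match basis mode count")
  n <- as.integer(grid_resolution)
  cc <- (seq_len(n) - 0.5) / n * 2 - 1   # pixel centers
  g <- expand.grid(x = cc, y = cc)
  inside <- g$x^2 + g$y^2 <= 1
  vals <- rep(NA_real_, nrow(g))
  if (any(inside)) {
    Z <- zernike_eval(basis, g$x[inside], g$y[inside])
    vals[inside] <- as.numeric(Z %*% state$coefficients)
  }
  matrix(vals, n, n)
}
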