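#' Deformable mirror configuration
#'
#' A 97-actuator magnetic DM modeled with Gaussian influence functions on an
#' 11 x 11 square grid cropped to a disk (the 97-actuator geometry), with
#' nearest-neighbor coupling of about 30% and a first-order temporal
#' response with time constant `t_dm`.
#'
#' @param n_side Actuator grid side (default 11; cropping yields 97).
#' @param layout_radius Crop radius in unit-pupil coordinates (default 1.1,
#'   so the outer ring sits just outside the pupil).
#' @param coupling Nearest-neighbor influence coupling (default 0.3); sets
#'   the Gaussian influence width.
#' @param t_dm Actuation time constant, seconds (default 0.55 ms).
#' @param command_limits Two-element clipping interval for commands
#'   (micrometres of surface stroke; default +/- 10).
#' @return Object of class `dm_config` with actuator `positions` (unit
#'   pupil), `n_actuators`, `influence_sigma`.
#' @export
dm_config <- function(n_side = 11L, layout_radius = 1.1, coupling = 0.3,
                      t_dm = 0.55e-3, command_limits = c(-10, 10)) {
  if (coupling <= 0 || coupling >= 1) stop("'coupling' must be in (0, 1)")
  half <- (n_side - 1) / 2
  g <- expand.grid(i = -half:half, j = -half:half)
  pos <- as.matrix(g) / half * layout_radius
  # crop to a disk with half an actuator spacing of margin: 97 of 121 remain
  keep <- sqrt(g$i^2 + g$j^2) <= half + 0.5
  pos <- pos[keep, , drop = FALSE]
  colnames(pos) <- c("x", "y")
  spacing <- layout_radius / half
  sigma <- spacing / sqrt(2 * log(1 / coupling))
  structure(list(n_actuators = nrow(pos), positions = pos,
                 influence_sigma = sigma, coupling = coupling,
                 t_dm = t_dm, command_limits = command_limits),
            class = "dm_config")
}

#' @export
print.dm_config <- function(x, ...) {
  cat(sprintf(
    "dm_config: %d actuators, influence sigma %.3f, t_dm %.3g ms\n",
    x$n_actuators, x$influence_sigma, 1e3 * x$t_dm))
  invisible(x)
}

#' Influence-function matrix: slopes per unit actuator command
#'
#' Column j holds the mean wavefront slope response over every active
#' sub-aperture (x-slopes stacked over y-slopes) to a unit poke (1 um of
#' surface) of actuator j, under the Gaussian influence-function model. The
#' slope units match [centroid_tcog()], so the matrix maps commands to the
#' slopes the sensor would measure.
#'
#' @param dm A [dm_config()].
#' @param geom A [lenslet_geometry()].
#' @return Numeric matrix, `2 * n_active_lenslets` rows by `n_actuators`
#'   columns.
#' @export
build_influence_matrix <- function(dm, geom) {
  stopifnot(inherits(dm, "dm_config"), inherits(geom, "lenslet_geometry"))
  sp <- subap_points(geom)
  r_um <- geom$pupil_radius_at_array_mm * 1e3
  s2 <- dm$influence_sigma^2
  n <- sp$n
  A <- matrix(0, 2 * n, dm$n_actuators)
  for (a in seq_len(dm$n_actuators)) {
    ax <- dm$positions[a, "x"]; ay <- dm$positions[a, "y"]
    gx <- matrix(0, n, 1); gy <- matrix(0, n, 1)
    for (i in seq_len(sp$nq)) for (j in seq_len(sp$nq)) {
      dxm <- sp$px[, i] - ax; dym <- sp$py[, j] - ay
      g <- exp(-(dxm^2 + dym^2) / (2 * s2))
      gx <- gx - dxm / s2 * g
      gy <- gy - dym / s2 * g
    }
    A[, a] <- c(gx, gy) / (sp$nq^2 * r_um)
  }
  A
}

#' SVD-truncated control matrix
#'
#' Pseudo-inverse of the influence matrix keeping the largest
#' `n_actuators - n_drop` singular values; the discarded small-singular-
#' value system modes are poorly sensed shapes that would amplify noise.
#' With the 97-actuator default and `n_drop = 12` the controller retains 85
#' system modes.
#'
#' @param influence The [build_influence_matrix()] result.
#' @param n_drop Number of smallest singular values to discard (default 12).
#' @return Object of class `control_matrix`: `matrix` (commands x slopes),
#'   `retained_modes`, `dropped_modes`, and the SVD factors.
#' @export
build_control_matrix <- function(influence, n_drop = 12L) {
  n_act <- ncol(influence)
  if (n_drop >= n_act) stop("'n_drop' must be smaller than the number of actuators")
  sv <- svd(influence)
  keep <- seq_len(n_act - n_drop)
  C <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  structure(list(matrix = C, retained_modes = length(keep),
                 dropped_modes = as.integer(n_drop), svd = sv),
            class = "control_matrix")
}

#' DM state: commands and transient bookkeeping
#'
#' @param dm A [dm_config()].
#' @return Object of class `dm_state` with zeroed `commands`,
#'   `previous_commands`, `last_update_time`, `held_for_blink`.
#' @export
dm_state <- function(dm) {
  z <- rep(0, dm$n_actuators)
  structure(list(commands = z, previous_commands = z,
                 last_update_time = -Inf, held_for_blink = FALSE,
                 dm = dm),
            class = "dm_state")
}

#' Leakless integral control update (direct slope control)
#'
#' Applies one step of the integral law
#' `commands <- commands - gain * (C %*% slopes)`, clipped to the command
#' limits. During a blink the commands are held unchanged (the DM keeps the
#' shape from the last non-blink frame) and the state is flagged.
#'
#' @param state A [dm_state()].
#' @param slopes A [centroid_tcog()] result, or a bare numeric slope vector
#'   (x-slopes stacked over y-slopes of the valid lenslets).
#' @param ctrl A [build_control_matrix()] result.
#' @param gain Loop gain.
#' @param blink Blink flag (e.g. from [detect_blink()]).
#' @param time Update timestamp, seconds.
#' @return The updated `dm_state`.
#' @export
control_update <- function(state, slopes, ctrl, gain, blink = FALSE,
                           time = 0) {
  stopifnot(inherits(state, "dm_state"), inherits(ctrl, "control_matrix"))
  if (blink) {
    state$held_for_blink <- TRUE
    return(state)
  }
  s <- if (inherits(slopes, "slope_set")) {
    tab <- slopes$table
    c(ifelse(tab$valid, tab$slope_x, 0), ifelse(tab$valid, tab$slope_y, 0))
  } else as.numeric(slopes)
  if (length(s) != ncol(ctrl$matrix))
    stop("slope vector length does not match the control matrix")
  lim <- state$dm$command_limits
  state$previous_commands <- state$commands
  newc <- state$commands - gain * as.numeric(ctrl$matrix %*% s)
  state$commands <- pmin(pmax(newc, lim[1]), lim[2])
  state$last_update_time <- time
  state$held_for_blink <- FALSE
  state
}

#' Effective DM commands during the actuation transient
#'
#' First-order response toward the commanded values:
#' `effective = previous + (commands - previous) * (1 - exp(-t / tau))`
#' with `tau = t_dm`.
#'
#' @param state A [dm_state()].
#' @param t_since_update Time since the last update, seconds (>= 0).
#' @param dm A [dm_config()] (defaults to the state's own).
#' @return Numeric vector of effective commands.
#' @export
dm_response <- function(state, t_since_update, dm = state$dm) {
  if (t_since_update < 0) stop("'t_since_update' must be non-negative")
  w <- 1 - exp(-t_since_update / dm$t_dm)
  state$previous_commands + (state$commands - state$previous_commands) * w
}
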