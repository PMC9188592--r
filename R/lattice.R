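# Lattice descriptors and lattice-physical unit mapping.

.make_descriptor <- function(name, cx, w) {
  q <- nrow(cx)
  opp <- integer(q)
  for (a in seq_len(q))
    opp[a] <- which(colSums((t(cx) + cx[a, ])^2) == 0)
  list(name = name, dim = ncol(cx), q = q, cx = cx, w = w, opp = opp,
       cs2 = 1 / 3)
}

#' D2Q9 lattice descriptor
#'
#' Nine discrete velocities in 2D with the standard weights (4/9 rest, 1/9
#' axis, 1/36 diagonal) and sound speed `c_s = 1/sqrt(3)` lattice units.
#'
#' @return a lattice descriptor list: `dim`, `q`, `cx` (q x dim integer
#'   velocity matrix), `w` (weights), `opp` (opposite-direction map), `cs2`
#' @export
d2q9 <- function() {
  cx <- rbind(c(0, 0),
              c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
              c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  w <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
  .make_descriptor("D2Q9", cx, w)
}

#' D3Q19 lattice descriptor
#'
#' Nineteen discrete velocities in 3D with the standard weights (1/3 rest,
#' 1/18 axis, 1/36 diagonal).
#'
#' @return a lattice descriptor list, see [d2q9()]
#' @export
d3q19 <- function() {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  di <- rbind(c(1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0),
              c(1, 0, 1), c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1),
              c(0, 1, 1), c(0, -1, -1), c(0, 1, -1), c(0, -1, 1))
  cx <- rbind(c(0, 0, 0), ax, di)
  w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  .make_descriptor("D3Q19", cx, w)
}

#' Lattice-physical unit mapping
#'
#' Fixes the diffusive scaling `dt = (nu_lattice / nu_phys) * dx^2`: choosing
#' the lattice viscosity (i.e. the relaxation time `tau0 = nu_lattice/cs2 +
#' 1/2`) and the cell size determines the physical time step. Velocity scale
#' is `dx/dt`, pressure/stress scale `rho_phys * (dx/dt)^2`.
#'
#' @param dx cell size, m
#' @param nu_phys physical kinematic viscosity, m2/s (blood:
#'   0.0035/1050 = 3.33e-6)
#' @param nu_lattice lattice kinematic viscosity (dimensionless); pick so
#'   tau0 lies in roughly 0.51-0.8
#' @param rho_phys physical density, kg/m3
#' @return a `unit_map` list: dx, dt, nu_phys, nu_lattice, tau0,
#'   u_scale (m/s per lattice velocity), p_scale (Pa per lattice
#'   pressure/stress unit)
#' @export
unit_map <- function(dx, nu_phys = 0.0035 / 1050, nu_lattice = 0.05,
                     rho_phys = 1050) {
  stopifnot(dx > 0, nu_phys > 0, nu_lattice > 0)
  dt <- (nu_lattice / nu_phys) * dx^2
  tau0 <- nu_lattice / (1 / 3) + 0.5
  structure(list(dx = dx, dt = dt, nu_phys = nu_phys,
                 nu_lattice = nu_lattice, tau0 = tau0,
                 rho_phys = rho_phys,
                 u_scale = dx / dt, p_scale = rho_phys * (dx / dt)^2),
            class = "unit_map")
}

#' @export
print.unit_map <- function(x, ...) {
  cat(sprintf("<unit_map> dx %.3g m, dt %.3g s, tau0 %.4f, u_scale %.3g m/s\n",
              x$dx, x$dt, x$tau0, x$u_scale))
  invisible(x)
}

#' Sinusoidal smooth-startup wrapper for an inlet waveform
#'
#' Prepends a half-sinusoid ramp rising from zero to `waveform(0)` over
#' `t_ramp`, then delegates to the waveform shifted by `t_ramp`. The output
#' is continuous at the junction; the steepest slope during the ramp is
#' `(pi/2) * waveform(0) / t_ramp`.
#'
#' @param waveform function of time returning inlet velocity
#' @param t_ramp ramp duration (same time units as the waveform)
#' @return a function of time
#' @export
smooth_startup <- function(waveform, t_ramp) {
  if (t_ramp <= 0) stop("t_ramp must be > 0", call. = FALSE)
  u0 <- waveform(0)
  function(t) {
    ifelse(t < t_ramp,
           u0 * sin(pi / 2 * pmax(t, 0) / t_ramp),
           waveform(t - t_ramp))
  }
}

#' Area-weighted outlet flow split
#'
#' Distributes a total flow over outlet branches proportionally to their
#' cross-sectional areas: `q_k = total_q * A_k / sum(A)`.
#'
#' @param total_q total flow to distribute
#' @param outlet_areas positive branch areas
#' @return per-branch flows summing exactly to `total_q`
#' @export
outlet_split <- function(total_q, outlet_areas) {
  if (length(outlet_areas) == 0) stop("no outlet areas given", call. = FALSE)
  if (any(outlet_areas <= 0)) stop("outlet areas must be > 0", call. = FALSE)
  total_q * outlet_areas / sum(outlet_areas)
}

#' Near-wall resolution in friction-velocity units
#'
#' `y+ = y * u_tau / nu` with friction velocity `u_tau = sqrt(tau_w / rho)`.
#' Used to verify that the first lattice cell sits inside the viscous
#' sublayer (y+ of order 1).
#'
#' @param tau_w wall shear stress, Pa
#' @param y wall-normal distance of the first cell, m
#' @param nu_phys kinematic viscosity, m2/s
#' @param rho_phys density, kg/m3
#' @return dimensionless y+
#' @export
y_plus <- function(tau_w, y, nu_phys = 0.0035 / 1050, rho_phys = 1050) {
  if (any(tau_w < 0)) stop("tau_w must be >= 0", call. = FALSE)
  y * sqrt(tau_w / rho_phys) / nu_phys
}
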