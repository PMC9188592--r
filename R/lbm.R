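# Lattice-Boltzmann kernel: BGK collision with Smagorinsky large-eddy
# closure, interpolated bounce-back (Bouzidi) at curved walls, velocity
# inlet with off-equilibrium reconstruction, pressure outlet, and
# wall-shear-stress extraction from the non-equilibrium moment.
#
# Populations are stored as an N x Q matrix over all cells (solid cells
# carry inert weights); geometry and streaming tables come from
# build_links(). All quantities are in lattice units unless converted
# through a unit_map.

#' BGK equilibrium populations
#'
#' Second-order Maxwellian:
#' `feq_a = w_a rho (1 + 3 c.u + 4.5 (c.u)^2 - 1.5 u.u)`.
#' Zeroth and first moments reproduce `rho` and `rho u` exactly.
#'
#' @param rho density vector (length N)
#' @param u velocity matrix (N x dim), lattice units
#' @param desc lattice descriptor
#' @param warn_mach warn if any |u| exceeds 0.3 lattice units
#' @return N x Q matrix of populations
#' @export
lbm_equilibrium <- function(rho, u, desc, warn_mach = TRUE) {
  if (is.null(dim(u))) u <- matrix(u, nrow = length(rho), ncol = desc$dim,
                                   byrow = TRUE)
  if (warn_mach && any(rowSums(u^2) > 0.09))
    warning("lattice velocity exceeds 0.3; the simulation may be unstable")
  cu <- u %*% t(desc$cx)                 # N x Q
  usq <- rowSums(u^2)
  f <- (1 + 3 * cu + 4.5 * cu^2 - 1.5 * usq) * rho
  sweep(f, 2, desc$w, "*")
}

#' Macroscopic moments of a population field
#'
#' @param f N x Q population matrix
#' @param desc lattice descriptor
#' @return list(rho, u) with u an N x dim matrix
#' @export
lbm_macroscopics <- function(f, desc) {
  rho <- rowSums(f)
  u <- (f %*% desc$cx) / rho
  list(rho = rho, u = u)
}

# second-order non-equilibrium moment Pi_ij and its Frobenius norm
.pi_neq <- function(fneq, desc) {
  dim <- desc$dim
  pairs <- which(upper.tri(diag(dim), diag = TRUE), arr.ind = TRUE)
  Pi <- matrix(0, nrow(fneq), nrow(pairs))
  Q2 <- numeric(nrow(fneq))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Pi[, k] <- fneq %*% (desc$cx[, i] * desc$cx[, j])
    Q2 <- Q2 + (if (i == j) 1 else 2) * Pi[, k]^2
  }
  list(Pi = Pi, pairs = pairs, norm = sqrt(Q2))
}

#' BGK collision with Smagorinsky subgrid closure
#'
#' Relaxes populations toward equilibrium with a per-cell effective
#' relaxation time. The eddy viscosity follows the Smagorinsky closure with
#' constant `c_smag` (0.1 by default in the solvers): with `Q = |Pi|` the
#' norm of the second-order non-equilibrium moment,
#' `tau_eff = (tau0 + sqrt(tau0^2 + 2 sqrt(2) c_smag^2 Q / (rho cs^4))) / 2`,
#' which reduces exactly to plain BGK (`tau_eff = tau0`) when `c_smag = 0`
#' or the field is at equilibrium.
#'
#' @param f N x Q populations
#' @param desc lattice descriptor
#' @param tau0 molecular relaxation time (> 0.5)
#' @param c_smag Smagorinsky constant (0 disables the closure)
#' @param return_fields also return rho, u, tau_eff and the non-equilibrium
#'   moment (needed for wall-stress extraction)
#' @return post-collision populations, or a list when `return_fields`
#' @export
lbm_collide <- function(f, desc, tau0, c_smag = 0, return_fields = FALSE) {
  m <- lbm_macroscopics(f, desc)
  feq <- lbm_equilibrium(m$rho, m$u, desc, warn_mach = FALSE)
  fneq <- f - feq
  if (c_smag > 0) {
    pn <- .pi_neq(fneq, desc)
    cs4 <- desc$cs2^2
    tau_eff <- (tau0 + sqrt(tau0^2 +
                              2 * sqrt(2) * c_smag^2 * pn$norm / (m$rho * cs4))) / 2
  } else {
    pn <- NULL
    tau_eff <- rep(tau0, nrow(f))
  }
  if (any(tau_eff <= 0.5)) stop("unstable collision: tau_eff <= 1/2", call. = FALSE)
  fpost <- f - fneq / tau_eff
  if (return_fields)
    list(f = fpost, rho = m$rho, u = m$u, tau_eff = tau_eff,
         fneq = fneq, pi_neq = pn)
  else fpost
}

#' Streaming with interpolated bounce-back at curved walls
#'
#' Propagates post-collision populations one cell along their velocities
#' (periodic pull), then repairs every population that would have streamed
#' out of a solid wall using the Bouzidi interpolated bounce-back with the
#' link fraction q:
#' for `q < 1/2`: `f_opp(A) = 2q fc_a(A) + (1 - 2q) fc_a(E)` (E the upstream
#' fluid neighbor); for `q >= 1/2`:
#' `f_opp(A) = fc_a(A) / (2q) + (2q - 1)/(2q) fc_opp(A)`.
#' At `q = 1/2` both branches reduce to plain bounce-back. Links whose
#' upstream neighbor is not fluid fall back to plain bounce-back.
#'
#' @param fpost N x Q post-collision populations
#' @param links streaming tables from [build_links()]
#' @return streamed populations
#' @export
lbm_stream <- function(fpost, links) {
  desc <- links$desc
  f <- fpost
  for (a in seq_len(desc$q))
    f[, a] <- fpost[links$pull[, a], a]
  for (a in seq_len(desc$q)) {
    wl <- links$wall[[a]]
    if (is.null(wl)) next
    ab <- desc$opp[a]
    q <- wl$q
    lo <- q < 0.5 & wl$ie_fluid
    hi <- q >= 0.5
    fb <- !lo & !hi                      # q < 1/2 but no upstream fluid cell
    if (any(lo)) {
      ia <- wl$ia[lo]; qq <- q[lo]
      f[ia, ab] <- 2 * qq * fpost[ia, a] +
        (1 - 2 * qq) * fpost[wl$ie[lo], a]
    }
    if (any(hi)) {
      ia <- wl$ia[hi]; qq <- q[hi]
      f[ia, ab] <- fpost[ia, a] / (2 * qq) +
        (2 * qq - 1) / (2 * qq) * fpost[ia, ab]
    }
    if (any(fb)) {
      ia <- wl$ia[fb]
      f[ia, ab] <- fpost[ia, a]
    }
  }
  f
}

# --- boundary conditions ----------------------------------------------------

#' Velocity-inlet boundary handler
#'
#' Prescribes the axial inlet velocity (plug or parabolic-like profile) on
#' the inlet plane. Density is copied from the neighboring bulk node
#' (corner/edge pressures extrapolated from bulk), and the off-equilibrium
#' part of the populations is reconstructed from finite-difference velocity
#' gradients: one-sided second order along the axis, central within the
#' plane (walls treated as no-slip), via
#' `fneq_a = -w_a rho tau0 / cs2 (c_a c_a - cs2 I) : S`.
#'
#' @param grid a voxel grid with an inlet plane (flag 2)
#' @param links streaming tables
#' @param desc lattice descriptor
#' @param profile `"plug"` or `"parabolic"` (scaled so the MEAN equals the
#'   prescribed waveform value)
#' @return an object passed to [lbm_run()]'s `inlet` argument; callable as
#'   `h(f, u_mean, tau0)` returning the corrected populations
#' @export
velocity_inlet <- function(grid, links, desc, profile = c("plug", "parabolic")) {
  profile <- match.arg(profile)
  cells <- which(as.vector(grid$flags) == 2L)
  if (!length(cells)) stop("grid has no inlet plane", call. = FALSE)
  a_xp <- which(desc$cx[, 1] == 1 & rowSums(abs(desc$cx)) == 1)  # +x axis dir
  nb1 <- links$nbr[cells, a_xp]
  nb2 <- links$nbr[nb1, a_xp]
  # in-plane neighbor tables per transverse axis (NA where not fluid)
  tdirs <- lapply(2:desc$dim, function(d) {
    ap <- which(desc$cx[, d] == 1 & rowSums(abs(desc$cx)) == 1)
    am <- desc$opp[ap]
    list(p = links$nbr[cells, ap], m = links$nbr[cells, am])
  })
  fluid <- links$fluid
  # profile shape, normalized to unit mean over the inlet cells
  shape <- rep(1, length(cells))
  if (profile == "parabolic") {
    co <- as.matrix(expand.grid(lapply(grid$dims, seq_len)))[cells, -1, drop = FALSE]
    ctr <- colMeans(co)
    r2 <- rowSums(sweep(co, 2, ctr)^2)
    shape <- pmax(1 - r2 / max(r2 * 1.04, 1e-9), 0)
    shape <- shape / mean(shape)
  }
  structure(function(f, u_mean, tau0) {
    m <- lbm_macroscopics(f, desc)
    rho_in <- m$rho[nb1]                        # bulk-node extrapolation
    ux <- u_mean * shape
    u_in <- matrix(0, length(cells), desc$dim)
    u_in[, 1] <- ux
    # velocity-gradient tensor S at the inlet by finite differences
    S <- array(0, c(length(cells), desc$dim, desc$dim))
    du_dx <- (-3 * u_in + 4 * m$u[nb1, , drop = FALSE] -
                m$u[nb2, , drop = FALSE]) / 2
    for (j in seq_len(desc$dim)) {
      S[, 1, j] <- S[, 1, j] + du_dx[, j] / 2
      S[, j, 1] <- S[, j, 1] + du_dx[, j] / 2
    }
    for (k in seq_along(tdirs)) {
      d <- k + 1
      up <- matrix(0, length(cells), desc$dim)
      um <- matrix(0, length(cells), desc$dim)
      okp <- fluid[tdirs[[k]]$p]; okm <- fluid[tdirs[[k]]$m]
      up[okp, ] <- u_in[match(tdirs[[k]]$p[okp], cells), , drop = FALSE]
      um[okm, ] <- u_in[match(tdirs[[k]]$m[okm], cells), , drop = FALSE]
      up[is.na(up)] <- 0; um[is.na(um)] <- 0
      dd <- (up - um) / 2
      for (j in seq_len(desc$dim)) {
        S[, d, j] <- S[, d, j] + dd[, j] / 2
        S[, j, d] <- S[, j, d] + dd[, j] / 2
      }
    }
    feq <- lbm_equilibrium(rho_in, u_in, desc, warn_mach = FALSE)
    fneq <- matrix(0, length(cells), desc$q)
    for (a in seq_len(desc$q)) {
      qa <- outer(desc$cx[a, ], desc$cx[a, ]) - desc$cs2 * diag(desc$dim)
      qs <- numeric(length(cells))
      for (i in seq_len(desc$dim))
        for (j in seq_len(desc$dim))
          qs <- qs + qa[i, j] * S[, i, j]
      fneq[, a] <- -desc$w[a] * rho_in * tau0 / desc$cs2 * qs
    }
    f[cells, ] <- feq + fneq
    f
  }, cells = cells, class = "lbm_inlet")
}

#' Pressure-outlet boundary handler
#'
#' Fixes the outlet density (pressure) and copies velocity and
#' off-equilibrium populations from the neighboring bulk node.
#'
#' @param grid a voxel grid with an outlet plane (flag 3)
#' @param links streaming tables
#' @param desc lattice descriptor
#' @param rho_out outlet density (1 = reference pressure)
#' @return handler callable as `h(f)`
#' @export
pressure_outlet <- function(grid, links, desc, rho_out = 1) {
  cells <- which(as.vector(grid$flags) == 3L)
  if (!length(cells)) stop("grid has no outlet plane", call. = FALSE)
  a_xm <- which(desc$cx[, 1] == -1 & rowSums(abs(desc$cx)) == 1)
  nb1 <- links$nbr[cells, a_xm]              # interior neighbor (x - 1)
  structure(function(f) {
    m <- lbm_macroscopics(f, desc)
    u_nb <- m$u[nb1, , drop = FALSE]
    feq_nb <- lbm_equilibrium(m$rho[nb1], u_nb, desc, warn_mach = FALSE)
    fneq_nb <- f[nb1, , drop = FALSE] - feq_nb
    f[cells, ] <- lbm_equilibrium(rep(rho_out, length(cells)), u_nb, desc,
                                  warn_mach = FALSE) + fneq_nb
    f
  }, cells = cells, class = "lbm_outlet")
}

# --- driver -----------------------------------------------------------------

#' Run a lattice-Boltzmann simulation
#'
#' Collide (BGK + optional Smagorinsky) -> boundary repair (Bouzidi) ->
#' stream loop with optional body force, velocity inlet and pressure outlet.
#' Aborts with the step index if the density field degenerates.
#'
#' @param grid a voxel grid
#' @param desc lattice descriptor
#' @param tau0 molecular relaxation time
#' @param n_steps number of time steps
#' @param c_smag Smagorinsky constant (0 = plain BGK)
#' @param force constant body-force vector (lattice units), or a function of
#'   the step index returning one, or NULL
#' @param inlet a [velocity_inlet()] handler or NULL
#' @param inlet_waveform function of the step index returning the mean inlet
#'   velocity (lattice units); required with `inlet`
#' @param outlet a [pressure_outlet()] handler or NULL
#' @param f0 initial populations (default: rest equilibrium)
#' @param snapshot_every record macroscopic fields every this many steps
#'   (0 = only final)
#' @param links precomputed [build_links()] tables (built if NULL)
#' @return an `lbm_result`: final `f`, `rho`, `u`, `tau_eff`, `links`,
#'   `snapshots` (list of rho/u), `grid`, `desc`, `tau0`
#' @export
lbm_run <- function(grid, desc, tau0, n_steps, c_smag = 0,
                    force = NULL, inlet = NULL, inlet_waveform = NULL,
                    outlet = NULL, f0 = NULL, snapshot_every = 0L,
                    links = NULL) {
  if (is.null(links)) links <- build_links(grid, desc)
  N <- links$N
  f <- if (is.null(f0)) lbm_equilibrium(rep(1, N), matrix(0, N, desc$dim), desc)
       else f0
  const_force <- !is.null(force) && !is.function(force)
  snapshots <- list()
  cf <- NULL
  for (s in seq_len(n_steps)) {
    cf <- lbm_collide(f, desc, tau0, c_smag, return_fields = TRUE)
    fpost <- cf$f
    if (!is.null(force)) {
      g <- if (const_force) force else force(s)
      # F_a = 3 w_a rho (c_a . g)
      fpost <- fpost + 3 * sweep(outer(as.vector(cf$rho),
                                       as.vector(desc$cx %*% g)), 2,
                                 desc$w, "*")
    }
    f <- lbm_stream(fpost, links)
    if (!is.null(inlet)) {
      u_t <- inlet_waveform(s)
      f <- inlet(f, u_t, tau0)
    }
    if (!is.null(outlet)) f <- outlet(f)
    if (s %% max(n_steps %/% 8, 1) == 0) {
      rho_f <- rowSums(f[links$fluid, , drop = FALSE])
      if (any(!is.finite(rho_f)) || any(rho_f <= 0))
        stop("LBM diverged at step ", s, call. = FALSE)
    }
    if (snapshot_every > 0L && s %% snapshot_every == 0L) {
      m <- lbm_macroscopics(f, desc)
      snapshots[[length(snapshots) + 1]] <- list(step = s, rho = m$rho, u = m$u)
    }
  }
  m <- lbm_macroscopics(f, desc)
  out <- list(f = f, rho = m$rho, u = m$u, tau_eff = cf$tau_eff,
              links = links, snapshots = snapshots, grid = grid, desc = desc,
              tau0 = tau0, c_smag = c_smag, n_steps = n_steps)
  class(out) <- "lbm_result"
  out
}

#' @export
print.lbm_result <- function(x, ...) {
  uf <- sqrt(rowSums(x$u[x$links$fluid, , drop = FALSE]^2))
  cat(sprintf("<lbm_result> %s, %d steps, %d fluid cells, max |u| %.4f lu\n",
              x$desc$name, x$n_steps, sum(x$links$fluid), max(uf)))
  invisible(x)
}

# --- wall shear stress ------------------------------------------------------

#' Wall-shear-stress samples from a flow state
#'
#' For every wall-adjacent fluid cell: the deviatoric stress is obtained
#' from the second-order non-equilibrium moment, `eps_ij = -Pi_ij /
#' (2 rho tau cs2)` and `sigma_ij = 2 mu eps_ij` with `mu = rho cs2
#' (tau_eff - 1/2)`; the traction on the wall (outward normal n from the
#' signed-distance gradient) is projected onto the tangent plane,
#' `t_i = sigma_ij n_j - (n_k sigma_kj n_j) n_i`, whose magnitude is the
#' wall shear stress. Cells with a degenerate normal are skipped with a
#' warning.
#'
#' @param res an `lbm_result` (or a list with f, links, grid, desc, tau0)
#' @param um optional [unit_map()] for conversion to Pa
#' @return a `wall_sample_set` data.frame: cell index, coordinates, normal,
#'   tangential traction components, `shear_lat` (lattice units), `shear_pa`
#'   (if `um` given), `wall_dist` (lattice units to the wall along the
#'   normal, from the distance field)
#' @export
wall_stress <- function(res, um = NULL) {
  links <- res$links; grid <- res$grid; desc <- res$desc
  cells <- sort(unique(unlist(lapply(links$wall, function(w) w$ia))))
  if (!length(cells)) stop("geometry has no wall links", call. = FALSE)
  m <- lbm_macroscopics(res$f, desc)
  feq <- lbm_equilibrium(m$rho[cells], m$u[cells, , drop = FALSE], desc,
                         warn_mach = FALSE)
  fneq <- res$f[cells, , drop = FALSE] - feq
  pn <- .pi_neq(fneq, desc)
  tau <- if (length(res$tau_eff) > 1) res$tau_eff[cells] else res$tau_eff
  rho <- m$rho[cells]
  dimn <- desc$dim
  eps <- array(0, c(length(cells), dimn, dimn))
  for (k in seq_len(nrow(pn$pairs))) {
    i <- pn$pairs[k, 1]; j <- pn$pairs[k, 2]
    e <- -pn$Pi[, k] / (2 * rho * tau * desc$cs2)
    eps[, i, j] <- e
    eps[, j, i] <- e
  }
  mu <- rho * desc$cs2 * (tau - 0.5)
  nrm <- wall_normals(grid, cells)
  ok <- !is.na(nrm[, 1])
  if (any(!ok))
    warning(sum(!ok), " wall sample(s) skipped: degenerate normal")
  trac <- matrix(0, length(cells), dimn)
  for (i in seq_len(dimn))
    for (j in seq_len(dimn))
      trac[, i] <- trac[, i] + 2 * mu * eps[, i, j] * nrm[, j]
  tn <- rowSums(trac * nrm)
  tang <- trac - tn * nrm
  shear <- sqrt(rowSums(tang^2))
  coords <- as.matrix(expand.grid(lapply(grid$dims, seq_len)))[cells, , drop = FALSE]
  out <- data.frame(cell = cells, coords, nrm, tang,
                    shear_lat = shear,
                    wall_dist = abs(as.vector(grid$phi)[cells]))
  names(out) <- c("cell", paste0("x", seq_len(dimn)), paste0("n", seq_len(dimn)),
                  paste0("t", seq_len(dimn)), "shear_lat", "wall_dist")
  if (!is.null(um)) out$shear_pa <- out$shear_lat * um$p_scale
  out <- out[ok, ]
  class(out) <- c("wall_sample_set", class(out))
  out
}

# --- refinement harness and turbulence accumulators -------------------------

#' Mesh-refinement acceptance check
#'
#' Runs a flow case at a base resolution and at `ratio` times finer, and
#' reports the relative change of the peak velocity magnitude and of the
#' inlet-outlet pressure drop. The mesh is acceptable when both changes are
#' below 2 percent.
#'
#' @param run_at function(resolution) returning an `lbm_result`; lattice
#'   parameters must represent the same physical problem at each resolution
#'   (diffusive scaling)
#' @param base base resolution (integer)
#' @param ratio refinement ratio (default 1.5)
#' @param u_ref,dp_ref functions extracting peak velocity and pressure drop
#'   from an `lbm_result` in physical or consistently scaled units
#' @return list(coarse, fine, rel_change_u, rel_change_dp, accepted)
#' @export
mesh_refinement_check <- function(run_at, base, ratio = 1.5,
                                  u_ref = NULL, dp_ref = NULL) {
  res1 <- run_at(base)
  res2 <- run_at(as.integer(round(base * ratio)))
  get_u <- if (is.null(u_ref))
    function(r) max(sqrt(rowSums(r$u[r$links$fluid, , drop = FALSE]^2))) * attr(r, "u_scale")
  else u_ref
  get_dp <- if (is.null(dp_ref)) function(r) attr(r, "dp_phys") else dp_ref
  u1 <- get_u(res1); u2 <- get_u(res2)
  d1 <- get_dp(res1); d2 <- get_dp(res2)
  out <- list(coarse = res1, fine = res2,
              rel_change_u = abs(u2 - u1) / abs(u2),
              rel_change_dp = abs(d2 - d1) / abs(d2))
  out$accepted <- out$rel_change_u < 0.02 && out$rel_change_dp < 0.02
  out
}

#' Ensemble mean/fluctuation statistics over snapshots
#'
#' Accumulates velocity snapshots (e.g. the same cardiac-cycle phase across
#' cycles) into ensemble means, turbulent kinetic energy
#' `0.5 rho (u'^2 + v'^2 + w'^2)` and Reynolds-stress components
#' `rho u_i' u_j'`.
#'
#' @param u_list list of N x dim velocity matrices
#' @param rho density (scalar or vector), lattice units by default
#' @return list(mean_u, tke, rss) where rss has one column per component
#'   pair (order as in upper.tri by column)
#' @export
flow_statistics <- function(u_list, rho = 1) {
  stopifnot(length(u_list) >= 2)
  dimn <- ncol(u_list[[1]])
  um <- Reduce(`+`, u_list) / length(u_list)
  fluct <- lapply(u_list, function(u) u - um)
  tke <- 0.5 * rho * Reduce(`+`, lapply(fluct, function(e) rowSums(e^2))) /
    length(u_list)
  pairs <- which(upper.tri(diag(dimn)), arr.ind = TRUE)
  rss <- sapply(seq_len(nrow(pairs)), function(k) {
    rho * Reduce(`+`, lapply(fluct, function(e)
      e[, pairs[k, 1]] * e[, pairs[k, 2]])) / length(u_list)
  })
  list(mean_u = um, tke = tke, rss = rss)
}
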