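# Voxel geometries for the flow kernel, built from signed-distance functions
# (phi < 0 inside the fluid). The signed distance supplies everything the
# curved-wall treatment needs: cell flags, the per-link wall-distance
# fraction q (linear interpolation of phi along the link, exact for planar
# walls), and outward wall normals (smoothed gradient of phi).

#' Voxelize a signed-distance function
#'
#' Samples `phi_fn` at cell centers (1-based integer lattice coordinates) on
#' a grid of size `dims` and assembles a `voxel_grid`: flags (0 solid,
#' 1 fluid, 2 inlet, 3+ outlet), the sampled distance field and periodicity.
#' If the first axis is not periodic, the first/last fluid planes become the
#' inlet/outlet.
#'
#' @param phi_fn function taking an n x dim matrix of coordinates and
#'   returning signed distances (negative inside the fluid)
#' @param dims grid dimensions (length 2 or 3)
#' @param periodic logical vector per axis
#' @return a `voxel_grid` object
#' @export
voxelize_sdf <- function(phi_fn, dims, periodic = c(TRUE, FALSE, FALSE)[seq_along(dims)]) {
  dim <- length(dims)
  stopifnot(dim %in% c(2L, 3L))
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))
  colnames(coords) <- NULL
  phi <- array(phi_fn(coords), dim = dims)
  flags <- array(ifelse(phi < 0, 1L, 0L), dim = dims)
  if (!periodic[1]) {
    # first and last planes along axis 1 that contain fluid
    ax_any <- apply(flags == 1L, 1, any)
    i_in <- which(ax_any)[1]
    i_out <- rev(which(ax_any))[1]
    if (dim == 2L) {
      flags[i_in, ][flags[i_in, ] == 1L] <- 2L
      flags[i_out, ][flags[i_out, ] == 1L] <- 3L
    } else {
      sl <- flags[i_in, , ]; sl[sl == 1L] <- 2L; flags[i_in, , ] <- sl
      sl <- flags[i_out, , ]; sl[sl == 1L] <- 3L; flags[i_out, , ] <- sl
    }
  }
  g <- list(dims = dims, dim = dim, phi = phi, flags = flags,
            periodic = periodic)
  class(g) <- "voxel_grid"
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      ", fluid cells: ", sum(x$flags > 0L), "\n", sep = "")
  invisible(x)
}

# linear cell index from integer coordinates (column-major), with wrap
.lin_index <- function(coords, dims) {
  idx <- coords[, 1]
  mult <- 1
  for (d in seq_along(dims)[-1]) {
    mult <- mult * dims[d - 1]
    idx <- idx + (coords[, d] - 1L) * mult
  }
  idx
}

.wrap <- function(x, n) ((x - 1L) %% n) + 1L

#' Precompute streaming and wall-link tables for a grid/descriptor pair
#'
#' For every direction: the pull index map (periodic wrap), and for every
#' fluid cell whose link in that direction crosses into a solid cell, the
#' wall-distance fraction `q in (0, 1]` from linear interpolation of the
#' signed-distance field along the link, the upstream cell index used by the
#' interpolated bounce-back, and whether that upstream cell is fluid.
#'
#' @param grid a [voxelize_sdf()] grid
#' @param desc a lattice descriptor ([d2q9()] / [d3q19()])
#' @return a `lbm_links` list
#' @export
build_links <- function(grid, desc) {
  stopifnot(grid$dim == desc$dim)
  dims <- grid$dims
  N <- prod(dims)
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))
  colnames(coords) <- NULL
  fluid <- as.vector(grid$flags) > 0L
  phi <- as.vector(grid$phi)

  pull <- matrix(1L, N, desc$q)
  nbr <- matrix(1L, N, desc$q)
  for (a in seq_len(desc$q)) {
    cm <- coords
    cp <- coords
    for (d in seq_len(grid$dim)) {
      cm[, d] <- .wrap(coords[, d] - desc$cx[a, d], dims[d])
      cp[, d] <- .wrap(coords[, d] + desc$cx[a, d], dims[d])
    }
    pull[, a] <- .lin_index(cm, dims)
    nbr[, a] <- .lin_index(cp, dims)
  }

  wall <- vector("list", desc$q)
  for (a in seq_len(desc$q)) {
    if (all(desc$cx[a, ] == 0)) next
    ia <- which(fluid & !fluid[nbr[, a]])
    if (!length(ia)) next
    pa <- phi[ia]; pb <- phi[nbr[ia, a]]
    q <- pa / (pa - pb)              # pa < 0 <= pb
    q <- pmin(pmax(q, 0.02), 1)
    ie <- pull[ia, a]                # upstream fluid neighbor x_A - c_a
    wall[[a]] <- list(ia = ia, q = q, ie = ie, ie_fluid = fluid[ie])
  }
  structure(list(pull = pull, nbr = nbr, wall = wall, fluid = fluid,
                 N = N, desc = desc, dims = dims),
            class = "lbm_links")
}

#' Outward wall normals from the signed-distance field
#'
#' Central-difference gradient of phi, normalized; at wall-adjacent cells
#' this approximates the outward (into-solid) unit normal.
#'
#' @param grid a [voxelize_sdf()] grid
#' @param cells linear cell indices at which to evaluate
#' @return matrix of unit normals (length(cells) x dim); rows of degenerate
#'   gradient are NA
#' @export
wall_normals <- function(grid, cells) {
  dims <- grid$dims
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))[cells, , drop = FALSE]
  colnames(coords) <- NULL
  grad <- matrix(0, length(cells), grid$dim)
  phi <- grid$phi
  for (d in seq_len(grid$dim)) {
    cp <- coords; cm <- coords
    cp[, d] <- .wrap(coords[, d] + 1L, dims[d])
    cm[, d] <- .wrap(coords[, d] - 1L, dims[d])
    grad[, d] <- (as.vector(phi)[.lin_index(cp, dims)] -
                    as.vector(phi)[.lin_index(cm, dims)]) / 2
  }
  nn <- sqrt(rowSums(grad^2))
  bad <- nn < 1e-12
  grad <- grad / pmax(nn, 1e-12)
  grad[bad, ] <- NA_real_
  grad
}

# ---------------------------------------------------------------------------
# parametric toy vessels

#' Straight 2D channel
#'
#' Periodic in x; plane walls at `y_lo`/`y_hi` (continuous lattice
#' coordinates, so fractional values exercise arbitrary wall offsets q).
#'
#' @param nx,ny grid size
#' @param y_lo,y_hi wall positions; defaults put the walls half a cell
#'   outside the first/last fluid row (q = 1/2 everywhere)
#' @return a `voxel_grid`
#' @export
vessel_channel2d <- function(nx, ny, y_lo = 1.5, y_hi = ny - 0.5) {
  voxelize_sdf(function(xy) pmax(y_lo - xy[, 2], xy[, 2] - y_hi),
               c(nx, ny), periodic = c(TRUE, FALSE))
}

#' Diagonal 2D channel array (walls not lattice-aligned)
#'
#' A 45-degree channel in a doubly periodic square box; the slab pattern
#' tiles exactly, so the flow is driven by a body force along the channel
#' axis. The walls cut lattice links at varying fractions, exercising the
#' interpolated bounce-back off-axis.
#'
#' @param n box size (square)
#' @param width_frac channel width as a fraction of the diagonal period
#' @return a `voxel_grid`
#' @export
vessel_channel2d_diag <- function(n, width_frac = 0.55) {
  P <- n / sqrt(2)   # diagonal period
  W <- width_frac * P
  voxelize_sdf(function(xy) {
    s <- (xy[, 2] - xy[, 1]) / sqrt(2)
    sm <- s - P * floor(s / P)
    abs(sm - P / 2) - W / 2
  }, c(n, n), periodic = c(TRUE, TRUE))
}

#' Straight 3D circular tube
#'
#' Axis along x. Periodic by default (body-force driven); set
#' `periodic = FALSE` to obtain inlet/outlet planes.
#'
#' @param nx axial cells
#' @param n transverse cells (square cross-section bounding box)
#' @param radius tube radius in lattice units (default centers the wall
#'   between the last fluid and first solid cell ring)
#' @param periodic axial periodicity
#' @return a `voxel_grid`
#' @export
vessel_tube3d <- function(nx, n, radius = (n - 2) / 2, periodic = TRUE) {
  ctr <- (n + 1) / 2
  voxelize_sdf(function(xyz) {
    sqrt((xyz[, 2] - ctr)^2 + (xyz[, 3] - ctr)^2) - radius
  }, c(nx, n, n), periodic = c(periodic, FALSE, FALSE))
}

#' Cosine-constricted 2D channel (stenosis model)
#'
#' Channel with a smooth cosine narrowing: the throat width is
#' `throat_ratio` times the unobstructed width, emulating a coarctation with
#' EOA/A equal to `throat_ratio` (2D area ratio = width ratio).
#'
#' @param nx,ny grid size
#' @param throat_ratio throat/reference area ratio in (0, 1]
#' @param len_frac constriction length as a fraction of nx
#' @param periodic axial periodicity (FALSE gives inlet/outlet planes)
#' @return a `voxel_grid`
#' @export
vessel_stenosis2d <- function(nx, ny, throat_ratio = 0.4, len_frac = 0.4,
                              periodic = FALSE) {
  y_lo <- 1.5; y_hi <- ny - 0.5
  yc <- (y_lo + y_hi) / 2
  h0 <- (y_hi - y_lo) / 2
  xc <- (nx + 1) / 2
  Lc <- len_frac * nx
  voxelize_sdf(function(xy) {
    x <- xy[, 1]
    h <- ifelse(abs(x - xc) <= Lc / 2,
                h0 * (1 - (1 - throat_ratio) / 2 * (1 + cos(2 * pi * (x - xc) / Lc))),
                h0)
    abs(xy[, 2] - yc) - h
  }, c(nx, ny), periodic = c(periodic, FALSE))
}

#' Cosine-constricted 3D tube
#'
#' Tube whose radius narrows smoothly so the throat cross-sectional AREA is
#' `throat_area_ratio` times the unobstructed area.
#'
#' @param nx axial cells
#' @param n transverse cells
#' @param throat_area_ratio throat/reference area ratio (EOA/A)
#' @param len_frac constriction length as a fraction of nx
#' @param periodic axial periodicity
#' @return a `voxel_grid`
#' @export
vessel_stenosis3d <- function(nx, n, throat_area_ratio = 0.4, len_frac = 0.4,
                              periodic = FALSE) {
  ctr <- (n + 1) / 2
  R0 <- (n - 2) / 2
  rr <- sqrt(throat_area_ratio)
  xc <- (nx + 1) / 2
  Lc <- len_frac * nx
  voxelize_sdf(function(xyz) {
    x <- xyz[, 1]
    R <- ifelse(abs(x - xc) <= Lc / 2,
                R0 * (1 - (1 - rr) / 2 * (1 + cos(2 * pi * (x - xc) / Lc))),
                R0)
    sqrt((xyz[, 2] - ctr)^2 + (xyz[, 3] - ctr)^2) - R
  }, c(nx, n, n), periodic = c(periodic, FALSE, FALSE))
}

# distance from points P to segment AB (rows of p; a, b length-dim)
.seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- ((p - matrix(a, nrow(p), length(a), byrow = TRUE)) %*% ab) / sum(ab^2)
  t <- pmin(pmax(as.vector(t), 0), 1)
  proj <- matrix(a, nrow(p), length(a), byrow = TRUE) + outer(t, ab)
  sqrt(rowSums((p - proj)^2))
}

#' Constricted 3D tube with an extra-anatomical bypass loop
#'
#' The main tube narrows at mid-length (the coarctation); a bypass conduit
#' leaves the main axis upstream of the throat, arches over it (three
#' straight segments) and rejoins downstream, emulating an extra-anatomical
#' graft left alongside the stenosis. Graft proportions follow the published
#' graft geometries (length about 5 tube diameters, diameter about 0.8 of
#' the aortic diameter).
#'
#' @param nx axial cells
#' @param n transverse cells of the main-tube bounding box
#' @param throat_area_ratio coarctation EOA/A
#' @param graft_radius_frac bypass radius as a fraction of the main radius
#' @param offset_frac bypass apex offset from the axis, fraction of nx
#' @return a `voxel_grid` (inlet/outlet on the first axis)
#' @export
vessel_bypass3d <- function(nx, n, throat_area_ratio = 0.4,
                            graft_radius_frac = 0.8, offset_frac = 0.22) {
  ctr <- (n + 1) / 2
  R0 <- (n - 2) / 2
  rb <- graft_radius_frac * R0
  rr <- sqrt(throat_area_ratio)
  xc <- (nx + 1) / 2
  Lc <- 0.3 * nx
  x1 <- xc - 0.28 * nx; x2 <- xc + 0.28 * nx
  yb <- ctr + R0 + offset_frac * nx
  a1 <- c(x1, ctr, ctr); a2 <- c(x1, yb, ctr)
  a3 <- c(x2, yb, ctr); a4 <- c(x2, ctr, ctr)
  ny_tot <- ceiling(yb + rb + 2)
  voxelize_sdf(function(xyz) {
    x <- xyz[, 1]
    R <- ifelse(abs(x - xc) <= Lc / 2,
                R0 * (1 - (1 - rr) / 2 * (1 + cos(2 * pi * (x - xc) / Lc))),
                R0)
    phi_main <- sqrt((xyz[, 2] - ctr)^2 + (xyz[, 3] - ctr)^2) - R
    phi_b <- pmin(.seg_dist(xyz, a1, a2),
                  .seg_dist(xyz, a2, a3),
                  .seg_dist(xyz, a3, a4)) - rb
    pmin(phi_main, phi_b)
  }, c(nx, ny_tot, n), periodic = c(FALSE, FALSE, FALSE))
}
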