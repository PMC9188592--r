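# Analytic flow benchmarks at the fast (CI) resolutions.

test_that("body-force Poiseuille channel matches the parabolic profile", {
  ny <- 35; g <- 1e-6; tau0 <- 0.8; nu <- (tau0 - 0.5) / 3
  grid <- vessel_channel2d(6, ny)
  res <- lbm_run(grid, d2q9(), tau0, n_steps = 12000, force = c(g, 0))
  fl <- res$links$fluid
  co <- as.matrix(expand.grid(seq_len(6), seq_len(ny)))[fl, ]
  prof <- tapply(res$u[fl, 1], co[, 2], mean)
  yy <- as.numeric(names(prof))
  ylo <- 1.5; yhi <- ny - 0.5
  ua <- g / (2 * nu) * (yy - ylo) * (yhi - yy)
  expect_lt(abs(max(prof) - max(ua)) / max(ua), 0.02)
  expect_lt(sqrt(mean((prof - ua)^2)) / max(ua), 0.02)
})

test_that("oscillatory channel flow matches the analytic series (alpha = 4)", {
  ny <- 34; h <- (ny - 2) / 2
  tau0 <- 0.8; nu <- (tau0 - 0.5) / 3
  om <- 16 * nu / h^2          # Womersley number 4
  g0 <- 1e-6
  Tper <- 2 * pi / om
  nsteps <- round(5 * Tper)
  res <- lbm_run(vessel_channel2d(4, ny), d2q9(), tau0, n_steps = nsteps,
                 force = function(s) c(g0 * cos(om * s), 0),
                 snapshot_every = max(1, round(Tper / 16)))
  fl <- res$links$fluid
  co <- as.matrix(expand.grid(seq_len(4), seq_len(ny)))
  snaps <- Filter(function(s) s$step > nsteps - Tper - 1, res$snapshots)
  uamp <- Reduce(pmax, lapply(snaps, function(s) abs(s$u[fl, 1])))
  prof <- tapply(uamp, co[fl, 2], mean)
  yy <- as.numeric(names(prof)); yc <- (1.5 + ny - 0.5) / 2
  amp_a <- Reduce(pmax, lapply(seq(0, Tper, length.out = 64), function(tt)
    abs(womersley_profile(yy - yc, h, tt, g0, om, nu))))
  expect_lt(abs(max(prof) - max(amp_a)) / max(amp_a), 0.05)
  sel <- amp_a > 0.3 * max(amp_a)
  expect_lt(max(abs(prof[sel] - amp_a[sel])) / max(amp_a), 0.05)
})

test_that("off-axis walls converge at close to second order", {
  # 45-degree channel array driven along its axis; error vs resolution
  err_at <- function(n) {
    tau0 <- 0.8; nu <- (tau0 - 0.5) / 3
    g <- 2e-6 * (24 / n)^3     # keep peak velocity comparable across sizes
    grid <- vessel_channel2d_diag(n, 0.55)
    gdir <- c(1, 1) / sqrt(2)
    res <- lbm_run(grid, d2q9(), tau0, n_steps = round(1500 * (n / 24)^2),
                   force = g * gdir)
    fl <- res$links$fluid
    co <- as.matrix(expand.grid(seq_len(n), seq_len(n)))[fl, ]
    ua <- (res$u[fl, 1] + res$u[fl, 2]) / sqrt(2)   # axial component
    P <- n / sqrt(2); W <- 0.55 * P
    s <- (co[, 2] - co[, 1]) / sqrt(2)
    sm <- s - P * floor(s / P)
    d <- abs(sm - P / 2)                            # distance from centerline
    uan <- g / (2 * nu) * (W^2 / 4 - d^2)
    keep <- uan > 0
    sqrt(mean((ua[keep] - uan[keep])^2)) / max(uan)
  }
  ns <- c(24, 36, 54)
  errs <- vapply(ns, err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  slope <- -coef(lm(log(errs) ~ log(ns)))[2]
  expect_gt(slope, 1.5)
})

test_that("velocity inlet enforces its target and conserves mass", {
  nx <- 60; ny <- 26
  # straight channel with inlet/outlet planes (non-periodic)
  grid <- voxelize_sdf(function(xy) pmax(1.5 - xy[, 2], xy[, 2] - (ny - 0.5)),
                       c(nx, ny), periodic = c(FALSE, FALSE))
  desc <- d2q9()
  links <- build_links(grid, desc)
  inl <- velocity_inlet(grid, links, desc, "plug")
  out <- pressure_outlet(grid, links, desc)
  u0 <- 0.03
  res <- lbm_run(grid, desc, 0.65, n_steps = 4000, inlet = inl,
                 inlet_waveform = smooth_startup(function(t) u0, 800),
                 outlet = out, links = links)
  icells <- which(as.vector(grid$flags) == 2L)
  expect_lt(abs(mean(res$u[icells, 1]) - u0) / u0, 0.005)
  # inlet mass flux = rho ubar A within 1 percent
  flux_in <- sum(res$rho[icells] * res$u[icells, 1])
  expect_lt(abs(flux_in - mean(res$rho[icells]) * u0 * length(icells)) /
              flux_in, 0.01)
  # zero-velocity target: no-flow steady state
  res0 <- lbm_run(grid, desc, 0.65, n_steps = 600, inlet = inl,
                  inlet_waveform = function(t) 0, outlet = out, links = links)
  expect_lt(max(abs(res0$u[res0$links$fluid, ])), 1e-10)
})

test_that("throat velocity in a constricted channel follows continuity", {
  nx <- 100; ny <- 30; ratio <- 0.4
  grid <- vessel_stenosis2d(nx, ny, throat_ratio = ratio)
  desc <- d2q9()
  links <- build_links(grid, desc)
  inl <- velocity_inlet(grid, links, desc, "parabolic")
  out <- pressure_outlet(grid, links, desc)
  u0 <- 0.035
  res <- lbm_run(grid, desc, 0.65, n_steps = 5000, inlet = inl,
                 inlet_waveform = smooth_startup(function(t) u0, 1200),
                 outlet = out, links = links)
  fl <- res$links$fluid
  umag <- sqrt(rowSums(res$u[fl, ]^2))
  co <- as.matrix(expand.grid(seq_len(nx), seq_len(ny)))[fl, ]
  inlet_peak <- max(umag[co[, 1] <= 3])
  expect_lt(abs(max(umag) / inlet_peak - 1 / ratio) / (1 / ratio), 0.2)
})

test_that("tube flow with curved Bouzidi walls matches 3D Poiseuille", {
  n <- 18; R <- (n - 2) / 2
  tau0 <- 0.8; nu <- (tau0 - 0.5) / 3; g <- 5e-7
  res <- lbm_run(vessel_tube3d(4, n), d3q19(), tau0, n_steps = 3500,
                 force = c(g, 0, 0))
  umax <- max(res$u[res$links$fluid, 1])
  expect_lt(abs(umax - g * R^2 / (4 * nu)) / (g * R^2 / (4 * nu)), 0.02)
})

test_that("the LES closure is inert for resolved laminar flow", {
  ny <- 27; g <- 1e-6; tau0 <- 0.8
  grid <- vessel_channel2d(4, ny)
  r0 <- lbm_run(grid, d2q9(), tau0, n_steps = 6000, force = c(g, 0))
  r1 <- lbm_run(grid, d2q9(), tau0, n_steps = 6000, force = c(g, 0),
                c_smag = 0.1)
  fl <- r0$links$fluid
  expect_lt(max(abs(r1$u[fl, 1] - r0$u[fl, 1])) / max(r0$u[fl, 1]), 0.01)
})

test_that("wall shear stress matches the analytic channel value", {
  # 64 cells across the gap per the resolution criterion
  ny <- 66; g <- 2e-7; tau0 <- 0.8
  grid <- vessel_channel2d(5, ny)
  res <- lbm_run(grid, d2q9(), tau0, n_steps = 25000, force = c(g, 0))
  ws <- wall_stress(res)
  tw <- g * (ny - 2) / 2          # rho g H/2, lattice units
  expect_lt(abs(mean(ws$shear_lat) - tw) / tw, 0.03)
  # traction is tangential: t . n = 0 at machine scale
  tn <- rowSums(as.matrix(ws[, c("t1", "t2")]) * as.matrix(ws[, c("n1", "n2")]))
  expect_lt(max(abs(tn)), 1e-10 * max(ws$shear_lat))
  # physical conversion
  um <- unit_map(dx = 1e-4, nu_lattice = (tau0 - 0.5) / 3)
  ws2 <- wall_stress(res, um)
  expect_equal(ws2$shear_pa, ws2$shear_lat * um$p_scale)
})

test_that("a quiescent field exerts no wall shear", {
  grid <- vessel_channel2d(5, 12)
  res <- lbm_run(grid, d2q9(), 0.7, n_steps = 50)
  ws <- wall_stress(res)
  expect_lt(max(ws$shear_lat), 1e-10)
})

test_that("mesh refinement changes the solution by less than 2 percent", {
  # inlet-driven constricted channel rerun at 1.5x resolution under
  # diffusive scaling; peak velocity and inlet-outlet pressure drop are the
  # headline acceptance quantities
  run_at <- function(ny) {
    desc <- d2q9()
    nx <- round(10 * ny / 3)
    grid <- vessel_stenosis2d(nx, ny, throat_ratio = 0.45)
    links <- build_links(grid, desc)
    u0 <- 0.04 * 24 / ny                 # fixed physical velocity
    res <- lbm_run(grid, desc, 0.62, n_steps = round(4000 * (ny / 24)^2),
                   inlet = velocity_inlet(grid, links, desc, "parabolic"),
                   inlet_waveform = smooth_startup(function(t) u0,
                                                   round(1000 * (ny / 24)^2)),
                   outlet = pressure_outlet(grid, links, desc), links = links)
    H <- ny - 2
    attr(res, "u_scale") <- H            # u_phys ~ u_lat / dx, dx ~ 1/H
    icells <- which(as.vector(grid$flags) == 2L)
    ocells <- which(as.vector(grid$flags) == 3L)
    dp_lat <- (mean(res$rho[icells]) - mean(res$rho[ocells])) / 3
    attr(res, "dp_phys") <- dp_lat * H^2  # pressure scale ~ (dx/dt)^2 ~ H^2
    res
  }
  chk <- mesh_refinement_check(run_at, base = 24, ratio = 1.5)
  expect_lt(chk$rel_change_u, 0.02)
  expect_lt(chk$rel_change_dp, 0.02)
  expect_true(chk$accepted)
})
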