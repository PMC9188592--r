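test_that("lattice descriptors satisfy the moment and symmetry identities", {
  for (desc in list(d2q9(), d3q19())) {
    expect_equal(sum(desc$w), 1)
    expect_equal(as.vector(t(desc$w) %*% desc$cx), rep(0, desc$dim))
    expect_identical(desc$opp[desc$opp], seq_len(desc$q))  # involution
    # second moment isotropy: sum w c_i c_j = cs2 delta_ij
    m2 <- t(desc$cx) %*% (desc$w * desc$cx)
    expect_equal(m2, diag(desc$dim) / 3, tolerance = 1e-12)
  }
})

test_that("the unit map enforces diffusive scaling", {
  um <- unit_map(dx = 1e-4, nu_phys = 0.0035 / 1050, nu_lattice = 0.05)
  expect_identical(um$dt, (um$nu_lattice / um$nu_phys) * um$dx^2)
  expect_equal(um$tau0, 0.05 * 3 + 0.5)
  expect_equal(um$u_scale, um$dx / um$dt)
})

test_that("equilibrium populations reproduce their defining moments", {
  desc <- d3q19()
  expect_equal(as.vector(lbm_equilibrium(1, matrix(0, 1, 3), desc)), desc$w)
  expect_equal(lbm_equilibrium(1, matrix(0, 1, 3), desc)[1], 1 / 3)
  set.seed(4)
  rho <- runif(20, 0.8, 1.2)
  u <- matrix(runif(60, -0.05, 0.05), 20)
  f <- lbm_equilibrium(rho, u, desc)
  expect_equal(rowSums(f), rho, tolerance = 1e-13)
  expect_equal(f %*% desc$cx, rho * u, tolerance = 1e-13)
  expect_warning(lbm_equilibrium(1, matrix(c(0.4, 0, 0), 1), desc), "0.3")
})

test_that("collision reduces to BGK at equilibrium and with c_smag = 0", {
  desc <- d2q9()
  set.seed(5)
  rho <- runif(12, 0.9, 1.1); u <- matrix(runif(24, -0.04, 0.04), 12)
  feq <- lbm_equilibrium(rho, u, desc)
  out <- lbm_collide(feq, desc, tau0 = 0.7, c_smag = 0.1, return_fields = TRUE)
  expect_equal(out$tau_eff, rep(0.7, 12), tolerance = 1e-9)
  expect_equal(out$f, feq, tolerance = 1e-12)
  f <- feq + matrix(rnorm(12 * 9, 0, 1e-4), 12)
  expect_identical(lbm_collide(f, desc, 0.7, c_smag = 0),
                   f - (f - lbm_equilibrium(rowSums(f), (f %*% desc$cx) / rowSums(f), desc)) / 0.7)
})

test_that("the Smagorinsky effective relaxation matches the scalar closure", {
  desc <- d2q9()
  # craft a known off-equilibrium xy moment
  rho <- 1; cs <- 0.1; tau0 <- 0.6
  delta <- 1e-3
  fneq <- delta * desc$w * desc$cx[, 1] * desc$cx[, 2]
  f <- lbm_equilibrium(1, matrix(0, 1, 2), desc) + rbind(fneq)
  out <- lbm_collide(f, desc, tau0, c_smag = cs, return_fields = TRUE)
  # oracle: Pi_xy = sum fneq cx cy (other components vanish by symmetry),
  # |Pi| = sqrt(2) |Pi_xy|; tau = (tau0 + sqrt(tau0^2 + 2 sqrt2 cs^2 |Pi| / (rho cs4)))/2
  pi_xy <- sum(fneq * desc$cx[, 1] * desc$cx[, 2])
  q_norm <- sqrt(2 * pi_xy^2)
  tau_oracle <- (tau0 + sqrt(tau0^2 + 2 * sqrt(2) * cs^2 * q_norm /
                               (rho * (1 / 3)^2))) / 2
  expect_equal(unname(out$tau_eff[1]), tau_oracle, tolerance = 1e-10)
  expect_gt(unname(out$tau_eff[1]), tau0)
})

test_that("streaming advects populations exactly and conserves mass", {
  desc <- d2q9()
  grid <- voxelize_sdf(function(xy) rep(-1, nrow(xy)), c(8, 6),
                       periodic = c(TRUE, TRUE))  # fully periodic fluid box
  links <- build_links(grid, desc)
  f <- matrix(0, 48, 9)
  cell <- 3 + (2 - 1) * 8   # (3, 2)
  f[cell, 2] <- 1           # +x population
  fs <- lbm_stream(f, links)
  expect_equal(which(fs[, 2] != 0), 4 + (2 - 1) * 8)
  # two single steps equal one distance-2 displacement on a random field
  set.seed(6)
  f <- matrix(runif(48 * 9), 48)
  f2 <- lbm_stream(lbm_stream(f, links), links)
  for (a in seq_len(9)) {
    arr <- array(f[, a], c(8, 6))
    sh <- desc$cx[a, ]
    arr2 <- arr[((seq_len(8) - 1 - 2 * sh[1]) %% 8) + 1,
                ((seq_len(6) - 1 - 2 * sh[2]) %% 6) + 1]
    expect_equal(array(f2[, a], c(8, 6)), arr2)
  }
  expect_equal(sum(lbm_stream(f, links)), sum(f), tolerance = 1e-12)
})

test_that("Bouzidi at q = 1/2 equals plain bounce-back bit for bit", {
  desc <- d2q9()
  grid <- vessel_channel2d(10, 9)   # walls exactly midway: q = 1/2
  links <- build_links(grid, desc)
  for (wl in links$wall) if (!is.null(wl)) expect_true(all(wl$q == 0.5))
  set.seed(7)
  f <- matrix(runif(90 * 9), 90)
  expect_identical(lbm_stream(f, links),
                   plain_bounceback_stream(f, grid, desc))
  # branch continuity at the q = 1/2 junction: both formulas give f_a^c(x_A)
  fa <- 0.37; fe <- 0.81; fab <- 0.12; q <- 0.5
  expect_identical(2 * q * fa + (1 - 2 * q) * fe, fa)
  expect_identical(fa / (2 * q) + (2 * q - 1) / (2 * q) * fab, fa)
})

test_that("smooth startup ramps continuously with the closed-form peak slope", {
  wf <- function(t) 1.5 + 0.5 * sin(2 * pi * t)
  ramp <- smooth_startup(wf, t_ramp = 2)
  expect_equal(ramp(0), 0)
  expect_equal(ramp(2), wf(0))
  expect_equal(ramp(2 + 0.3), wf(0.3))
  tg <- seq(0, 2, by = 1e-4)
  slope <- max(abs(diff(ramp(tg)) / 1e-4))
  expect_equal(slope, pi / 2 * wf(0) / 2, tolerance = 1e-3)
  expect_error(smooth_startup(wf, 0), "t_ramp")
})

test_that("outlet split is exactly area-proportional", {
  expect_equal(outlet_split(9, c(2, 2, 2)), c(3, 3, 3))
  expect_equal(sum(outlet_split(12.34, c(1.2, 3.4, 0.7))), 12.34)
  expect_equal(outlet_split(10, c(1, 2, 3)), 10 * c(1, 2, 3) / 6)
  expect_error(outlet_split(1, numeric(0)), "no outlet")
})

test_that("y+ follows the friction-velocity definition", {
  expect_equal(y_plus(0, 1e-4), 0)
  # calculator oracle: y 1e-4 m, tau_w 1 Pa, rho 1050, nu 10/3 um2/s
  expect_equal(y_plus(1, 1e-4, nu_phys = 1 / 3e5, rho_phys = 1050),
               1e-4 * sqrt(1 / 1050) * 3e5)
  expect_equal(y_plus(1, 2e-4), 2 * y_plus(1, 1e-4))
})

test_that("ensemble accumulators recover imposed fluctuation statistics", {
  set.seed(8)
  base <- matrix(rnorm(40 * 2), 40)
  snaps <- lapply(1:6, function(i) base + cbind(rep(c(-1, 1)[1 + i %% 2], 40), 0))
  st <- flow_statistics(snaps)
  expect_equal(st$mean_u, base, tolerance = 1e-12)
  expect_equal(st$tke, rep(0.5 * 1, 40), tolerance = 1e-12)  # var x = 1, y = 0
  expect_equal(as.vector(st$rss), rep(0, 40), tolerance = 1e-12)
})
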