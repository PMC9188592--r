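make_smooth_field <- function(dims = c(20, 16, 12), noise = 0, seed = 1) {
  set.seed(seed)
  co <- as.matrix(expand.grid(lapply(dims, seq_len)))
  u <- array(0, c(dims, 3))
  u[, , , 1] <- array(sin(2 * pi * co[, 1] / dims[1]) *
                        cos(2 * pi * co[, 2] / dims[2]), dims)
  u[, , , 2] <- array(0.5 * cos(2 * pi * co[, 3] / dims[3]), dims)
  u[, , , 3] <- array(0.2 * co[, 1] / dims[1], dims)
  if (noise > 0) u <- u + array(rnorm(length(u), 0, noise), dim(u))
  vector_field(u, spacing = c(1, 1, 1))
}

test_that("down-sampling is exact for constant and linear fields", {
  dims <- c(12, 10, 8)
  u <- array(2.5, c(dims, 3))
  const <- vector_field(u, spacing = c(1, 1, 1))
  ds <- downsample_field(const, c(5, 4, 3))
  expect_true(all(abs(ds$u - 2.5) < 1e-12))
  co <- as.matrix(expand.grid(lapply(dims, seq_len)))
  lin <- array(0, c(dims, 3))
  for (k in 1:3) lin[, , , k] <- array(0.5 + 0.1 * co[, 1] - 0.2 * co[, 2] +
                                         0.05 * co[, 3], dims)
  vf <- vector_field(lin, spacing = c(1, 1, 1))
  ds <- downsample_field(vf, c(5, 4, 3))
  cou <- as.matrix(expand.grid(seq(1, 12, length = 5), seq(1, 10, length = 4),
                               seq(1, 8, length = 3)))
  expect_equal(as.vector(ds$u[, , , 2]),
               0.5 + 0.1 * cou[, 1] - 0.2 * cou[, 2] + 0.05 * cou[, 3],
               tolerance = 1e-12)
  expect_error(downsample_field(vf, c(5, 4, 3), spacing = c(10, 1, 1)),
               "outside")
})

test_that("down-sampling matches an independent interpolation oracle", {
  vf <- make_smooth_field()
  ds <- downsample_field(vf, c(7, 6, 5))
  # oracle: loop-based trilinear interpolation at 10 probe voxels
  set.seed(3)
  probes <- cbind(sample(7, 10, TRUE), sample(6, 10, TRUE), sample(5, 10, TRUE))
  for (k in seq_len(10)) {
    pc <- ds$origin + (probes[k, ] - 1) * ds$spacing
    gi <- (pc - vf$origin) / vf$spacing + 1
    lo <- pmin(floor(gi), vf$dims - 1); fr <- gi - lo
    val <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
      val <- val + w * vf$u[lo[1] + cx, lo[2] + cy, lo[3] + cz, 1]
    }
    expect_equal(ds$u[probes[k, 1], probes[k, 2], probes[k, 3], 1], val,
                 tolerance = 1e-12)
  }
})

test_that("down-sampling propagates invalid voxels", {
  vf <- make_smooth_field(c(12, 10, 8))
  vf$mask[6, 5, 4] <- FALSE
  ds <- downsample_field(vf, c(12, 10, 8), spacing = c(1, 1, 1))
  expect_false(ds$mask[6, 5, 4])
  expect_true(sum(!ds$mask) == 1)
})

test_that("GCV smoothing preserves clean fields and suppresses noise", {
  vf <- make_smooth_field()
  sm <- smooth_field(vf)
  rms <- sqrt(mean((sm$u - vf$u)^2)) / sqrt(mean(vf$u^2))
  expect_lt(rms, 0.01)
  truth <- make_smooth_field()
  for (sn in c(5, 10)) {  # SNR >= 5: smoothing must improve on no smoothing
    noisy <- make_smooth_field(noise = sd(truth$u) / sn, seed = 7)
    smn <- smooth_field(noisy)
    err_raw <- sqrt(mean((noisy$u - truth$u)^2))
    err_sm <- sqrt(mean((smn$u - truth$u)^2))
    expect_lt(err_sm, err_raw)
  }
})

test_that("robust smoothing replaces an injected outlier", {
  vf <- make_smooth_field()
  i <- c(10, 8, 6)
  local_sd <- sd(vf$u[i[1] + (-2:2), i[2] + (-2:2), i[3] + (-2:2), 1])
  vf$u[i[1], i[2], i[3], 1] <- 10 * max(abs(vf$u[, , , 1]))
  sm <- smooth_field(vf, robust = TRUE)
  clean <- make_smooth_field()
  expect_lt(abs(sm$u[i[1], i[2], i[3], 1] - clean$u[i[1], i[2], i[3], 1]),
            3 * local_sd)
})

test_that("masked voxels are imputed from the smooth surroundings", {
  vf <- make_smooth_field()
  truth <- make_smooth_field()
  vf$mask[9:11, 8, 6] <- FALSE
  sm <- smooth_field(vf)
  expect_true(all(sm$mask))
  expect_lt(max(abs(sm$u[9:11, 8, 6, 1] - truth$u[9:11, 8, 6, 1])), 0.15)
})

test_that("Bland-Altman recovers exact and constant-offset differences", {
  a <- make_smooth_field()
  expect_identical(bland_altman(a, a)$bias, 0)
  expect_identical(bland_altman(a, a)$loa_half_width, 0)
  b <- a; b$u <- b$u + 0.17
  ba <- bland_altman(a, b, mode = "x")
  expect_equal(ba$bias, 0.17, tolerance = 1e-12)
  expect_equal(ba$loa_half_width, 0, tolerance = 1e-9)
  # down-sample then compare a field against itself: exact zeros
  ds <- downsample_field(a, c(9, 7, 5))
  ba2 <- bland_altman(ds, ds)
  expect_identical(c(ba2$bias, ba2$loa_half_width), c(0, 0))
  bad <- make_smooth_field(c(10, 16, 12))
  expect_error(bland_altman(a, bad), "identical grids")
})

test_that("Monte-Carlo difference construction reproduces bias and limits", {
  # emulate the first validation case: differences N(-0.05, 0.098) m/s
  set.seed(42)
  dims <- c(30, 25, 20)
  base <- make_smooth_field(dims)
  base$u <- abs(base$u) + 1          # positive magnitudes, keep masks simple
  d <- array(rnorm(prod(dims), -0.05, 0.098), dims)
  other <- base
  # add the difference along the magnitude direction: scale each vector
  mg <- field_magnitude(base)
  scale <- (mg + d) / mg
  for (k in 1:3) other$u[, , , k] <- base$u[, , , k] * array(scale, dims)
  ba <- bland_altman(base, other)
  expect_lt(abs(ba$bias - (-0.05)), 0.005)
  expect_lt(abs(ba$loa_half_width - 1.96 * 0.098), 0.01)
  expect_equal(ba$n_voxels, prod(dims))
})

test_that("correlation is exact for affine relations and matches textbook form", {
  a <- make_smooth_field()
  b <- a; b$u <- 2 * a$u + 1
  fc <- field_correlation(a, b, mode = "x")
  expect_equal(fc$pearson_r, 1, tolerance = 1e-12)
  neg <- a; neg$u <- -a$u
  expect_equal(field_correlation(a, neg, mode = "x")$pearson_r, -1,
               tolerance = 1e-12)
  # affine invariance on magnitude mode
  c1 <- field_correlation(a, b)
  b2 <- b; b2$u <- b$u * 3
  expect_equal(field_correlation(a, b2)$pearson_r, c1$pearson_r,
               tolerance = 1e-10)
  # textbook-formula oracle on the paired x-components
  va <- as.vector(a$u[, , , 1]); vb <- as.vector(b$u[, , , 1]) + rnorm(length(va), 0, 0.1)
  bb <- a; bb$u[, , , 1] <- array(vb, a$dims)
  r_oracle <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  fc2 <- field_correlation(a, bb, mode = "x")
  expect_equal(fc2$pearson_r, r_oracle, tolerance = 1e-12)
  expect_equal(fc2$r_squared, fc2$pearson_r^2, tolerance = 1e-14)
  flat <- a; flat$u[] <- 1
  expect_error(field_correlation(a, flat, mode = "x"), "variance")
})

test_that("VTK structured-points round trip preserves fields and masks", {
  vf <- make_smooth_field(c(8, 7, 6))
  vf$mask[2, 2, 2] <- FALSE
  tf <- tempfile(fileext = ".vtk")
  write_field_vtk(vf, tf)
  rd <- read_field_vtk(tf)
  expect_equal(rd$dims, vf$dims)
  expect_equal(rd$mask, vf$mask)
  m <- array(vf$mask, dim(vf$u))
  expect_equal(rd$u[m], vf$u[m], tolerance = 1e-12)
})
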