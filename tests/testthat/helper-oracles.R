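# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths.

# trapezoidal quadrature
trapz_oracle <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# analytic oscillatory (Womersley-type) channel profile for body force
# g0 * cos(om * t): complex series solution
womersley_profile <- function(y, h, t, g0, om, nu) {
  lam <- sqrt(1i * om / nu)
  Re((g0 / (1i * om)) * (1 - cosh(lam * y) / cosh(lam * h)) * exp(1i * om * t))
}

# plain (halfway) bounce-back streaming written as an explicit loop over
# cells; reference for the q = 1/2 Bouzidi identity
plain_bounceback_stream <- function(fpost, grid, desc) {
  dims <- grid$dims
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))
  lin <- function(co) {
    idx <- co[, 1]; mult <- 1
    for (d in seq_along(dims)[-1]) {
      mult <- mult * dims[d - 1]
      idx <- idx + (co[, d] - 1) * mult
    }
    idx
  }
  fluid <- as.vector(grid$flags) > 0L
  f <- fpost
  for (a in seq_len(desc$q)) {
    co <- coords
    for (d in seq_len(grid$dim))
      co[, d] <- ((coords[, d] - 1 - desc$cx[a, d]) %% dims[d]) + 1
    src <- lin(co)
    f[, a] <- fpost[src, a]
  }
  # repair: populations that streamed out of solid cells
  for (a in seq_len(desc$q)) {
    if (all(desc$cx[a, ] == 0)) next
    co <- coords
    for (d in seq_len(grid$dim))
      co[, d] <- ((coords[, d] - 1 + desc$cx[a, d]) %% dims[d]) + 1
    nb <- lin(co)
    hit <- which(fluid & !fluid[nb])
    f[hit, desc$opp[a]] <- fpost[hit, a]
  }
  f
}

# build a patient record whose measured targets come from simulating a known
# parameter set (used by calibration-recovery tests)
make_truth_record <- function(seed = 5, truth = c(q_mpv = 330, r_sa = 0.95,
                                                  c_sac = 2.4, c_ao = 0.6,
                                                  r_ub = 0.45)) {
  rec <- generate_synthetic_patient(seed, "moderate", "pre")
  p <- circuit_params_from_record(rec)
  p$q_mpv <- truth[["q_mpv"]]; p$r_sa <- truth[["r_sa"]]
  p$c_sac <- truth[["c_sac"]]; p$c_ao <- truth[["c_ao"]]
  p$r_ub <- truth[["r_ub"]]
  sim <- simulate_circuit(p, 200, steady_tol = 2e-5)
  s <- sim$cycle_summary[sim$cycles_run, ]
  sv <- trapz_oracle(sim$waves$time, sim$waves$q_av)
  br <- trapz_oracle(sim$waves$time, sim$waves$q_ub)
  d <- rec$doppler
  rec2 <- patient_record(
    doppler_measurements(d$heart_rate, d$ejection_time, d$a_lvot,
                         sv / d$a_lvot, d$a_ao, d$a_dao, d$vti_dao,
                         d$eoa_av, d$eoa_mv, d$eoa_coa, d$a_downstream_coa,
                         edv = d$edv, esv = d$esv),
    pressure_measurements(s$sbp, s$dbp), state = "pre")
  list(record = rec2, truth = truth, branch_frac = br / sv, sim = sim)
}
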