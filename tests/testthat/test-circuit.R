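rec_pre <- generate_synthetic_patient(7, "moderate", "pre")
par_pre <- circuit_params_from_record(rec_pre)

test_that("the circuit is at rest when pressures equal venous pressure", {
  p <- par_pre
  y <- c(v_lv = p$lv$v0, v_la = p$la$v0, p_ao = p$p_cv0, p_sa = p$p_cv0,
         q_av = 0, q_mv = 0, q_coa = 0, q_ar = 0, q_mr = 0)
  t_dia <- p$t_ee + 0.6 * (p$T - p$t_ee)   # pulmonary inflow is zero here
  dy <- assemble_derivatives(y, t_dia, p,
                             act = c(av = FALSE, mv = FALSE, ar = FALSE, mr = FALSE))
  expect_equal(as.vector(dy), rep(0, 9), tolerance = 1e-12)
})

test_that("compliance-node derivatives satisfy C dP/dt = sum of flows", {
  p <- par_pre
  set.seed(2)
  for (k in 1:5) {
    y <- c(runif(1, 50, 200), runif(1, 20, 90), runif(1, 60, 140),
           runif(1, 60, 140), runif(1, 0, 300), 0, runif(1, 0, 200), 0, 0)
    dy <- assemble_derivatives(y, runif(1, 0, p$T), p)
    aux <- attr(dy, "aux")
    expect_equal(p$c_ao * dy[3], y[5] - 0 - (y[3] - aux[["p_apost"]]) / p$r_ao,
                 tolerance = 1e-10)
    expect_equal(p$c_sac * dy[4],
                 aux[["q_ub"]] + y[7] + aux[["q_graft"]] -
                   (y[4] - p$p_cv0) / (p$r_sa + p$r_sv),
                 tolerance = 1e-10)
  }
  expect_error(assemble_derivatives(c(NaN, rep(1, 8)), 0, p), "non-finite")
})

test_that("compiled and pure-R integrators agree", {
  simc <- simulate_circuit(par_pre, n_cycles = 2, steady_tol = 0)
  simr <- simulate_circuit(par_pre, n_cycles = 2, steady_tol = 0, engine = "r")
  sc <- unlist(simc$cycle_summary[2, ])
  sr <- unlist(simr$cycle_summary[2, ])
  expect_equal(sc, sr, tolerance = 1e-4)
})

sim_pre <- simulate_circuit(par_pre, n_cycles = 150)

test_that("the model reaches a periodic steady state within 150 cycles", {
  expect_true(sim_pre$converged)
  expect_lte(sim_pre$cycles_run, 150)
  s <- sim_pre$cycle_summary
  n <- nrow(s)
  drift <- abs(unlist(s[n, ]) - unlist(s[n - 1, ])) / unlist(s[n - 1, ])
  expect_true(all(drift < 1e-3))
  # periodicity of the full state across the last recorded cycle
  w <- sim_pre$waves
  first <- unlist(w[1, c("v_lv", "v_la", "p_ao", "p_sa")])
  last <- unlist(w[nrow(w), c("v_lv", "v_la", "p_ao", "p_sa")])
  expect_equal(first, last, tolerance = 1e-3)
})

test_that("steady-cycle volume is conserved through every branch", {
  w <- sim_pre$waves
  sv_av <- trapz_oracle(w$time, w$q_av)
  sv_out <- trapz_oracle(w$time, w$q_ub + w$q_coa + w$q_graft)
  expect_equal(sv_av, sv_out, tolerance = 5e-3)
  # inflow equals outflow through the systemic vein path
  sv_pv <- trapz_oracle(w$time, w$q_pv)
  sv_sys <- trapz_oracle(w$time, (w$p_sa - par_pre$p_cv0) /
                           (par_pre$r_sa + par_pre$r_sv))
  expect_equal(sv_pv, sv_sys, tolerance = 1e-2 * sv_pv)
  # forward conduit flows never negative; no regurgitant elements here
  expect_true(all(w$q_av >= 0) && all(w$q_mv >= 0))
  expect_true(all(w$q_ar == 0) && all(w$q_mr == 0))
})

test_that("a stenosis-free patient has a sub-mmHg trans-COA gradient", {
  rec0 <- generate_synthetic_patient(3, "none", "pre")
  sim0 <- simulate_circuit(circuit_params_from_record(rec0), n_cycles = 150)
  hs <- hemodynamic_summary(sim0)
  expect_lt(hs$peak_coa_gradient, 1)
})

test_that("removing the graft reproduces the pre-intervention model bit-for-bit", {
  post <- generate_synthetic_patient(11, "severe", "post")
  p_post <- circuit_params_from_record(post)
  p_off <- p_post
  p_off$graft_present <- FALSE
  p_off$r_graft <- NA_real_
  # identical parameters with the graft absent = the pre-intervention circuit
  pre_equiv <- patient_record(post$doppler, post$pressures, state = "pre")
  p_pre <- circuit_params_from_record(pre_equiv)
  s1 <- simulate_circuit(p_off, n_cycles = 5, steady_tol = 0)
  s2 <- simulate_circuit(p_pre, n_cycles = 5, steady_tol = 0)
  expect_identical(s1$waves[names(s1$waves) != "cycle"],
                   s2$waves[names(s2$waves) != "cycle"])
})

test_that("peak trans-COA gradient is non-increasing in the orifice area", {
  rec <- generate_synthetic_patient(13, "moderate", "pre")
  d <- rec$doppler
  ratios <- c(0.25, 0.4, 0.6, 0.9)
  peaks <- vapply(ratios, function(r) {
    d2 <- d; d2$eoa_coa <- r * d$a_downstream_coa
    rec2 <- rec; rec2$doppler <- d2
    hemodynamic_summary(
      simulate_circuit(circuit_params_from_record(rec2), 150))$peak_coa_gradient
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
  # the moderate-to-severe range spans a clinically meaningful gradient
  expect_gt(peaks[1], 2)
})
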