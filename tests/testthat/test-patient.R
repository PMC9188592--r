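test_that("Doppler stroke-volume products match hand arithmetic", {
  expect_equal(forward_lvot_sv_from_doppler(4.0, 20), 80)
  expect_equal(forward_lvot_sv_from_doppler(3.7, 0), 0)
  expect_equal(forward_lvot_sv_from_doppler(3.2, 21.3), 3.2 * 21.3)  # 68.16
  expect_equal(descending_sv_from_doppler(2.5, 24), 60)
  expect_equal(descending_sv_from_doppler(2.41, 24.99), 2.41 * 24.99)  # 60.23
  expect_error(forward_lvot_sv_from_doppler(0, 10), "invalid measurement")
  expect_error(forward_lvot_sv_from_doppler(-1, 10), "invalid measurement")
  expect_error(descending_sv_from_doppler(2.5, -3), "invalid measurement")
})

test_that("graft resistance follows the Poiseuille scaling laws", {
  g1 <- graft_geometry(8.0, 1.5)
  expect_equal(graft_resistance(graft_geometry(8.0, 3.0)),
               graft_resistance(g1) / 16)
  expect_equal(graft_resistance(graft_geometry(16.0, 1.5)),
               graft_resistance(g1) * 2)
  # independent unit-conversion oracle for the first published graft
  # (L = 8.1 cm, D = 1.6 cm, mu = 0.0035 Pa.s), all in SI then converted
  r_si <- 128 * 0.0035 * 0.081 / (pi * 0.016^4)   # Pa.s/m3
  r_clin <- r_si / 133.322 / 1e6                   # mmHg.s/mL
  expect_equal(graft_resistance(graft_geometry(8.1, 1.6)), r_clin,
               tolerance = 1e-12)
  expect_error(graft_resistance(g1, viscosity = 0), "viscosity")
})

test_that("synthetic patients are deterministic and respect the envelope", {
  a <- generate_synthetic_patient(42, "moderate", "pre")
  b <- generate_synthetic_patient(42, "moderate", "pre")
  a$id <- b$id
  expect_identical(a, b)
  none <- generate_synthetic_patient(3, "none", "pre")
  expect_equal(none$doppler$eoa_coa, none$doppler$a_downstream_coa)
  post <- generate_synthetic_patient(9, "severe", "post")
  expect_s3_class(post$graft, "graft_geometry")
  expect_error(patient_record(post$doppler, post$pressures, "post"),
               "graft")
})

test_that("every generated record satisfies all measurement invariants", {
  sev <- c("none", "mild", "moderate", "severe")
  for (seed in seq_len(1000)) {
    rec <- generate_synthetic_patient(seed, sev[1 + seed %% 4],
                                      if (seed %% 2) "pre" else "post")
    d <- rec$doppler
    expect_silent(validate_doppler(d))
    expect_true(d$forward_lvot_sv >= 55 && d$forward_lvot_sv <= 90)
    expect_true(rec$pressures$sbp >= 120 && rec$pressures$sbp <= 160)
    expect_true(rec$pressures$dbp >= 50 && rec$pressures$dbp <= 80)
    # descending flow can never exceed the forward stroke volume
    expect_lte(descending_sv_from_doppler(d$a_dao, d$vti_dao),
               d$forward_lvot_sv)
  }
})

test_that("patient YAML round trip preserves every scalar", {
  rec <- generate_synthetic_patient(17, "severe", "post")
  tf <- tempfile(fileext = ".yaml")
  write_patient_yaml(rec, tf)
  back <- read_patient_yaml(tf)
  expect_equal(back$doppler[names(back$doppler)],
               rec$doppler[names(rec$doppler)], tolerance = 1e-12)
  expect_equal(back$pressures$sbp, rec$pressures$sbp)
  expect_equal(back$graft$length, rec$graft$length)
  expect_equal(back$state, "post")
})

test_that("measurement invariants reject inconsistent records", {
  expect_error(doppler_measurements(70, 0.33, 3.5, 20, a_ao = 7, a_dao = 4,
                                    vti_dao = 12, eoa_av = 8, eoa_mv = 4,
                                    eoa_coa = 1, a_downstream_coa = 3),
               "eoa_av")
  expect_error(doppler_measurements(70, 0.33, 3.5, 20, a_ao = 7, a_dao = 4,
                                    vti_dao = 12, eoa_av = 2, eoa_mv = 4,
                                    eoa_coa = 4, a_downstream_coa = 3),
               "eoa_coa")
  expect_error(doppler_measurements(70, 0.33, 3.5, 20, a_ao = 7, a_dao = 4,
                                    vti_dao = 12, eoa_av = 2, eoa_mv = 4,
                                    eoa_coa = 1, a_downstream_coa = 3,
                                    cycle_duration_T = 1.2),
               "cycle_duration_T")
  expect_error(pressure_measurements(80, 90), "sbp > dbp")
})
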