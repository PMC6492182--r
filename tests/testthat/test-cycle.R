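test_that("the arterial compartment decays and saturates as an RC circuit", {
  wk <- windkessel_params(35.82, 26.00, 187.74, 15.23)
  tau <- wk$R_art * wk$C_art
  expect_equal(tau, 2859.2802, tolerance = 1e-6)
  # zero flow: exponential decay with time constant R C
  p <- 10; dt <- 1
  for (k in 1:500) p <- windkessel_step(p, 0, dt, wk)$p_c
  expect_equal(p, 10 * exp(-500 / tau), tolerance = 1e-3)
  # constant flow forever: fixed point q R
  p <- 0
  for (k in 1:20000) p <- windkessel_step(p, 0.05, 5, wk)$p_c
  expect_equal(p, 0.05 * wk$R_art, tolerance = 1e-3)
  # p_ao adds the characteristic-impedance drop
  st <- windkessel_step(10, 0.2, 1, wk)
  expect_equal(st$p_ao - st$p_c, wk$Z_a * 0.2)
})

test_that("derived record fields reproduce the tabulated arithmetic", {
  a <- derive_record_fields(112.0, 46.0, 53, 74, 126)
  expect_equal(a$SV, 66.00)
  expect_equal(round(a$EF, 2), 58.93)
  expect_equal(round(a$MAP, 2), 91.33)
  expect_equal(a$CO, 66 * 53)
  d <- derive_record_fields(172.0, 103.0, 68, 79, 144)
  expect_equal(round(d$EF, 2), 40.12)
  expect_equal(round(d$MAP, 2), 100.67)
  expect_equal(derive_record_fields(100, 50, 60, 70, 100)$EF, 50)
  expect_error(derive_record_fields(-1, 0, 60, 70, 100), "EDV")
  expect_error(derive_record_fields(100, 100, 60, 70, 100), "EDV > ESV")
})

# one shared patient-A-like cycle for the trace-level properties
cfgA <- cycle_config(
  geometry = sphere_geometry(24, 39.6),
  passive = material_demiray(1.5, 3),
  active = active_params(42, 80, 30, 300),
  wk = windkessel_params(35.82, 26.00, 187.74, 15.23),
  edp = 1.5, period = 60000 / 53, p_ao0 = mmHg_to_kPa(74))
trA <- simulate_cycle(cfgA)

test_that("a passive cycle does not eject", {
  cfg0 <- cycle_config(
    geometry = sphere_geometry(24, 39.6),
    passive = material_demiray(1.5, 3),
    active = active_params(0, 80, 30, 300),
    wk = windkessel_params(35.82, 26.00, 187.74, 15.23),
    edp = 1.5, period = 400)
  tr0 <- simulate_cycle(cfg0)
  expect_equal(simulated_ef(tr0), 0, tolerance = 1e-9)
  expect_true(all(tr0$p_lv_kPa <= cfg0$edp + 1e-9))
  expect_true(all(tr0$phase == "IVC"))
})

test_that("the simulated trace satisfies the valve and wall invariants", {
  iv <- trA$phase %in% c("IVC", "IVR")
  for (ph in c("IVC", "IVR")) {
    V <- trA$V_cav_ml[trA$phase == ph]
    expect_lt(diff(range(V)) / mean(V), 1e-6)
  }
  ej <- trA$phase == "ejection"
  expect_true(any(ej))
  expect_true(all(trA$q_ml_per_ms[ej] >= 0))
  expect_true(all(trA$q_ml_per_ms[!ej] == 0))
  # transvalvular gradient: delta p = Z_v q during ejection
  dp <- trA$p_lv_kPa[ej] - trA$p_ao_kPa[ej]
  expect_equal(dp, 35.82 * trA$q_ml_per_ms[ej], tolerance = 1e-8)
  # peak gradient at peak flow
  expect_equal(which.max(dp), which.max(trA$q_ml_per_ms[ej]))
  # wall volume is exactly conserved
  Vmyo <- 4 * pi / 3 * (trA$R_mm^3 - trA$r_mm^3) / 1000
  expect_lt(diff(range(Vmyo)) / mean(Vmyo), 1e-9)
  # the cycle closes at the end-diastolic state
  expect_equal(trA$V_cav_ml[nrow(trA)], trA$V_cav_ml[1], tolerance = 1e-6)
  expect_equal(trA$p_lv_kPa[nrow(trA)], cfgA$edp, tolerance = 1e-8)
})

test_that("peak pressure falls inside ejection, after its onset", {
  ev <- attr(trA, "events")
  expect_gt(ev[["t_phat"]], ev[["t_0ej"]])
  expect_lte(ev[["t_phat"]], ev[["t_ES"]])
})

test_that("traces are reproducible and noise injection is seed-controlled", {
  tr2 <- simulate_cycle(cfgA)
  expect_identical(trA$p_lv_kPa, tr2$p_lv_kPa)
  expect_identical(trA$r_mm, tr2$r_mm)
  cfg_n <- cfgA; cfg_n$noise_sd <- 0.1
  n1 <- simulate_cycle(cfg_n)
  n2 <- simulate_cycle(cfg_n)
  expect_identical(n1$r_mm, n2$r_mm)
  expect_false(identical(n1$r_mm, trA$r_mm))
  cfg_n2 <- cfg_n; cfg_n2$seed <- 2L
  expect_false(identical(simulate_cycle(cfg_n2)$r_mm, n1$r_mm))
})

test_that("internal and external power balance over ejection", {
  tru <- truth_series(trA)
  ej <- trA$phase == "ejection"
  W_int <- pracma::trapz(trA$t_ms[ej], tru$P_int_W[ej]) * 1e-3
  W_ext <- pracma::trapz(trA$t_ms[ej], tru$P_ext_W[ej]) * 1e-3
  expect_equal(W_int / W_ext, 1, tolerance = 0.01)
  # no deformation during isovolumetric phases: internal power marginal
  iv <- trA$phase %in% c("IVC", "IVR")
  expect_lt(max(abs(tru$P_int_W[iv])), 0.02 * max(abs(tru$P_int_W)))
  expect_true(all(tru$P_ext_W[iv] == 0))
})

test_that("patient mapping unloads the reference to the measured EDV", {
  rec <- patient_records()[1, ]
  wk <- patient_a_windkessel()
  cfg <- config_from_patient(rec, wk)
  r_ed <- (3 * rec$EDV * 1000 / (4 * pi))^(1 / 3)
  ed <- inflate(cfg$geometry, cfg$passive, cfg$edp, n_profile = 3)
  expect_equal(ed$r, r_ed, tolerance = 1e-6)
  expect_equal(cavity_volume(ed), rec$EDV, tolerance = 1e-4)
  # wall volume equals the measured-thickness shell at ED
  h_ed <- mean(c(rec$h_septum, rec$h_lateral))
  expect_equal(cfg$geometry$R0^3 - cfg$geometry$r0^3,
               (r_ed + h_ed)^3 - r_ed^3, tolerance = 1e-6)
  # the fitted EF honors the bisection contract
  expect_lt(abs(attr(cfg, "EF_achieved") - rec$EF), 0.5)
  # a record without ejection yields a quiescent configuration
  rec0 <- rec; rec0$ESV <- rec0$EDV; rec0$SV <- 0; rec0$EF <- 0
  cfg0 <- config_from_patient(rec0, wk)
  expect_equal(attr(cfg0, "S_peak"), 0)
})

test_that("emitted surfaces preserve cavity and wall volume", {
  for (shape in c("sphere", "prolate")) {
    pair <- emit_surfaces(24, 39, shape = shape, subdiv = 4)
    vc <- mesh_volume(pair$endo)
    vm <- mesh_volume(pair$epi) - vc
    expect_equal(vc, 4 * pi / 3 * 24^3 / 1000, tolerance = 0.01)
    expect_equal(vm, 4 * pi / 3 * (39^3 - 24^3) / 1000, tolerance = 0.01)
  }
  # the prolate mapping really is nonspherical
  pp <- emit_surfaces(24, 39, "prolate")
  ext <- apply(pp$endo$vertices, 2, function(x) diff(range(x)))
  expect_gt(ext[3] / ext[1], 1.5)
})
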