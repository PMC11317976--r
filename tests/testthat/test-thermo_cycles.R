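spec <- acetonitrile_spec()

test_that("standard-state helpers come out of R and T, not constants", {
  expect_equal(round(atm_to_molar_correction(298.15), 2), 1.89)
  expect_equal(round(pka_term(1, 298.15), 3), 1.364)
  # RT = 1 atm L/mol at ~12.19 K: the correction crosses zero there
  T0 <- 1 / ccsa_constants$R_Latm
  expect_equal(atm_to_molar_correction(T0), 0, tolerance = 1e-12)
  # closed-form oracle at doubled temperature (frozen value)
  expect_equal(atm_to_molar_correction(596.3), 4.6100154361,
               tolerance = 1e-9)
  expect_equal(pka_term(0), 0)
  expect_equal(pka_term(20.7, 298.15), 28.2399131698, tolerance = 1e-9)
  expect_error(atm_to_molar_correction(-1), "T must be")
})

test_that("neat-solvent concentration term matches the published constant", {
  expect_equal(neat_solvent_conc_term(1), 0)
  # acetonitrile molarity from density 0.786 g/mL over 41.05 g/mol
  expect_equal(round(neat_solvent_conc_term(19.14, 298.15), 2), 1.75)
  # log additivity
  expect_equal(neat_solvent_conc_term(2 * 19.14) -
                 neat_solvent_conc_term(19.14),
               ccsa_constants$R_kcal * 298.15 * log(2), tolerance = 1e-12)
  expect_error(neat_solvent_conc_term(0), "concentration")
})

test_that("anion cycle: term-by-term oracle and pKa round trip", {
  # pKa = 0, gas acidity tuned so only the standard-state terms survive
  input <- thermo_cycle_input(pKa = 0, dG_gas_dissoc = 253.2 + 1.89,
                              dG_solv_neutral = 0)
  oracle <- 0 + 0 - (253.2 + 1.89) - atm_to_molar_correction(298.15) + 253.2
  expect_equal(anion_solvation_from_cycle(input, spec), oracle)

  # realistic magnitudes (A-anion scale); inverse recovers pKa to 1e-10
  set.seed(11)
  for (i in 1:25) {
    inp <- thermo_cycle_input(pKa = runif(1, 0, 35),
                              dG_gas_dissoc = runif(1, 300, 360),
                              dG_solv_neutral = runif(1, -15, -2))
    dG <- anion_solvation_from_cycle(inp, spec)
    expect_equal(cycle_implied_pka(dG, inp, spec, "anion"), inp$pKa,
                 tolerance = 1e-10)
  }
  # gas acidity 333.1 (the corrected A11 value) is evaluable
  a11 <- thermo_cycle_input(pKa = 20.0, dG_gas_dissoc = 333.1,
                            dG_solv_neutral = -8.0,
                            note = "acidity recomputed; database value in error")
  expect_true(is.finite(anion_solvation_from_cycle(a11, spec)))
  expect_match(a11$note, "error")
})

test_that("cation cycle: anchor passthrough and pKa round trip", {
  # all terms zero except the anchor (T where the 1atm->1M term vanishes)
  T0 <- 1 / ccsa_constants$R_Latm
  sp0 <- solvent_spec("toy", temperature = T0, probe_radius = 1,
                      alpha_A = -0.005, gamma_N = 1, W_R = -2, eta = 1.5,
                      E_R = -12, rt_ln_conc = 0,
                      proton_solvation_anchor = -253.2)
  inp0 <- thermo_cycle_input(0, 0, 0, temperature = T0)
  expect_equal(cation_solvation_from_cycle(inp0, sp0), -253.2,
               tolerance = 1e-10)

  set.seed(12)
  for (i in 1:25) {
    inp <- thermo_cycle_input(pKa = runif(1, -5, 25),
                              dG_gas_dissoc = runif(1, 180, 260),
                              dG_solv_neutral = runif(1, -12, -1))
    dG <- cation_solvation_from_cycle(inp, spec)
    expect_equal(cycle_implied_pka(dG, inp, spec, "cation"), inp$pKa,
                 tolerance = 1e-10)
  }
})

test_that("sign-convention audit: solution dissociation closes the loop", {
  # Reassembling the solution-phase dissociation free energy from the cycle
  # output must reproduce RT ln(10) pKa exactly, for both ion kinds.
  inp <- thermo_cycle_input(pKa = 14.2, dG_gas_dissoc = 330.0,
                            dG_solv_neutral = -6.5)
  dG_an <- anion_solvation_from_cycle(inp, spec)
  lhs_an <- (inp$dG_gas_dissoc + atm_to_molar_correction(298.15)) +
    dG_an + spec$proton_solvation_anchor - inp$dG_solv_neutral
  expect_equal(lhs_an, pka_term(inp$pKa), tolerance = 1e-10)

  inp2 <- thermo_cycle_input(pKa = 8.7, dG_gas_dissoc = 225.0,
                             dG_solv_neutral = -4.0)
  dG_cat <- cation_solvation_from_cycle(inp2, spec)
  lhs_cat <- (inp2$dG_gas_dissoc + atm_to_molar_correction(298.15)) +
    inp2$dG_solv_neutral + spec$proton_solvation_anchor - dG_cat
  expect_equal(lhs_cat, pka_term(inp2$pKa), tolerance = 1e-10)
})

test_that("protonated-solvent cycle reproduces the worked reference value", {
  got <- protonated_solvent_solvation(179, -4.19, spec)
  expect_equal(got, -74.8, tolerance = 0.1 / 74.8)
  # all-zero inputs at 298.15 K: only the standard-state term survives
  sp0 <- solvent_spec("toy", probe_radius = 1, alpha_A = -0.005, gamma_N = 1,
                      W_R = -2, eta = 1.5, E_R = -12, rt_ln_conc = 0,
                      proton_solvation_anchor = 0)
  expect_equal(round(protonated_solvent_solvation(0, 0, sp0), 2), 1.89)
  # linearity in the anchor
  sp1 <- spec; sp1$proton_solvation_anchor <- spec$proton_solvation_anchor + 1
  expect_equal(protonated_solvent_solvation(179, -4.19, sp1) - got, 1,
               tolerance = 1e-12)
})

test_that("cation cycle specializes to the protonated-solvent cycle", {
  # With B = solvent, replacing the pKa term by -RT ln[S] must give the same
  # number through either expression.
  dG_gas <- 179
  via_eq10 <- protonated_solvent_solvation(dG_gas, spec$dG_solv_solvent, spec)
  pka_equiv <- -spec$rt_ln_conc / pka_term(1, spec$temperature)
  inp <- thermo_cycle_input(pKa = pka_equiv, dG_gas_dissoc = dG_gas,
                            dG_solv_neutral = spec$dG_solv_solvent)
  via_eq9 <- cation_solvation_from_cycle(inp, spec)
  expect_lt(abs(via_eq9 - via_eq10), 0.01)
})
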