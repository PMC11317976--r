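spec <- acetonitrile_spec()

test_that("damping_factor reproduces the published anchors", {
  # saturated, partially damped, and strongly damped cases
  expect_equal(round(damping_factor(-14.35, -34.53, spec)$f_d, 2), 1.00)
  expect_equal(round(damping_factor(-4.42, -22.54, spec)$f_d, 2), 0.97)
  expect_equal(round(damping_factor(-1.63, -15.24, spec)$f_d, 2), 0.36)
  # weak-interaction limit: both switches essentially closed
  expect_lt(damping_factor(0, 0, spec)$f_d, 1e-8)
})

test_that("damping factor bounds, factorization and limits hold", {
  set.seed(7)
  dW <- runif(300, -30, 5)
  dE <- runif(300, -50, 5)
  fd <- damping_factor(dW, dE, spec)
  expect_true(all(fd$f1 >= 0 & fd$f1 <= 1))
  expect_true(all(fd$f2 >= 0 & fd$f2 <= 1))
  expect_true(all(abs(fd$f_d - fd$f1 * fd$f2) < 1e-12))
  # limits
  expect_equal(damping_factor(-1e4, -50, spec)$f1, 1)
  expect_lt(damping_factor(-1e-9, -50, spec)$f1, 0.05)
  # f2 saturates once dE is well below E_R
  expect_gt(damping_factor(-10, -15.5, spec)$f2, 0.99)
})

test_that("f_d is monotone non-increasing in each argument", {
  dW_grid <- seq(-25, 0, length.out = 120)
  for (dE in c(-40, -18, -12, -9)) {
    fd <- damping_factor(dW_grid, dE, spec)$f_d
    expect_true(all(diff(fd) <= 1e-12))
  }
  dE_grid <- seq(-45, -5, length.out = 120)
  for (dW in c(-20, -5, -1.5)) {
    fd <- damping_factor(dW, dE_grid, spec)$f_d
    expect_true(all(diff(fd) <= 1e-12))
  }
})

test_that("ccsa_solvation reproduces Table 1 rows from components", {
  cases <- list(
    list(id = "BH1", dG_cont = -60.09, dW = -14.35, dE = -34.53,
         want = -73.44),
    list(id = "BH10", dG_cont = -51.59, dW = -1.63, dE = -15.24,
         want = -51.82),
    list(id = "BH18", dG_cont = -60.87, dW = -20.66, dE = -38.20,
         want = -80.53)
  )
  for (cs in cases) {
    rec <- species_record(cs$id, 1L, dG_cont = cs$dG_cont, dW = cs$dW,
                          dE = cs$dE)
    res <- ccsa_solvation(rec, spec)
    expect_equal(res$dG_ccsa, cs$want, tolerance = 0.01 / abs(cs$want))
    expect_equal(res$dG_ccsa, res$dG_cont + res$correction,
                 tolerance = 1e-9)
  }
})

test_that("full 22-cation equivalence with computed f_d", {
  tab1 <- builtin_fixture("table1")
  res <- ccsa_solvation_table(tab1, spec)
  expect_true(all(abs(res$f_d - tab1$f_d_printed) <= 0.005))
  expect_true(all(abs(res$dG_ccsa - tab1$dG_ccsa_printed) <= 0.05))
})

test_that("continuum fallbacks and the repulsive-PMF guard", {
  # dW absent -> pure continuum, flagged
  rec <- species_record("noW", 0L, dG_cont = -12.3)
  res <- ccsa_solvation(rec, spec)
  expect_equal(res$dG_ccsa, -12.3)
  expect_equal(res$correction, 0)
  expect_true(res$reduced_to_continuum)

  # weak/positive PMF (fluoride-like): correction exactly zero even though
  # gamma_N alone would push dG upward
  f_like <- species_record("A1", -1L, dG_cont = -55.0, dW = 0.4, dE = -13.0)
  res_f <- ccsa_solvation(f_like, spec)
  expect_identical(res_f$correction, 0)
  expect_equal(res_f$dG_ccsa, -55.0)

  # continuum limit: correction vanishes smoothly as dW -> 0-
  for (dW in c(-0.5, -0.1, -0.01)) {
    r <- ccsa_solvation(species_record("x", 0L, dG_cont = -10, dW = dW,
                                       dE = -30), spec)
    expect_lt(abs(r$dG_ccsa - r$dG_cont), abs(dW) + spec$gamma_N)
  }
  r_small <- ccsa_solvation(species_record("x", 0L, dG_cont = -10,
                                           dW = -1e-6, dE = -30), spec)
  expect_lt(abs(r_small$dG_ccsa - r_small$dG_cont), 0.05)
})

# Thin re-derivation of the CCQC candidate sum, independent of the package's
# internal helper.
ccqc_candidate_for_test <- function(ccqc, dG_solv_S, spec) {
  ccqc$dG_gas_complexation + ccqc$dG_solv_AS - dG_solv_S - spec$rt_ln_conc
}

test_that("ccqc_solvation applies the stated sum and selection rule", {
  # all-zero components: only -RT ln[S] survives
  z <- list(dG_gas_complexation = 0, dG_solv_AS = 0)
  expect_equal(ccqc_solvation(z, 0, spec, dG_cont_A = 10), -1.75)
  # selection rule keeps the more negative continuum value
  c50 <- list(dG_gas_complexation = 0, dG_solv_AS = -48.25)
  expect_equal(ccqc_candidate_for_test(c50, 0, spec), -50)
  expect_equal(ccqc_solvation(c50, 0, spec, dG_cont_A = -60), -60)
  # hand-evaluated sum: -5 + (-40) - (-4.19) - 1.75 = -42.56
  h <- list(dG_gas_complexation = -5, dG_solv_AS = -40)
  expect_equal(ccqc_solvation(h, -4.19, spec, dG_cont_A = -30), -42.56)
})

test_that("ccqc_gamma_equivalent is the exact offset to the undamped CCSA", {
  # identity: candidate equal to dG_cont + dW
  ccqc <- list(dG_gas_complexation = -3, dG_solv_AS = -40)
  cand <- ccqc_candidate_for_test(ccqc, -4.19, spec)
  expect_equal(ccqc_gamma_equivalent(ccqc, dW = cand - (-30), -4.19, spec,
                                     dG_cont_A = -30), 0)
  # fixed offset
  expect_equal(ccqc_gamma_equivalent(ccqc, dW = cand - (-30) - 2.5, -4.19,
                                     spec, dG_cont_A = -30), 2.5)
  # fixture-scale inputs, explicit subtraction oracle
  ccqc2 <- list(dG_gas_complexation = -8.4, dG_solv_AS = -62.7)
  dW <- -14.35; dG_cont_A <- -60.09
  oracle <- (-8.4 - 62.7 + 4.19 - 1.75) - (dG_cont_A + dW)
  expect_equal(ccqc_gamma_equivalent(ccqc2, dW, -4.19, spec, dG_cont_A),
               oracle)
})
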