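test_that("dose conversion matches molar-mass arithmetic", {
  expect_identical(dose_amount(0), 0)
  # independent oracle: M(C8H16O4) from atomic masses
  M <- 8 * 12.011 + 16 * 1.008 + 4 * 15.999
  expect_equal(M, 176.212, tolerance = 1e-6)
  expect_equal(dose_amount(192, 70), 192 * 70 / M, tolerance = 1e-6)
  expect_equal(dose_amount(192, 70), 76.27, tolerance = 1e-4)
  expect_equal(dose_amount(573, 70), 227.6, tolerance = 1e-3)
  expect_error(dose_amount(10, molar_mass_g_mol = 0), "positive")
})

test_that("with production disabled an empty system stays identically empty", {
  m0 <- disable_production(model_default)
  m0$states$initial <- rep(0, nrow(m0$states))
  expect_equal(unname(equilibrate(m0)), rep(0, 37))
})

test_that("the baseline is unique across starting points and below 0.5 mM", {
  ns <- nonsink_ids(model_default)
  b2 <- equilibrate(model_default, init = rep(1, 37))
  expect_equal(unname(b2[ns]), unname(baseline_default[ns]),
               tolerance = 1e-6)
  bhb <- state_index(model_default, "blood", "BHB")
  conc <- baseline_default[bhb] / model_default$metadata$blood_volume_L
  expect_gt(unname(conc), 0)
  expect_lt(unname(conc), 0.5)
})

test_that("a zero dose leaves blood BHB flat at baseline", {
  sim <- run_dose(model_default, 0, baseline = baseline_default)
  expect_lt(diff(range(sim$conc)) / sim$conc[1], 1e-6)
})

test_that("halving the solver tolerances moves the AUC by far less than 0.1%", {
  s1 <- run_dose(model_default, 192, baseline = baseline_default,
                 rtol = 1e-8, atol = 1e-10)
  s2 <- run_dose(model_default, 192, baseline = baseline_default,
                 rtol = 5e-9, atol = 5e-11)
  a1 <- auc(s1$time, s1$conc); a2 <- auc(s2$time, s2$conc)
  expect_lt(abs(a1 - a2) / a1, 1e-3)
})

test_that("peak blood BHB increases with dose and no state goes negative", {
  s_lo <- run_dose(model_default, 192, baseline = baseline_default)
  s_hi <- run_dose(model_default, 573, baseline = baseline_default)
  expect_gt(max(s_hi$conc), max(s_lo$conc))
  expect_gt(min(s_lo$amounts), -1e-10)
  expect_gt(min(s_hi$amounts), -1e-10)
})

test_that("dosing later shifts the trajectory without changing its shape", {
  grid <- seq(0, 8, by = 0.01)
  s0 <- run_dose(model_default, 192, baseline = baseline_default,
                 t_grid = seq(0, 6, by = 0.01))
  s2 <- run_dose(model_default, 192, baseline = baseline_default,
                 dose_time = 2, t_grid = grid)
  shifted <- s2$conc[s2$time >= 2 - 1e-12]
  expect_equal(shifted, s0$conc, tolerance = 1e-6)
  # pre-dose segment is flat at baseline
  expect_lt(diff(range(s2$conc[s2$time < 2])) / s2$conc[1], 1e-6)
})

test_that("mole-equivalents are conserved along dosed trajectories with production off", {
  m0 <- disable_production(model_default)
  w <- mole_equivalents(m0)
  for (dose in c(192, 573)) {
    init <- baseline_default
    init[1] <- init[1] + dose_amount(dose)
    sim <- simulate_model(m0, init = init)
    tot <- drop(sim$amounts %*% w)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("the all-first-order variant satisfies dose superposition within 0.5%", {
  lin <- linearize_model(model_default)
  bl <- equilibrate(lin)
  b <- run_dose(lin, 0, baseline = bl)
  s1 <- run_dose(lin, 100, baseline = bl)
  s2 <- run_dose(lin, 200, baseline = bl)
  auc_b <- auc(b$time, b$conc)
  a1 <- auc(s1$time, s1$conc) - auc_b
  a2 <- auc(s2$time, s2$conc) - auc_b
  expect_equal(a2 / a1, 2, tolerance = 0.005)
})

test_that("every saturable flux stays below fraction * vmax along a dosed run", {
  sim <- run_dose(model_default, 573, baseline = baseline_default)
  sat <- Filter(function(p)
    p$kind %in% c("saturable", "saturable_competitive") && p$indicator == 1L,
    model_default$processes)
  for (p in sat[c("apical.mct1.upper_distal", "liver_to_blood.mct1.BHB",
                  "blood_to_tissues.mct1.BHB")]) {
    a <- pmax(sim$amounts[, p$source], 0)
    flux <- if (p$kind == "saturable") saturable_rate(p$vmax, p$km, a)
      else competitive_rate(p$vmax, p$km, a, p$km_comp,
                            pmax(sim$amounts[, p$competitor], 0))
    expect_true(all(p$fraction * flux <= p$fraction * p$vmax))
  }
})

test_that("simulation rejects invalid grids and wrong-length initials", {
  expect_error(simulate_model(model_default, t_grid = c(0, 0, 1)),
               "strictly increasing")
  expect_error(simulate_model(model_default, init = c(1, 2)), "wrong length")
})
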