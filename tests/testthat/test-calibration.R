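# Noise-free datasets for recovery tests are generated once per run.
noise_free_design <- study_design(cv_between = 0, cv_within = 0, sd_add = 0)
noise_free_data <- generate_dataset(noise_free_design, fix_default)

test_that("the ELS objective vanishes at a perfect fit and grows with residuals", {
  prob <- estimation_problem(
    fix_default, noise_free_data,
    free = list("gut.upper_proximal.passive_k.bhb" = c(0.5, 12.5)),
    var_a = 1, var_b = 0, multistart = 1)
  truth <- fixture_value(fix_default, "gut.upper_proximal.passive_k.bhb")
  at_truth <- els_objective(truth, prob)
  expect_lt(abs(at_truth), 1e-8)
  # grid oracle around the truth: every perturbation scores worse
  for (f in c(0.8, 0.9, 1.1, 1.25))
    expect_gt(els_objective(truth * f, prob), at_truth)
  # log-variance penalty: a perfect fit with g != 1 scores sum(log g)
  prob2 <- estimation_problem(
    fix_default, noise_free_data,
    free = list("gut.upper_proximal.passive_k.bhb" = c(0.5, 12.5)),
    var_a = 2, var_b = 0, multistart = 1)
  expect_equal(els_objective(truth, prob2),
               nrow(noise_free_data) * log(4), tolerance = 1e-6)
})

test_that("the objective is invariant to observation ordering", {
  free <- list("gut.upper_proximal.passive_k.bhb" = c(0.5, 12.5))
  truth <- 1.3 * fixture_value(fix_default, "gut.upper_proximal.passive_k.bhb")
  shuffled <- noise_free_data[rev(seq_len(nrow(noise_free_data))), ]
  p1 <- estimation_problem(fix_default, noise_free_data, free, var_a = 0.05,
                           var_b = 0.1, multistart = 1)
  p2 <- estimation_problem(fix_default, shuffled, free, var_a = 0.05,
                           var_b = 0.1, multistart = 1)
  expect_equal(els_objective(truth, p1), els_objective(truth, p2))
})

test_that("a single free parameter is recovered from noise-free data within 1%", {
  truth <- fixture_value(fix_default, "gut.upper_proximal.passive_k.bhb")
  prob <- estimation_problem(
    fix_default, noise_free_data,
    free = list("gut.upper_proximal.passive_k.bhb" = c(truth / 5, truth * 5)),
    start = truth * 2, var_a = 1, var_b = 0, multistart = 1)
  fit <- fit_els(prob)
  expect_lt(abs(fit$estimates - truth) / truth, 0.01)
  expect_equal(fit$convergence, 0)
  # determinism: the same problem refits to the identical estimate
  prob2 <- estimation_problem(
    fix_default, noise_free_data,
    free = list("gut.upper_proximal.passive_k.bhb" = c(truth / 5, truth * 5)),
    start = truth * 2, var_a = 1, var_b = 0, multistart = 1)
  expect_identical(fit_els(prob2)$estimates, fit$estimates)
})

test_that("sensitivities: inert parameters score zero, blood volume has unit elasticity", {
  fix0 <- fixture_set(fix_default, "gut.lower_proximal.smct1.vmax", 0)
  tab <- sensitivity_analysis(
    fix0, c("gut.lower_proximal.smct1.km", "blood_volume_L",
            "gut.upper_proximal.passive_k.bhb"),
    t_grid = seq(0, 6, by = 0.1))
  s <- setNames(tab$rms_sensitivity, tab$parameter)
  expect_identical(unname(s["gut.lower_proximal.smct1.km"]), 0)
  expect_equal(unname(s["blood_volume_L"]), 1, tolerance = 1e-3)
  expect_gt(unname(s["gut.upper_proximal.passive_k.bhb"]), 0)
  # ranking is descending
  expect_true(!is.unsorted(rev(tab$rms_sensitivity)))
})

test_that("halving the finite-difference step barely changes the sensitivities", {
  params <- c("gut.upper_proximal.passive_k.bhb", "liver.endogenous.ic50")
  t1 <- sensitivity_analysis(fix_default, params, rel_step = 0.01,
                             t_grid = seq(0, 6, by = 0.1))
  t2 <- sensitivity_analysis(fix_default, params, rel_step = 0.005,
                             t_grid = seq(0, 6, by = 0.1))
  m1 <- setNames(t1$rms_sensitivity, t1$parameter)
  m2 <- setNames(t2$rms_sensitivity, t2$parameter)
  expect_equal(m1[params], m2[params], tolerance = 0.01)
})

test_that("a zero-valued parameter triggers the one-sided difference warning", {
  fix0 <- fixture_set(fix_default, "gut.lower_proximal.smct1.vmax", 0)
  expect_warning(
    sensitivity_analysis(fix0, "gut.lower_proximal.smct1.vmax",
                         t_grid = seq(0, 6, by = 0.5)),
    "one-sided")
})

test_that("overlay on self-generated noise-free data has zero residuals", {
  ov <- calibration_overlay(model_default, noise_free_data)
  expect_lt(max(abs(ov$residuals$residual)), 1e-8)
  expect_equal(ov$within_sem_fraction, 1)
  expect_s3_class(ov$plot, "ggplot")
})
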