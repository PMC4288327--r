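# IVIVE, bounded least-squares calibration, and local sensitivity analysis.

test_that("IVIVE Vmax is the product of its factors and matches the packaged set", {
  expect_equal(ivive_vmax(1, 1, 1), 1)
  expect_equal(ivive_vmax(2, 3, 4), 24)
  expect_equal(ivive_vmax(2, 3, 8), 2 * ivive_vmax(2, 3, 4))
  expect_error(ivive_vmax(-1, 1, 1), "positive")

  iv <- rat_adult()$ivive
  expect_equal(ivive_vmax(iv$vmax_in_vitro, iv$mppgl, iv$liver_mass_g),
               rat_adult()$metabolism$vmax_hepatic)
})

test_that("parameter paths address and update leaves", {
  p <- rat_adult()
  expect_equal(get_param(p, "ehr.fraction_reconjugated"), 0.9)
  p2 <- set_param(p, "chemical.partition_coefficients.fat", 3.3)
  expect_equal(get_param(p2, "chemical.partition_coefficients.fat"), 3.3)
  expect_equal(get_param(p, "chemical.partition_coefficients.fat"), 5.0)
  expect_error(get_param(p, "metabolism.k_hepatic"), "unknown")
})

test_that("calibration with no free parameters returns the input unchanged", {
  fit <- calibrate_model(list(base = rat_adult(), free = NULL,
                              targets = list(target_window(function(p) 1, 0, 2))))
  expect_true(fit$converged)
  expect_identical(fit$params, rat_adult())
})

test_that("a noiseless time course recovers the generating constant", {
  sched <- dose_schedule("oral", 100)
  s <- generate_series(rat_adult(), sched,
                       list(times = c(0.25, 0.5, 1, 2, 4, 8, 24)), seed = 3)
  fit <- calibrate_model(list(
    base = rat_adult(),
    free = data.frame(path = "metabolism.k_gut_composite",
                      lower = 1, upper = 100, start = 40),
    targets = list(target_series(s, sched))))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), 13, tolerance = 1e-2)
})

test_that("window targets steer the rat model into both excretion ranges at once", {
  ex_fn <- function(what) function(p) {
    r <- simulate_pk(p, dose_schedule("iv", 100), t_end = 96, dt_out = 0.1)
    excretion_fractions(r)[[what]]
  }
  fit <- calibrate_model(list(
    base = rat_adult(),
    free = data.frame(path = c("ehr.k_fecal", "conjugate.urinary_clearance"),
                      lower = c(0.05, 5e-4), upper = c(5, 0.1),
                      start = c(1.5, 0.03)),
    targets = list(target_window(ex_fn("urine_conjugate"), 6, 8, name = "urine"),
                   target_window(ex_fn("feces_parent"), 46, 49, name = "feces"))))
  r <- simulate_pk(fit$params, dose_schedule("iv", 100), t_end = 96)
  ex <- excretion_fractions(r)
  expect_lte(ex$urine_conjugate, 8)
  expect_gte(ex$urine_conjugate, 6)
  expect_gte(ex$feces_parent, 46)
  expect_lte(ex$feces_parent, 49)
})

test_that("sensitivity: no pathway means a zero coefficient; ranking is physiological", {
  metric <- metric_parent_auc("oral", 100)
  # urinary clearance of the conjugate cannot reach the parent curve in humans
  s0 <- normalized_sensitivity(human_adult(), metric,
                               parameters = c("conjugate.urinary_clearance"))
  expect_lt(abs(s0$coefficient), 1e-6)

  sens <- normalized_sensitivity(monkey_adult(), metric)
  top <- sens$parameter[1:3]
  expect_true("metabolism.k_hepatic" %in% top)
  expect_true(any(c("metabolism.k_gut_metabolism",
                    "absorption.k_portal_transfer",
                    "absorption.k_lumen_uptake") %in% top))
  expect_error(normalized_sensitivity(monkey_adult(), metric, perturbation = 0.5),
               "perturbation")
})

test_that("cardiac output lowers i.v. parent exposure under flow-limited clearance", {
  s <- normalized_sensitivity(monkey_adult(), metric_parent_auc("iv", 100),
                              parameters = "physiology.cardiac_output")
  expect_lt(s$coefficient, -0.3)
})

test_that("sensitivity coefficients are stable as the perturbation shrinks", {
  metric <- metric_parent_auc("oral", 100)
  c1 <- normalized_sensitivity(monkey_adult(), metric,
                               parameters = "metabolism.k_hepatic",
                               perturbation = 0.01)$coefficient
  c2 <- normalized_sensitivity(monkey_adult(), metric,
                               parameters = "metabolism.k_hepatic",
                               perturbation = 0.005)$coefficient
  expect_equal(c1, c2, tolerance = 0.05)
})
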