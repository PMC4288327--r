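# Flow-limited core: unit rates, bolus handling, conservation, solver oracle.

test_that("tissue_rate is zero at equilibrium and flow-limited away from it", {
  # equilibrium: tissue concentration equals pc * arterial
  expect_equal(tissue_rate(amount = 50, volume = 1, flow = 2, pc = 5,
                           c_arterial = 10), 0)
  # empty tissue takes up at flow * arterial concentration
  expect_equal(tissue_rate(0, 1, 1, 5, 10), 10)
  expect_error(tissue_rate(1, 0, 1, 1, 1), "positive")
  expect_error(tissue_rate(1, 1, 1, -2, 1), "positive")
})

test_that("hepatic metabolism: half-saturation, zero limit, low-dose linearisation", {
  mm <- list(hepatic_mode = "michaelis_menten", vmax_hepatic = 1000, km_hepatic = 50)
  expect_equal(hepatic_metabolism_rate(50, mm, 0.01), 500)
  expect_equal(hepatic_metabolism_rate(0, mm, 0.01), 0)
  expect_error(hepatic_metabolism_rate(-1, mm, 0.01), "negative")

  # matched first-order constant k = vmax/(km * V) agrees within 1% at c << km
  v <- 0.01
  fo <- list(hepatic_mode = "first_order", k_hepatic = 1000 / (50 * v))
  c <- 50 / 500
  expect_equal(hepatic_metabolism_rate(c, mm, v),
               hepatic_metabolism_rate(c, fo, v), tolerance = 0.01)
})

test_that("zero dose gives an identically zero trajectory with zero residual", {
  r <- simulate_pk(rat_adult(), dose_schedule("iv", 0), t_end = 12)
  expect_true(all(r$amounts == 0))
  expect_true(all(r$mass_balance_residual == 0))
  expect_equal(excretion_fractions(r)$feces_parent, 0)
})

test_that("an i.v. bolus appears instantaneously as dose over venous volume", {
  p <- rat_adult()
  r <- rat_iv_96()
  vven <- p$physiology$tissue_volumes$blood * p$physiology$venous_blood_fraction
  dose <- 100 * p$physiology$body_weight / p$chemical$molecular_weight_parent * 1000
  expect_equal(r$serum_parent_nM[r$time == 0], dose / vven, tolerance = 1e-12)
  expect_equal(venous_concentration(r$amounts[1, ], p), dose / vven,
               tolerance = 1e-12)
})

test_that("stiff solver matches the fixed-step Runge-Kutta oracle within 0.1%", {
  p <- rat_adult()
  sched <- dose_schedule("iv", 100)
  a <- simulate_pk(p, sched, t_end = 3, dt_out = 0.05)
  b <- simulate_fixed_step(p, sched, t_end = 3, dt = 2e-4, dt_out = 0.05)
  common <- intersect(a$time, b$time)
  expect_gte(length(common), 50)
  ia <- match(common, a$time); ib <- match(common, b$time)
  for (curve in c("serum_parent_nM", "serum_conjugate_nM")) {
    x <- a[[curve]][ia]; y <- b[[curve]][ib]
    rel <- abs(x - y) / pmax(abs(y), 1e-6 * max(abs(y)))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("mass balance closes to 0.1% of dose and states stay non-negative", {
  for (r in list(rat_iv_96(), monkey_iv_96(), rat_oral_24(), monkey_oral_24())) {
    expect_lt(max(r$mass_balance_residual), 1e-3)
    expect_gte(min(r$amounts), -1e-6 * r$dose_nmol)
    # cumulative quantities never decrease
    for (col in c("urine_conj", "feces_par", "feces_conj", "cum_hep_met",
                  "cum_deconj", "auc_par")) {
      expect_gte(min(diff(r$amounts[, col])), -1e-9 * max(r$amounts[, col], 1e-12))
    }
  }
})

test_that("AUC is dose-proportional within 2% at low doses", {
  p <- rat_adult()
  m10 <- dose_metrics(simulate_pk(p, dose_schedule("iv", 10), t_end = 24), c(0, 24))
  m100 <- dose_metrics(simulate_pk(p, dose_schedule("iv", 100), t_end = 24), c(0, 24))
  expect_equal(m100$auc / m10$auc, 10, tolerance = 0.02)
})

test_that("with metabolism and excretion disabled every tissue converges to its PC", {
  p <- set_param(rat_adult(), "metabolism.vmax_hepatic", 0)
  p <- set_param(p, "conjugate.urinary_clearance", 0)
  r <- simulate_pk(p, dose_schedule("iv", 100), t_end = 48)
  n <- length(r$time)
  vol <- p$physiology$tissue_volumes
  pc <- p$chemical$partition_coefficients
  ca <- r$amounts[n, "art"] / (vol$blood * (1 - p$physiology$venous_blood_fraction))
  tissues <- c(fat = "fat", rich = "richly_perfused", slow = "slowly_perfused",
               liv = "liver")
  for (i in seq_along(tissues)) {
    ratio <- unname((r$amounts[n, names(tissues)[i]] / vol[[tissues[i]]]) / ca)
    expect_equal(ratio, pc[[tissues[i]]], tolerance = 0.005)
  }
})

test_that("post-distribution serum decline is log-linear (R^2 > 0.99 over 4-8 h)", {
  expect_gt(log_r_squared(rat_iv_96(), c(4, 8)), 0.99)
})

test_that("repeated runs of the same scenario are bit-for-bit identical", {
  p <- load_parameter_set("rat", "PND3")
  s <- dose_schedule("oral", 50, n_days = 2)
  r1 <- simulate_pk(p, s, t_end = 48)
  r2 <- simulate_pk(p, s, t_end = 48)
  expect_identical(r1$amounts, r2$amounts)
})

test_that("simulation rejects inconsistent horizons and reports tidy export", {
  expect_error(simulate_pk(rat_adult(), dose_schedule("iv", 100), t_end = -1),
               "t_end")
  td <- sim_tidy(rat_oral_24())
  expect_true(all(c("time", "variable", "value", "units") %in% names(td)))
  expect_true("serum_parent" %in% td$variable)
})
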