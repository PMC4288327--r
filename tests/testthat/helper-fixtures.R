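# Shared fixtures, memoized so the expensive reference simulations run once
# per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

rat_adult <- function() fixture("rat_adult", load_parameter_set("rat", "adult"))
monkey_adult <- function() fixture("monkey_adult", load_parameter_set("monkey", "adult"))
human_adult <- function() fixture("human_adult", load_parameter_set("human", "adult"))
human_newborn <- function() fixture("human_newborn", load_parameter_set("human", "newborn"))

rat_iv_96 <- function() fixture("rat_iv_96",
  simulate_pk(rat_adult(), dose_schedule("iv", 100), t_end = 96))
monkey_iv_96 <- function() fixture("monkey_iv_96",
  simulate_pk(monkey_adult(), dose_schedule("iv", 100), t_end = 96))
rat_oral_24 <- function() fixture("rat_oral_24",
  simulate_pk(rat_adult(), dose_schedule("oral", 100), t_end = 24))
monkey_oral_24 <- function() fixture("monkey_oral_24",
  simulate_pk(monkey_adult(), dose_schedule("oral", 100), t_end = 24))
panel_50 <- function() fixture("panel_50", cross_species_panel(50))

# terminal slope (1/h) of a log-linear fit over a time window
log_slope <- function(r, window, analyte = "parent") {
  y <- if (analyte == "parent") r$serum_parent_nM else r$serum_conjugate_nM
  i <- r$time >= window[1] & r$time <= window[2] & y > 0
  unname(-stats::coef(stats::lm(log(y[i]) ~ r$time[i]))[2])
}

log_r_squared <- function(r, window, analyte = "parent") {
  y <- if (analyte == "parent") r$serum_parent_nM else r$serum_conjugate_nM
  i <- r$time >= window[1] & r$time <= window[2] & y > 0
  summary(stats::lm(log(y[i]) ~ r$time[i]))$r.squared
}

# fabricate a minimal simulation object carrying a prescribed serum curve
# and its analytically integrated AUC state, for closed-form metric tests
make_fake_sim <- function(time, conc_ugL, auc_state_ugLh, p = rat_adult()) {
  mw <- p$chemical$molecular_weight_parent
  amounts <- matrix(0, length(time), length(bpapbpk:::STATE_NAMES),
                    dimnames = list(NULL, bpapbpk:::STATE_NAMES))
  vven <- p$physiology$tissue_volumes$blood * p$physiology$venous_blood_fraction
  amounts[, "ven"] <- conc_ugL / mw * 1000 * vven
  amounts[, "auc_par"] <- auc_state_ugLh / mw * 1000
  structure(list(time = time, amounts = amounts,
                 serum_parent_nM = conc_ugL / mw * 1000,
                 serum_conjugate_nM = rep(0, length(time)),
                 serum_parent_ugL = conc_ugL,
                 serum_conjugate_ugL = rep(0, length(time)),
                 mass_balance_residual = rep(0, length(time)),
                 dose_nmol = 1, params = p,
                 schedule = dose_schedule("iv", 1)),
            class = "bpa_simulation")
}
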