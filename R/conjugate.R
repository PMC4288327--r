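# Systemic disposition of total BPA conjugates: one compartment for monkey
# and human, three for rat, urinary excretion, and capacity-limited renal
# reabsorption in the monkey.

#' Renal filtration and (monkey) reabsorption of conjugate
#'
#' The filtration flux is `urinary_clearance * concentration`. For the
#' monkey a Michaelis-Menten reabsorption flux, capped at the filtration
#' flux so the urine rate can never go negative, is returned to the central
#' pool; the urinary rate is the difference. For rat and human the
#' reabsorbed flux is zero.
#'
#' @param c_central Central conjugate concentration (nmol/L).
#' @param cpar Conjugate parameter list (`urinary_clearance`, optional
#'   `renal_reabsorption = list(vmax, km)`).
#' @return List with `to_urine` and `reabsorbed` (nmol/h).
#' @export
renal_handling_rate <- function(c_central, cpar) {
  if (any(c_central < 0)) stop("negative conjugate concentration", call. = FALSE)
  filtration <- cpar$urinary_clearance * c_central
  rr <- cpar$renal_reabsorption
  reabsorbed <- if (is.null(rr)) {
    0 * c_central
  } else {
    pmin(rr$vmax * c_central / (rr$km + c_central), filtration)
  }
  list(to_urine = filtration - reabsorbed, reabsorbed = reabsorbed)
}

#' Net rates for the systemic conjugate pools
#'
#' The central pool receives all conjugate inputs (hepatic bypass flux,
#' enterocyte conjugate efflux, reconjugation in the rat EHR loop),
#' exchanges first-order with up to two peripheral pools (rat), and loses
#' mass to urine, to feces (monkey: a small first-order fecal clearance),
#' and — in the rat — to bile (`biliary_removal`, computed by
#' [biliary_excretion_rate()] on the same pool).
#'
#' @param state List with `central`, and for the rat `peripheral_1`,
#'   `peripheral_2` (amounts, nmol).
#' @param cpar Conjugate parameter list.
#' @param inputs Total conjugate inflow to the central pool (nmol/h).
#' @param biliary_removal Biliary excretion flux leaving the central pool
#'   (nmol/h; rat only, 0 otherwise).
#' @return List with `d_central`, `d_peripheral_1`, `d_peripheral_2`,
#'   `to_urine`, `fecal` (nmol/h).
#' @export
conjugate_rhs <- function(state, cpar, inputs, biliary_removal = 0) {
  vc <- cpar$volumes$central
  cc <- state$central / vc
  renal <- renal_handling_rate(max(cc, 0), cpar)
  fecal <- (cpar$fecal_clearance %||% 0) * max(cc, 0)
  exch_out1 <- exch_in1 <- exch_out2 <- exch_in2 <- 0
  d_p1 <- d_p2 <- 0
  if (identical(as.integer(cpar$n_compartments), 3L)) {
    exch_out1 <- cpar$k_central_p1 * state$central
    exch_in1 <- cpar$k_p1_central * state$peripheral_1
    exch_out2 <- cpar$k_central_p2 * state$central
    exch_in2 <- cpar$k_p2_central * state$peripheral_2
    d_p1 <- exch_out1 - exch_in1
    d_p2 <- exch_out2 - exch_in2
  }
  d_central <- inputs - renal$to_urine - fecal - biliary_removal -
    exch_out1 + exch_in1 - exch_out2 + exch_in2
  list(d_central = d_central, d_peripheral_1 = d_p1, d_peripheral_2 = d_p2,
       to_urine = renal$to_urine, fecal = fecal)
}
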