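# Oral absorption, presystemic enterocyte conjugation, and the rat
# enterohepatic recirculation (EHR) loop.
#
# All functions here return instantaneous rates (nmol/h) given amounts
# (nmol); the master ODE right-hand side in pbpk_core.R composes them, so
# the unit-level behavior tested on these functions is exactly what the
# integrated model uses.

#' First-order gastric emptying and gut-lumen uptake rates
#'
#' @param state List with `stomach` and `lumen` amounts (nmol).
#' @param a Absorption parameter list with `k_gastric_emptying`,
#'   `k_lumen_uptake` (both /h).
#' @return List with `d_stomach`, `d_lumen` (net nmol/h for the two pools)
#'   and `uptake` (the lumen-to-enterocyte flux, nmol/h). The transfers are
#'   conservative: `d_stomach + d_lumen + uptake == 0`.
#' @export
oral_absorption_rhs <- function(state, a) {
  emptying <- a$k_gastric_emptying * state$stomach
  uptake <- a$k_lumen_uptake * state$lumen
  list(d_stomach = -emptying,
       d_lumen = emptying - uptake,
       uptake = uptake)
}

#' Partition enterocyte parent compound between portal escape and conjugation
#'
#' In the rat a single composite first-order constant lumps enterocyte
#' conjugation together with the immediate (MRP3-like) transport of the
#' formed conjugate into portal blood, so the conjugated flux appears in the
#' systemic conjugate pool with no intervening enterocyte-conjugate state.
#' In monkey and human the conjugate is formed into an explicit enterocyte
#' pool and effluxed to systemic blood with its own first-order constant.
#'
#' @param enterocyte_parent Parent amount in enterocytes (nmol).
#' @param m Metabolism parameter list.
#' @param a Absorption parameter list (supplies `k_portal_transfer`, the
#'   first-order escape of unconjugated parent to portal blood).
#' @param species `"rat"`, `"monkey"` or `"human"`.
#' @param enterocyte_conjugate Conjugate amount in enterocytes (nmol;
#'   monkey/human only).
#' @return List of rates (nmol/h): `to_portal_parent`, `conjugated`,
#'   `conjugate_to_systemic`.
#' @export
enterocyte_split <- function(enterocyte_parent, m, a, species,
                             enterocyte_conjugate = 0) {
  to_portal <- a$k_portal_transfer * enterocyte_parent
  if (identical(species, "rat")) {
    if (is.null(m$k_gut_composite)) {
      stop("rat enterocyte model requires k_gut_composite", call. = FALSE)
    }
    conj <- m$k_gut_composite * enterocyte_parent
    list(to_portal_parent = to_portal, conjugated = conj,
         conjugate_to_systemic = conj)
  } else {
    if (is.null(m$k_gut_metabolism) || is.null(m$k_enterocyte_conjugate_efflux)) {
      stop(species, " enterocyte model requires k_gut_metabolism and ",
           "k_enterocyte_conjugate_efflux", call. = FALSE)
    }
    conj <- m$k_gut_metabolism * enterocyte_parent
    list(to_portal_parent = to_portal, conjugated = conj,
         conjugate_to_systemic = m$k_enterocyte_conjugate_efflux * enterocyte_conjugate)
  }
}

#' Capacity-limited (Michaelis-Menten) biliary excretion of conjugate
#'
#' Applied to the central conjugate pool of the rat, so conjugate arriving
#' systemically (from gut-wall conjugation or reconjugation of deconjugated
#' parent) recirculates through bile along with the hepatically formed share.
#'
#' @param c_conjugate Central conjugate concentration (nmol/L).
#' @param e EHR parameter list with `vmax_biliary` (nmol/h) and `km_biliary`
#'   (nmol/L).
#' @return Biliary excretion rate (nmol/h).
#' @export
biliary_excretion_rate <- function(c_conjugate, e) {
  if (any(c_conjugate < 0)) stop("negative conjugate concentration", call. = FALSE)
  e$vmax_biliary * c_conjugate / (e$km_biliary + c_conjugate)
}

#' Rates for the rat enterohepatic recirculation loop
#'
#' Biliary conjugate passes through `n_transit` first-order transit
#' compartments to the terminal intestine, where bacteria deconjugate it.
#' The deconjugation flux is partitioned at rate level — so the split is
#' exact at every instant — into reconjugation (fraction_reconjugated, the
#' liberated parent re-enters enterocytes, is conjugated and appears in the
#' systemic conjugate pool), reabsorption into systemic blood as parent
#' (fraction_reabsorbed_parent; this sustained return is what slows the
#' apparent systemic clearance of parent BPA), and fecal excretion of
#' parent (the remainder). Conjugate that is not deconjugated leaves in
#' feces at `k_fecal`.
#'
#' @param state List with `bile_transit` (numeric vector of length
#'   `n_transit`, nmol), `terminal_conjugate` (nmol) and `bile_input`
#'   (nmol/h, the flux entering the first transit compartment).
#' @param e EHR parameter list.
#' @return List with `d_transit` (vector), `d_terminal_conjugate`,
#'   `deconjugation`, `reconjugated`, `reabsorbed_parent`, `fecal_parent`,
#'   `fecal_conjugate` (all nmol/h).
#' @export
ehr_loop_rhs <- function(state, e) {
  n <- as.integer(e$n_transit)
  bt <- state$bile_transit
  if (n > 0 && length(bt) < n) stop("bile_transit shorter than n_transit", call. = FALSE)
  if (n > 0L) {
    inflow <- c(state$bile_input, e$k_transit * bt[seq_len(n - 1L)])
    d_transit <- inflow - e$k_transit * bt[seq_len(n)]
    to_terminal <- e$k_transit * bt[n]
  } else {
    d_transit <- numeric(0)
    to_terminal <- state$bile_input
  }
  deconj <- e$k_deconjugation * state$terminal_conjugate
  fecal_conj <- e$k_fecal * state$terminal_conjugate
  f_fecal <- 1 - e$fraction_reconjugated - e$fraction_reabsorbed_parent
  list(d_transit = d_transit,
       d_terminal_conjugate = to_terminal - deconj - fecal_conj,
       deconjugation = deconj,
       reconjugated = e$fraction_reconjugated * deconj,
       reabsorbed_parent = e$fraction_reabsorbed_parent * deconj,
       fecal_parent = f_fecal * deconj,
       fecal_conjugate = fecal_conj)
}
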