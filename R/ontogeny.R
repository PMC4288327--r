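# Life-stage and cross-species parameter derivation: allometric scaling,
# maturation fractions, and the monkey-to-human extrapolation.
#
# Allometric conventions (recorded as assumptions): volumes scale with body
# weight to the power 1, flows and Vmax-like capacities to the power 0.75,
# and first-order rate constants to the power -0.25, so that first-order
# capacities (k x V) also scale with the 0.75 power.

ALLOMETRIC_EXPONENTS <- c(volume = 1.0, flow = 0.75,
                          clearance_capacity = 0.75, first_order_rate = -0.25)

scale_leaves <- function(x, factor) rapply(x, function(v) v * factor, classes = "numeric", how = "replace")

#' Derive a life-stage parameter set from a base set and an ontogeny table
#'
#' Physiological volumes scale in proportion to body weight; cardiac output,
#' tissue flows and Vmax-type capacities with the 0.75 power of the
#' body-weight ratio; first-order rate constants with the -0.25 power. The
#' maturation fractions then multiply the allometrically scaled capacities:
#' hepatic conjugation by `hepatic_fraction_of_adult`, gut-wall conjugation
#' by `gut_fraction_of_adult`, and biliary conjugate export (MRP2-mediated)
#' by `mrp2_fraction_of_adult`. Because the table stores fractions relative
#' to the adult, scaling is compositional: adult to PND3 directly equals
#' adult to PND21 to PND3.
#'
#' @param base A `bpa_parameters` object whose `life_stage` appears in `table`.
#' @param table Ontogeny table, see [load_ontogeny_table()].
#' @param life_stage Target life stage (must appear in `table`).
#' @return A new `bpa_parameters` object for the target stage.
#' @export
scale_for_age <- function(base, table, life_stage) {
  stopifnot(inherits(base, "bpa_parameters"))
  check_ontogeny_table(table)
  for (st in c(base$life_stage, life_stage)) {
    if (!st %in% table$life_stage) {
      stop("life stage '", st, "' not in ontogeny table (has: ",
           paste(table$life_stage, collapse = ", "), ")", call. = FALSE)
    }
  }
  if (identical(base$life_stage, life_stage)) return(base)
  row_b <- table[table$life_stage == base$life_stage, ][1, ]
  row_t <- table[table$life_stage == life_stage, ][1, ]
  s <- row_t$body_weight / row_b$body_weight
  f_vol <- s^ALLOMETRIC_EXPONENTS[["volume"]]
  f_cap <- s^ALLOMETRIC_EXPONENTS[["clearance_capacity"]]
  f_rate <- s^ALLOMETRIC_EXPONENTS[["first_order_rate"]]
  hep <- row_t$hepatic_fraction_of_adult / row_b$hepatic_fraction_of_adult
  gut <- row_t$gut_fraction_of_adult / row_b$gut_fraction_of_adult
  mrp2 <- row_t$mrp2_fraction_of_adult / row_b$mrp2_fraction_of_adult

  p <- base
  ph <- p$physiology
  ph$body_weight <- ph$body_weight * s
  ph$cardiac_output <- ph$cardiac_output * f_cap
  ph$bile_flow <- ph$bile_flow * f_cap
  ph$glomerular_filtration <- ph$glomerular_filtration * f_cap
  ph$tissue_volumes <- scale_leaves(ph$tissue_volumes, f_vol)
  ph$tissue_flows <- scale_leaves(ph$tissue_flows, f_cap)
  p$physiology <- ph

  m <- p$metabolism
  if (identical(p$species, "rat")) {
    m$vmax_hepatic <- m$vmax_hepatic * f_cap * hep
    m$k_gut_composite <- m$k_gut_composite * f_rate * gut
  } else {
    m$k_hepatic <- m$k_hepatic * f_rate * hep
    m$k_gut_metabolism <- m$k_gut_metabolism * f_rate * gut
    m$k_enterocyte_conjugate_efflux <- m$k_enterocyte_conjugate_efflux * f_rate
  }
  p$metabolism <- m

  p$absorption <- scale_leaves(p$absorption, f_rate)

  if (!is.null(p$ehr)) {
    e <- p$ehr
    e$vmax_biliary <- e$vmax_biliary * f_cap * mrp2
    for (f in c("k_transit", "k_deconjugation", "k_fecal")) e[[f]] <- e[[f]] * f_rate
    p$ehr <- e
  }

  cj <- p$conjugate
  cj$volumes <- scale_leaves(cj$volumes, f_vol)
  cj$urinary_clearance <- cj$urinary_clearance * f_cap
  if (!is.null(cj$fecal_clearance)) cj$fecal_clearance <- cj$fecal_clearance * f_cap
  for (f in c("k_central_p1", "k_p1_central", "k_central_p2", "k_p2_central")) {
    if (!is.null(cj[[f]])) cj[[f]] <- cj[[f]] * f_rate
  }
  if (!is.null(cj$renal_reabsorption)) {
    cj$renal_reabsorption$vmax <- cj$renal_reabsorption$vmax * f_cap
  }
  p$conjugate <- cj

  p$ivive <- NULL   # the IVIVE product is an adult-set consistency record
  p$life_stage <- life_stage
  p
}

tag_all <- function(x, tag) rapply(x, function(v) tag, how = "replace")

#' Extrapolate a calibrated monkey parameter set to a human
#'
#' Replaces the physiology (and, optionally, the chemical properties) with
#' human values, rescales all first-order rate constants by the body-weight
#' ratio to the -0.25 power, rescales clearances and conjugate volumes
#' allometrically, and removes renal reabsorption of the conjugate, which is
#' not supported for humans.
#'
#' @param monkey A calibrated monkey `bpa_parameters` object.
#' @param human_physiology A physiology list (same structure as the
#'   `physiology` block of a parameter file).
#' @param life_stage Label for the resulting human set (e.g. `"newborn"`).
#' @param chemical Optional human chemical-properties list; defaults to the
#'   monkey values.
#' @param provenance Optional provenance block for the supplied physiology
#'   and chemical values.
#' @return A human `bpa_parameters` object.
#' @export
extrapolate_monkey_to_human <- function(monkey, human_physiology, life_stage,
                                        chemical = NULL, provenance = NULL) {
  stopifnot(inherits(monkey, "bpa_parameters"))
  if (!identical(monkey$species, "monkey")) {
    stop("source set must be a monkey model (got ", monkey$species, ")",
         call. = FALSE)
  }
  r <- human_physiology$body_weight / monkey$physiology$body_weight
  f_rate <- r^ALLOMETRIC_EXPONENTS[["first_order_rate"]]
  f_cap <- r^ALLOMETRIC_EXPONENTS[["clearance_capacity"]]

  p <- monkey
  p$species <- "human"
  p$life_stage <- life_stage
  p$physiology <- human_physiology
  p$chemical <- chemical %||% monkey$chemical

  m <- p$metabolism
  for (f in c("k_hepatic", "k_gut_metabolism", "k_enterocyte_conjugate_efflux")) {
    m[[f]] <- m[[f]] * f_rate
  }
  p$metabolism <- m
  p$absorption <- scale_leaves(p$absorption, f_rate)

  cj <- p$conjugate
  cj$volumes <- scale_leaves(cj$volumes, r)
  cj$urinary_clearance <- cj$urinary_clearance * f_cap
  cj$fecal_clearance <- 0
  cj$renal_reabsorption <- NULL
  p$conjugate <- cj

  prov <- monkey$provenance
  prov$physiology <- (provenance %||% list())$physiology %||%
    tag_all(human_physiology, "assumed (human physiology)")
  prov$chemical <- (provenance %||% list())$chemical %||%
    tag_all(p$chemical, "assumed (human)")
  prov$conjugate$renal_reabsorption <- NULL
  p$provenance <- prov
  p
}
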