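# Parameter sets: loading, validation, round-trip and ontogeny fold reports.
#
# Internal unit conventions: amounts nmol, volumes L, time h, flows L/h,
# concentrations nmol/L. Mass units (ug) appear only at the dosing and
# reporting boundaries, converted through the molecular weight.

BPA_SPECIES <- c("rat", "monkey", "human")

# life stages resolvable by load_parameter_set(); "adult" sets are files,
# the others are derived at load time from the adult file plus the packaged
# ontogeny table (or, for the newborn human, by cross-species extrapolation
# from the postnatal-day-5 monkey).
BPA_LIFE_STAGES <- list(
  rat    = c("adult", "PND3", "PND10", "PND21"),
  monkey = c("adult", "PND5", "PND35", "PND70"),
  human  = c("adult", "newborn")
)

#' List the packaged parameter sets
#'
#' @return A data.frame with columns `species`, `life_stage` and `source`
#'   (`"file"` for sets shipped as YAML, `"ontogeny"` for life stages derived
#'   from the adult set and the packaged ontogeny table, `"extrapolated"` for
#'   the newborn human derived from the infant monkey).
#' @export
available_parameter_sets <- function() {
  out <- do.call(rbind, lapply(names(BPA_LIFE_STAGES), function(sp) {
    st <- BPA_LIFE_STAGES[[sp]]
    data.frame(species = sp, life_stage = st,
               source = ifelse(st == "adult", "file",
                               ifelse(sp == "human", "extrapolated", "ontogeny")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Load a validated parameter set for one species and life stage
#'
#' Adult sets are read from the YAML files shipped under
#' `inst/extdata/parameters/`. Immature rat and monkey stages are produced by
#' [scale_for_age()] from the adult set and the packaged ontogeny table. The
#' newborn human set is produced by [extrapolate_monkey_to_human()] from the
#' postnatal-day-5 (PND5) monkey set and the packaged newborn-human
#' physiology, mirroring how the infant-monkey model, rather than the
#' immature-rat model, is taken as the better surrogate for human infants.
#'
#' @param species One of `"rat"`, `"monkey"`, `"human"`.
#' @param life_stage Life-stage label, e.g. `"adult"`, `"PND10"`, `"newborn"`.
#' @return An object of class `bpa_parameters`.
#' @examples
#' rat <- load_parameter_set("rat", "adult")
#' rat$metabolism$hepatic_mode
#' @export
load_parameter_set <- function(species, life_stage = "adult") {
  species <- match.arg(species, BPA_SPECIES)
  stages <- BPA_LIFE_STAGES[[species]]
  if (!life_stage %in% stages) {
    stop("unknown life stage '", life_stage, "' for ", species,
         "; available: ", paste(stages, collapse = ", "), call. = FALSE)
  }
  adult <- read_parameter_set(bpk_extdata("parameters", paste0(species, "_adult.yaml")))
  p <-
    if (life_stage == "adult") {
      adult
    } else if (species == "human") {
      monkey_pnd5 <- load_parameter_set("monkey", "PND5")
      hum <- read_physiology_yaml(bpk_extdata("parameters", "human_newborn_physiology.yaml"))
      extrapolate_monkey_to_human(monkey_pnd5, hum$physiology, "newborn",
                                  chemical = hum$chemical)
    } else {
      scale_for_age(adult, load_ontogeny_table(species), life_stage)
    }
  rep <- validate_parameters(p)
  if (!is_valid(rep)) {
    stop("parameter set (", species, ", ", life_stage, ") failed validation:\n",
         paste(format(rep), collapse = "\n"), call. = FALSE)
  }
  p
}

#' Read a parameter-set YAML file
#'
#' @param path Path to a YAML file following the packaged schema
#'   (`schema_version: 1`).
#' @return A `bpa_parameters` object (not yet validated).
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1) {
    stop("unsupported or missing schema_version in ", path, call. = FALSE)
  }
  required <- c("species", "life_stage", "physiology", "chemical",
                "metabolism", "absorption", "conjugate")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("parameter file ", path, " lacks blocks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_bpa_parameters(raw)
}

new_bpa_parameters <- function(x) {
  keep <- c("species", "life_stage", "physiology", "chemical", "metabolism",
            "absorption", "ehr", "conjugate", "ivive", "provenance")
  p <- x[intersect(keep, names(x))]
  p <- p[!vapply(p, is.null, logical(1))]   # optional blocks simply absent
  p$schema_version <- 1
  structure(p, class = "bpa_parameters")
}

#' Write a parameter set back to YAML
#'
#' Values are written with enough precision that a write-then-read round trip
#' is value-identical (to double precision printing, 15 significant digits).
#'
#' @param p A `bpa_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(p, path) {
  stopifnot(inherits(p, "bpa_parameters"))
  out <- unclass(p)
  out <- out[!vapply(out, is.null, logical(1))]
  out <- c(list(schema_version = 1), out[setdiff(names(out), "schema_version")])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

read_physiology_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$physiology)) stop("no physiology block in ", path, call. = FALSE)
  raw
}

## ---- validation -----------------------------------------------------------

violation <- function(field, message) {
  data.frame(field = field, message = message, stringsAsFactors = FALSE)
}

#' Validate a parameter set against the model's structural invariants
#'
#' Checks positivity of physiological values, conservation of blood flow
#' (tissue flows must sum to cardiac output), plausibility of partition
#' coefficients, species-consistency of the metabolic mode (Michaelis-Menten
#' with an enterohepatic-recirculation block for the rat; first-order hepatic
#' and gut constants for monkey and human), the near-complete routing of
#' hepatically formed conjugate to bile in the rat (fraction >= 0.99), the
#' conjugate compartment count (three for rat, one otherwise), and that renal
#' reabsorption parameters are present for the monkey only.
#'
#' @param p A `bpa_parameters` object.
#' @return A `bpa_validation` object: a data.frame of violations (zero rows
#'   when the set is valid) with a `format()`/`print()` method and a JSON
#'   rendering via [validation_json()].
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "bpa_parameters"))
  v <- list()
  add <- function(field, msg) v[[length(v) + 1L]] <<- violation(field, msg)

  ph <- p$physiology
  num_pos <- c(body_weight = ph$body_weight, cardiac_output = ph$cardiac_output,
               bile_flow = ph$bile_flow, glomerular_filtration = ph$glomerular_filtration,
               unlist(ph$tissue_volumes), unlist(ph$tissue_flows))
  bad <- names(num_pos)[!vapply(num_pos, is_scalar_number, logical(1)) | num_pos <= 0]
  for (b in bad) add(paste0("physiology.", b), "must be a finite positive number")

  flows <- unlist(ph$tissue_flows)
  if (length(flows) && is_scalar_number(ph$cardiac_output)) {
    rel <- abs(sum(flows) - ph$cardiac_output) / ph$cardiac_output
    if (rel > 1e-9) {
      add("physiology.tissue_flows",
          sprintf("must sum to cardiac_output (relative error %.3g)", rel))
    }
  }
  vols <- unlist(ph$tissue_volumes)
  if (length(vols) && is_scalar_number(ph$body_weight) &&
      sum(vols) > ph$body_weight) {
    add("physiology.tissue_volumes",
        "sum exceeds body weight (density 1 kg/L assumed)")
  }

  ch <- p$chemical
  pcs <- unlist(ch$partition_coefficients)
  if (any(pcs <= 0)) add("chemical.partition_coefficients", "must all be > 0")
  fat_pc <- ch$partition_coefficients$fat
  if (!is.null(fat_pc) && (fat_pc < 1 || fat_pc > 20)) {
    add("chemical.partition_coefficients.fat", "must lie in [1, 20]")
  }
  for (f in c("molecular_weight_parent", "molecular_weight_conjugate")) {
    if (!is_scalar_number(ch[[f]]) || ch[[f]] <= 0) add(paste0("chemical.", f), "must be > 0")
  }

  m <- p$metabolism
  if (identical(p$species, "rat")) {
    if (!identical(m$hepatic_mode, "michaelis_menten")) {
      add("metabolism.hepatic_mode", "rat model uses michaelis_menten hepatic conjugation")
    }
    for (f in c("vmax_hepatic", "km_hepatic", "k_gut_composite",
                "fraction_hepatic_conjugate_to_bile")) {
      if (!is_scalar_number(m[[f]]) || m[[f]] < 0) add(paste0("metabolism.", f), "must be finite and >= 0")
    }
    fb <- m$fraction_hepatic_conjugate_to_bile
    if (is_scalar_number(fb) && (fb < 0.99 || fb > 1)) {
      add("metabolism.fraction_hepatic_conjugate_to_bile",
          "must be >= 0.99: less than 1% of hepatically formed conjugate may bypass bile")
    }
    for (f in c("k_hepatic", "k_gut_metabolism", "k_enterocyte_conjugate_efflux")) {
      if (!is.null(m[[f]])) add(paste0("metabolism.", f), "not a rat-model parameter")
    }
  } else {
    if (!identical(m$hepatic_mode, "first_order")) {
      add("metabolism.hepatic_mode", "monkey/human models use first_order hepatic conjugation")
    }
    for (f in c("k_hepatic", "k_gut_metabolism", "k_enterocyte_conjugate_efflux")) {
      if (!is_scalar_number(m[[f]]) || m[[f]] < 0) add(paste0("metabolism.", f), "must be finite and >= 0")
    }
    for (f in c("vmax_hepatic", "km_hepatic", "k_gut_composite",
                "fraction_hepatic_conjugate_to_bile")) {
      if (!is.null(m[[f]])) add(paste0("metabolism.", f), "rat-only parameter")
    }
  }

  ab <- p$absorption
  for (f in c("k_gastric_emptying", "k_lumen_uptake", "k_portal_transfer")) {
    if (!is_scalar_number(ab[[f]]) || ab[[f]] < 0) add(paste0("absorption.", f), "must be finite and >= 0")
  }

  if (identical(p$species, "rat")) {
    e <- p$ehr
    if (is.null(e)) {
      add("ehr", "rat model requires the enterohepatic recirculation block")
    } else {
      for (f in c("vmax_biliary", "km_biliary", "k_transit", "k_deconjugation",
                  "k_fecal", "fraction_reconjugated", "fraction_reabsorbed_parent")) {
        if (!is_scalar_number(e[[f]]) || e[[f]] < 0) add(paste0("ehr.", f), "must be finite and >= 0")
      }
      if (!is_scalar_number(e$n_transit) || e$n_transit < 0 || e$n_transit > 3 ||
          e$n_transit != round(e$n_transit)) {
        add("ehr.n_transit", "must be an integer in 0..3")
      }
      if (is_scalar_number(e$fraction_reconjugated) &&
          is_scalar_number(e$fraction_reabsorbed_parent)) {
        tot <- e$fraction_reconjugated + e$fraction_reabsorbed_parent
        if (tot > 1 + 1e-12) {
          add("ehr.fraction_reconjugated",
              "reconjugated + reabsorbed fractions exceed 1 (fecal fraction would be negative)")
        }
      }
    }
  } else if (!is.null(p$ehr)) {
    add("ehr", "enterohepatic recirculation block is rat-only")
  }

  cj <- p$conjugate
  n_expected <- if (identical(p$species, "rat")) 3L else 1L
  if (!identical(as.integer(cj$n_compartments), n_expected)) {
    add("conjugate.n_compartments",
        sprintf("must be %d for %s", n_expected, p$species))
  }
  if (!is_scalar_number(cj$urinary_clearance) || cj$urinary_clearance < 0) {
    add("conjugate.urinary_clearance", "must be finite and >= 0")
  }
  if (any(unlist(cj$volumes) <= 0)) add("conjugate.volumes", "must all be > 0")
  if (identical(p$species, "monkey")) {
    rr <- cj$renal_reabsorption
    if (is.null(rr) || !is_scalar_number(rr$vmax) || !is_scalar_number(rr$km)) {
      add("conjugate.renal_reabsorption", "monkey model requires {vmax, km}")
    }
  } else if (!is.null(cj$renal_reabsorption)) {
    add("conjugate.renal_reabsorption", "present for monkey only")
  }

  # provenance: every top-level parameter block entry should carry a tag
  prov <- p$provenance
  tagged <- names(unlist(prov))
  leaves <- names(unlist(p[c("physiology", "chemical", "metabolism",
                             "absorption", "ehr", "conjugate")]))
  untagged <- setdiff(leaves, tagged)
  if (length(untagged)) {
    add("provenance", paste("untagged parameters:", paste(untagged, collapse = ", ")))
  }

  out <- if (length(v)) do.call(rbind, v) else violation(character(), character())
  structure(out, class = c("bpa_validation", "data.frame"))
}

#' @rdname validate_parameters
#' @param report A `bpa_validation` object.
#' @export
is_valid <- function(report) nrow(report) == 0L

#' @export
format.bpa_validation <- function(x, ...) {
  if (nrow(x) == 0L) return("all invariants hold")
  paste0("- ", x$field, ": ", x$message)
}

#' @export
print.bpa_validation <- function(x, ...) {
  cat("<bpa_validation> ", nrow(x), " violation(s)\n", sep = "")
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @rdname validate_parameters
#' @export
validation_json <- function(report) {
  jsonlite::toJSON(list(valid = is_valid(report),
                        violations = as.data.frame(report)),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' @export
print.bpa_parameters <- function(x, ...) {
  cat("<bpa_parameters> ", x$species, " / ", x$life_stage,
      " (", x$physiology$body_weight, " kg)\n", sep = "")
  cat("  hepatic mode: ", x$metabolism$hepatic_mode,
      if (!is.null(x$ehr)) " | enterohepatic recirculation" else "",
      if (!is.null(x$conjugate$renal_reabsorption)) " | renal reabsorption" else "",
      "\n", sep = "")
  invisible(x)
}

## ---- ontogeny table -------------------------------------------------------

#' Load a packaged ontogeny (maturation) table
#'
#' Each row gives, for one life stage, the body weight and the maturation of
#' hepatic conjugation, gut-wall conjugation and biliary (MRP2-mediated)
#' conjugate export, each as a fraction of the adult, allometrically scaled,
#' capacity. Fractions are 1 at the adult row by construction.
#'
#' @param species `"rat"` or `"monkey"`.
#' @return A data.frame with columns `life_stage`, `body_weight`,
#'   `hepatic_fraction_of_adult`, `gut_fraction_of_adult`,
#'   `mrp2_fraction_of_adult`.
#' @export
load_ontogeny_table <- function(species) {
  species <- match.arg(species, c("rat", "monkey"))
  tab <- utils::read.csv(bpk_extdata("ontogeny", paste0(species, ".csv")),
                         stringsAsFactors = FALSE)
  check_ontogeny_table(tab)
  tab
}

check_ontogeny_table <- function(tab) {
  need <- c("life_stage", "body_weight", "hepatic_fraction_of_adult",
            "gut_fraction_of_adult", "mrp2_fraction_of_adult")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("ontogeny table lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  fr <- as.matrix(tab[, need[3:5]])
  if (any(fr <= 0 | fr > 1)) stop("ontogeny fractions must lie in (0, 1]", call. = FALSE)
  if (!"adult" %in% tab$life_stage) stop("ontogeny table has no adult row", call. = FALSE)
  adult <- tab[tab$life_stage == "adult", need[3:5]]
  if (any(abs(unlist(adult) - 1) > 1e-12)) stop("adult fractions must equal 1", call. = FALSE)
  invisible(tab)
}

#' Fold difference in hepatic metabolic capacity versus the adult
#'
#' Capacity at a life stage is the stage's maturation fraction applied to the
#' adult capacity allometrically rescaled (exponent 0.75) to the stage's body
#' weight; the fold difference is adult capacity divided by stage capacity, so
#' the adult row is 1 by construction.
#'
#' @param table An ontogeny table as returned by [load_ontogeny_table()].
#' @return A data.frame with columns `life_stage`, `body_weight`, `fold`.
#' @export
fold_difference_report <- function(table) {
  check_ontogeny_table(table)
  bw_adult <- table$body_weight[table$life_stage == "adult"][1]
  fold <- (bw_adult / table$body_weight)^0.75 / table$hepatic_fraction_of_adult
  data.frame(life_stage = table$life_stage, body_weight = table$body_weight,
             fold = fold, stringsAsFactors = FALSE)
}
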