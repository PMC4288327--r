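# Parameter sets: loading, structural validation, round trips, ontogeny folds.

test_that("every packaged set loads, validates cleanly, and has the right structure", {
  sets <- available_parameter_sets()
  for (i in seq_len(nrow(sets))) {
    p <- load_parameter_set(sets$species[i], sets$life_stage[i])
    rep <- validate_parameters(p)
    expect_true(is_valid(rep), info = paste(sets$species[i], sets$life_stage[i]))
    if (p$species == "rat") {
      expect_identical(p$metabolism$hepatic_mode, "michaelis_menten")
      expect_false(is.null(p$ehr))
      expect_identical(as.integer(p$conjugate$n_compartments), 3L)
    } else {
      expect_identical(p$metabolism$hepatic_mode, "first_order")
      expect_null(p$ehr)
      expect_identical(as.integer(p$conjugate$n_compartments), 1L)
    }
    expect_identical(is.null(p$conjugate$renal_reabsorption), p$species != "monkey")
  }
})

test_that("unknown species/life-stage combinations error with the available sets", {
  err <- expect_error(load_parameter_set("rat", "PND200"), "PND200")
  expect_match(conditionMessage(err), "PND3")
  expect_match(conditionMessage(err), "adult")
  expect_error(load_parameter_set("dog", "adult"))
})

test_that("constructed invariant violations are reported by name", {
  p <- rat_adult()

  p_flow <- p
  p_flow$physiology$tissue_flows$fat <- p_flow$physiology$tissue_flows$fat +
    0.1 * p_flow$physiology$cardiac_output
  rep <- validate_parameters(p_flow)
  expect_false(is_valid(rep))
  expect_true(any(grepl("tissue_flows", rep$field)))

  p_bile <- set_param(p, "metabolism.fraction_hepatic_conjugate_to_bile", 0.5)
  rep <- validate_parameters(p_bile)
  expect_true(any(grepl("fraction_hepatic_conjugate_to_bile", rep$field)))
  expect_true(any(grepl("0.99", rep$message)))

  p_renal <- human_adult()
  p_renal$conjugate$renal_reabsorption <- list(vmax = 1, km = 1)
  rep <- validate_parameters(p_renal)
  expect_true(any(grepl("renal_reabsorption", rep$field)))

  # report renders as text and JSON
  expect_match(paste(format(rep), collapse = "\n"), "renal_reabsorption")
  expect_true(jsonlite::validate(validation_json(rep)))
})

test_that("write-then-read round trip is value-identical", {
  for (p in list(rat_adult(), monkey_adult(), human_newborn())) {
    f <- withr::local_tempfile(fileext = ".yaml")
    write_parameter_set(p, f)
    p2 <- read_parameter_set(f)
    expect_equal(unclass(p), unclass(p2), tolerance = 1e-12)
    expect_true(is_valid(validate_parameters(p2)))
  }
})

test_that("ontogeny fold-difference reports honour the maturation constraints", {
  rat <- fold_difference_report(load_ontogeny_table("rat"))
  expect_equal(rat$fold[rat$life_stage == "adult"], 1)
  expect_equal(max(rat$fold), 282, tolerance = 1e-5)
  expect_identical(rat$life_stage[which.max(rat$fold)], "PND3")

  mk <- fold_difference_report(load_ontogeny_table("monkey"))
  infant <- mk[mk$life_stage != "adult", ]
  expect_lte(max(infant$fold), 15)
  expect_gte(min(infant$fold), 8)

  # identity table: equal body weights, all fractions 1
  flat <- data.frame(life_stage = c("young", "adult"), body_weight = c(1, 1),
                     hepatic_fraction_of_adult = c(1, 1),
                     gut_fraction_of_adult = c(1, 1),
                     mrp2_fraction_of_adult = c(1, 1))
  expect_equal(fold_difference_report(flat)$fold, c(1, 1))

  no_adult <- flat[flat$life_stage != "adult", ]
  expect_error(fold_difference_report(no_adult), "adult")
})
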