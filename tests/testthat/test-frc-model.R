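# The reference FRC metabolism network: structure, conditions, steady
# states, and the proton-mediation counterfactual.

frc <- frc_reference_model()

settled <- function(condition, clamp = NULL) {
  cond <- frc_condition(condition)
  settle_state(frc, frc_baseline_state(frc, cond),
               clamp = c(cond$clamps, clamp))
}

test_that("the reference model validates and carries the annotated ranges", {
  expect_length(validate_qn_model(frc), 0)
  expect_equal(c(frc$nodes$OCR$range_lo, frc$nodes$OCR$range_hi), c(0, 10))
  expect_equal(c(frc$nodes$Counter$range_lo, frc$nodes$Counter$range_hi),
               c(0, 100))
  for (drug in c("Oligomycin", "FCCP", "RotAA")) {
    expect_equal(c(frc$nodes[[drug]]$range_lo, frc$nodes[[drug]]$range_hi),
                 c(0, 1))
  }
  # all remaining nodes sit on the default 0-4 scale
  others <- setdiff(node_names(frc), c("OCR", "Counter", "Oligomycin",
                                       "FCCP", "RotAA"))
  for (nm in others) {
    expect_equal(c(frc$nodes[[nm]]$range_lo, frc$nodes[[nm]]$range_hi), c(0, 4))
  }
})

test_that("conditions clamp only environment nodes, at documented levels", {
  expect_equal(frc_condition("control")$clamps,
               c(Ext_Lactate = 2L, Ext_Protons = 2L))
  expect_equal(frc_condition("lactic_acid")$clamps,
               c(Ext_Lactate = 4L, Ext_Protons = 4L))
  expect_equal(frc_condition("sodium_lactate")$clamps,
               c(Ext_Lactate = 4L, Ext_Protons = 2L))
  expect_equal(frc_condition("protons_only")$clamps,
               c(Ext_Lactate = 2L, Ext_Protons = 4L))
  for (cn in c("control", "lactic_acid", "sodium_lactate", "protons_only")) {
    clamped <- names(frc_condition(cn)$clamps)
    expect_true(all(vapply(clamped, function(nm)
      sum(frc$edges$to == nm) == 0L, logical(1))))  # no incoming edges
  }
  expect_error(frc_condition("coffee"), "valid conditions")
})

test_that("the control baseline settles to a unique fixed point", {
  s <- settled("control")
  expect_true(is_fixed_point(frc, s, clamp = c(Counter = 0L)))
  expect_equal(unname(s["OCR"]), 5)
  expect_equal(unname(s["H_in"]), 2)
  # normal level 2 across the metabolic core
  for (nm in c("Glycolysis", "Pyruvate", "AcetylCoA", "TCA_flux", "NADH",
               "ETC", "ProtonGradient", "ATP_Synthase", "Acetylcarnitine")) {
    expect_equal(unname(s[nm]), 2, info = nm)
  }
})

test_that("settled basal OCR orders the conditions as the model predicts", {
  ocr <- vapply(c(control = "control", lactic_acid = "lactic_acid",
                  sodium_lactate = "sodium_lactate",
                  protons_only = "protons_only"),
                function(cn) unname(settled(cn)["OCR"]), integer(1))
  expect_lt(ocr[["lactic_acid"]], ocr[["control"]])
  expect_lt(ocr[["protons_only"]], ocr[["control"]])
  expect_identical(ocr[["sodium_lactate"]], ocr[["control"]])
})

test_that("acidification is the mediator: H_in rises only under acid load", {
  expect_gt(unname(settled("lactic_acid")["H_in"]), 2)
  expect_gt(unname(settled("protons_only")["H_in"]), 2)
  expect_equal(unname(settled("sodium_lactate")["H_in"]), 2)
})

test_that("clamping H_in to normal under lactic acid restores control OCR", {
  control_ocr <- unname(settled("control")["OCR"])
  counterfactual <- settled("lactic_acid", clamp = c(H_in = 2L))
  expect_equal(unname(counterfactual["OCR"]), control_ocr)
})

test_that("acetylcarnitine accumulates under lactate load, not control", {
  expect_gt(unname(settled("lactic_acid")["Acetylcarnitine"]), 2)
  expect_gt(unname(settled("sodium_lactate")["Acetylcarnitine"]), 2)
  expect_equal(unname(settled("control")["Acetylcarnitine"]), 2)
})
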