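# Stress-test driver and metrics: counter bookkeeping, drug scheduling,
# window arithmetic, and condition comparison.

frc <- frc_reference_model()

test_that("protocol construction validates ordering and bounds", {
  p <- stress_protocol()
  expect_equal(p$events$at, c(20L, 50L, 80L))
  expect_equal(p$duration, 100L)
  expect_error(stress_protocol(oligomycin = 50, fccp = 50),
               "strictly increasing")
  expect_error(stress_protocol(oligomycin = -1), "\\[0, duration\\]")
})

test_that("protocol files read as key/value text", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# injections", "oligomycin = 25", "fccp = 55",
               "rot_aa = 85", "lag = 4"), path)
  p <- read_protocol(path)
  expect_equal(p$events$at, c(25L, 55L, 85L))
  expect_equal(p$lag, 4L)
  writeLines("mystery = 3", path)
  expect_error(read_protocol(path), "unknown protocol key")
})

test_that("the counter advances by one per sample to the full duration", {
  tr <- run_stress_test(frc, "control")
  expect_equal(nrow(tr), 101)
  expect_equal(tr$counter, 0:100)
  expect_true(all(diff(tr$counter) == 1))
  expect_true(all(tr$OCR >= 0 & tr$OCR <= 10))
})

test_that("drugs are forced at their counters and held to run end", {
  tr <- run_stress_test(frc, "control", full_state = TRUE)
  expect_true(all(tr$Oligomycin[tr$counter < 20] == 0))
  expect_true(all(tr$Oligomycin[tr$counter >= 20] == 1))
  expect_true(all(tr$FCCP[tr$counter >= 50] == 1))
  expect_true(all(tr$RotAA[tr$counter >= 80] == 1))
})

test_that("the control trace has the canonical four-phase shape", {
  tr <- run_stress_test(frc, "control")
  p <- attr(tr, "protocol")
  basal <- tr$OCR[tr$counter >= p$lag & tr$counter < 20]
  oligo <- tr$OCR[tr$counter >= 20 + p$lag & tr$counter < 50]
  fccp <- tr$OCR[tr$counter >= 50 & tr$counter < 80]
  tail_ <- tr$OCR[tr$counter >= 80 + p$lag]
  expect_true(all(diff(basal) == 0))            # flat basal
  expect_lt(mean(oligo), mean(basal))           # drop after oligomycin
  expect_gt(max(fccp), max(basal))              # rise above basal after FCCP
  expect_equal(min(tail_), min(tr$OCR))         # global minimum in the tail
  expect_lt(mean(tail_), mean(oligo))
})

test_that("a protocol with no injections keeps OCR at the settled basal", {
  p <- stress_protocol(oligomycin = NA, fccp = NA, rot_aa = NA)
  tr <- run_stress_test(frc, "control", p)
  expect_equal(nrow(tr), 101)
  expect_true(all(tr$OCR == tr$OCR[1]))
  m <- compute_metrics(tr, p)
  expect_equal(m$basal, tr$OCR[1])
  expect_equal(m$spare, 0)
  expect_equal(m$atp_linked, 0)
})

test_that("metrics recover a hand-built step trace exactly", {
  p <- stress_protocol()
  tr <- make_synthetic_trace(c(4, 2, 8, 0), noise_sd = 0, protocol = p)
  m <- compute_metrics(tr, p)
  expect_equal(m$basal, 4)
  expect_equal(m$atp_linked, 2)
  expect_equal(m$maximal, 8)
  expect_equal(m$spare, 4)
  expect_equal(m$non_mito, 0)
})

test_that("spare capacity is exactly maximal minus basal", {
  for (cn in c("control", "lactic_acid")) {
    m <- compute_metrics(run_stress_test(frc, cn))
    expect_identical(m$spare, m$maximal - m$basal)
    expect_gte(m$non_mito, 0)
  }
})

test_that("windows that collapse to nothing raise an error", {
  p <- stress_protocol(oligomycin = 20, fccp = 21, rot_aa = 80)
  tr <- run_stress_test(frc, "control", p)
  expect_error(compute_metrics(tr, p), "empty measurement window")
})

test_that("condition comparison reports deltas and the three verdicts", {
  cmp <- compare_conditions(frc)
  expect_setequal(cmp$condition,
                  c("control", "lactic_acid", "sodium_lactate", "protons_only"))
  v <- attr(cmp, "verdicts")
  expect_true(v[["LA_lowers_basal"]])
  expect_true(v[["protons_lower_basal"]])
  expect_true(v[["sodium_lactate_neutral"]])
  expect_equal(cmp$delta_basal[cmp$condition == "control"], 0)
  expect_lt(cmp$delta_basal[cmp$condition == "lactic_acid"], 0)
  expect_equal(cmp$delta_basal[cmp$condition == "sodium_lactate"], 0)
  expect_error(compare_conditions(frc, c("lactic_acid", "protons_only")),
               "'control'")
})

test_that("shifting all injections by +5 leaves the verdicts unchanged", {
  shifted <- stress_protocol(oligomycin = 25, fccp = 55, rot_aa = 85)
  v0 <- attr(compare_conditions(frc), "verdicts")
  v5 <- attr(compare_conditions(frc, protocol = shifted), "verdicts")
  expect_identical(v0, v5)
})

test_that("stress tests are deterministic end to end", {
  t1 <- run_stress_test(frc, "lactic_acid", full_state = TRUE)
  t2 <- run_stress_test(frc, "lactic_acid", full_state = TRUE)
  expect_identical(t1, t2)
})

test_that("missing required nodes are reported by name", {
  m <- qn_model(list(qn_node("OCR", c(0, 10), "2")))
  expect_error(run_stress_test(m, "control"), "Counter")
})
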