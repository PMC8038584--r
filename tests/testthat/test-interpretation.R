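test_that("a fully normal panel returns correct results in all four approaches", {
  rep <- abg_interpret(panel(7.4, 40, 24, sbe = 0, ag = 11, alb = 40))
  expect_length(rep$results, 4L)
  for (r in rep$results) expect_identical(canonical_label_set(r),
                                          "correct results")
  expect_equal(rep$compliance_pct, 100)
})

test_that("inadequate CO2 retention in metabolic alkalosis adds definite respiratory alkalosis", {
  # bicarbonate 51 expects PaCO2 56.9-60.9; measured 45 is > 5% below
  rep <- abg_interpret(panel(7.6, 45, 51, ag = 14))
  expect_length(rep$results, 2L)
  for (r in rep$results) {
    expect_labels(r, c("metabolic_alkalosis", "respiratory_alkalosis"))
  }
  expect_equal(rep$compliance_pct, 100)
  expect_identical(sort(names(rep$skipped)),
                   c("chemical_agc", "physiological_agc"))
})

test_that("an elevated gap below the escalation thresholds is tolerated when metabolic alkalosis explains it", {
  rep <- abg_interpret(panel(7.6, 45, 51, ag = 14))
  for (r in rep$results) expect_false("hagma" %in% r$labels$kind)

  # at or above 30 mEq/L the high-gap acidosis is asserted regardless
  rep <- abg_interpret(panel(7.6, 45, 51, ag = 31))
  for (r in rep$results) expect_true("hagma" %in% r$labels$kind)
})

test_that("the albumin correction can flip a normal-gap call to high-gap with a suspected third disorder", {
  rep <- abg_interpret(panel(7.06, 28, 8, ag = 10, alb = 23))
  expect_length(rep$results, 4L)
  expect_labels(rep$results$physiological,
                c("nagma", "respiratory_acidosis"))
  expect_labels(rep$results$chemical,
                c("nagma", "respiratory_acidosis"))
  expect_labels(rep$results$physiological_agc,
                c("hagma", "respiratory_acidosis", "nagma|none|probable"))
  expect_labels(rep$results$chemical_agc,
                c("hagma", "respiratory_acidosis", "nagma|none|probable"))
  expect_equal(rep$compliance_pct, 50)
  expect_equal(rep$results$physiological_agc$evidence$ag_used, 14.25)
})

test_that("normal pH with both components deranged reports a mixed disorder without chronicity", {
  rep <- abg_interpret(panel(7.42, 59, 36, ag = 7))
  for (r in rep$results) {
    expect_labels(r, c("respiratory_acidosis", "metabolic_alkalosis"))
    expect_true(all(r$labels$chronicity == "none"))
  }
})

test_that("chronicity is recovered from the compensation zones of respiratory primaries", {
  # marker exactly at the acute expectation
  rep <- abg_interpret(panel(7.522, 27, 21.4, sbe = -1.11, ag = 11, alb = 43))
  expect_labels(rep$results$physiological, "respiratory_alkalosis|acute")

  # marker beyond the chronic expectation: chronic plus the metabolic
  # disorder in the adaptation direction
  rep <- abg_interpret(panel(7.47, 23, 16, ag = 44))
  expect_labels(rep$results$physiological,
                c("respiratory_alkalosis|chronic", "hagma",
                  "metabolic_alkalosis"))

  # marker short of the acute expectation: no chronicity, opposing
  # metabolic disorder added
  rep <- abg_interpret(panel(7.042, 82, 21, sbe = -8.09, ag = 8, alb = 39))
  expect_labels(rep$results$physiological,
                c("respiratory_acidosis", "nagma"))
})

test_that("a rejected panel yields findings and no interpretation", {
  rep <- abg_interpret(panel(7.438, 38, 18, sbe = -5.42, ag = 17, alb = 46))
  expect_true(any(rep$validation$severity == "reject"))
  expect_length(rep$results, 0L)
  expect_true(is.na(rep$compliance_pct))
})

test_that("identical panels always produce identical reports", {
  p <- panel(7.36, 22, 11, ag = 25)
  r1 <- abg_interpret(p)
  r2 <- abg_interpret(p)
  expect_identical(write_abg_report(r1, "json"), write_abg_report(r2, "json"))
})

test_that("compliance is the largest agreeing fraction and lives on the allowed grid", {
  for (s in c(11, 23, 47)) {
    cs <- abg_synthesize("metabolic_acidosis", adequacy = "in_band",
                         ag_profile = "masked", seed = s)
    rep <- abg_interpret(cs$panel)
    expect_true(rep$compliance_pct %in% c(25, 50, 75, 100))
  }
  # the corrected approaches disagree with the plain ones on a masked
  # gap, so full agreement is impossible
  cs <- abg_synthesize("metabolic_acidosis", adequacy = "in_band",
                       ag_profile = "masked", seed = 5)
  rep <- abg_interpret(cs$panel)
  expect_lte(rep$compliance_pct, 50)
  expect_false(identical(label_key(rep$results$physiological),
                         label_key(rep$results$physiological_agc)))
})

test_that("the corrected-gap approach demands albumin", {
  expect_error(classify_approach(panel(7.4, 40, 24, ag = 11),
                                 "physiological_agc"),
               "albumin")
})
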