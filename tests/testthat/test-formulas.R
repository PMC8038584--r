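test_that("Henderson-Hasselbalch pH reproduces hand-evaluated values and rejects bad input", {
  expect_equal(hh_ph(40, 24), 7.401, tolerance = 1e-3)
  expect_equal(hh_ph(20, 12.5), 7.4188, tolerance = 1e-4)
  expect_equal(hh_ph(38, 18), 6.1 + log10(18 / 1.14), tolerance = 1e-12)
  expect_error(hh_ph(0, 24), "positive")
  expect_error(hh_ph(40, -1), "positive")
})

test_that("Henderson-Hasselbalch pH is monotone in both arguments", {
  paco2 <- seq(15, 80, by = 5)
  hco3 <- seq(5, 40, by = 2.5)
  for (h in hco3) {
    expect_true(all(diff(hh_ph(paco2, h)) < 0))
  }
  for (p in paco2) {
    expect_true(all(diff(hh_ph(p, hco3)) > 0))
  }
})

test_that("van Slyke base excess matches its published evaluations and zero point", {
  expect_equal(van_slyke_sbe(7.6, 51), 27.458, tolerance = 5e-4)
  expect_equal(van_slyke_sbe(7.4, 24.4), 0)
  expect_equal(van_slyke_sbe(7.419, 12.5), -10.79, tolerance = 0.01)
})

test_that("anion gap is the potassium-free electrolyte difference", {
  expect_equal(anion_gap(145, 100, 24), 21)
  expect_equal(anion_gap(140, 105, 24), 11)
  expect_equal(anion_gap(0, 0, 0), 0)
})

test_that("albumin correction is linear with slope -0.25 and identity at normal albumin", {
  expect_equal(corrected_anion_gap(10, 23), 14.25)
  expect_equal(corrected_anion_gap(10.5, 28), 13.5)
  ag <- 8.7
  for (alb in seq(5, 70, by = 5)) {
    expect_equal(corrected_anion_gap(ag, alb), ag + 0.25 * (40 - alb))
  }
  expect_equal(corrected_anion_gap(13, 40), 13)
  expect_error(corrected_anion_gap(10, NA), "albumin")
})

test_that("delta ratio value, band edges and degenerate cases behave as specified", {
  r <- delta_ratio(14.25, 8)
  expect_equal(r$value, 7.25 / 16)
  expect_identical(r$band, "below_0p8")

  # bicarbonate at baseline with an elevated gap: infinite ratio
  r <- delta_ratio(19, 24)
  expect_identical(r$value, Inf)
  expect_identical(r$band, "above_2")

  # both edges of the neutral band are inside it; 2.0 belongs to the
  # upper intermediate band
  expect_identical(delta_ratio(7 + 0.8 * 10, 14)$band, "b0p8_1p2")
  expect_identical(delta_ratio(7 + 1.2 * 10, 14)$band, "b0p8_1p2")
  expect_identical(delta_ratio(43, 6)$band, "b1p2_2")
  expect_equal(delta_ratio(43, 6)$value, 2)

  # gap at baseline and bicarbonate above it: nothing to compare
  expect_identical(delta_ratio(6, 25)$band, "not_applicable")
})

test_that("compensation expectations reproduce the published rule evaluations", {
  ranges <- abg_ranges()

  # metabolic alkalosis, bicarbonate 51: expected PaCO2 56.9-60.9
  p <- panel(7.6, 45, 51, ag = 14)
  e <- expected_compensation("metabolic_alkalosis", p, "physiological",
                             ranges = ranges)
  expect_equal(e$center - e$band_halfwidth, 56.9)
  expect_equal(e$center + e$band_halfwidth, 60.9)
  expect_identical(e$target, "paco2")

  # chemical variant via the van Slyke estimate: point estimate 56.475
  e <- expected_compensation("metabolic_alkalosis", p, "chemical",
                             sbe = van_slyke_sbe(7.6, 51), ranges = ranges)
  expect_equal(e$center, 56.475, tolerance = 5e-4)
  expect_equal(e$band_halfwidth, 0)

  # metabolic alkalosis at baseline bicarbonate: fixed point 40
  e <- expected_compensation("metabolic_alkalosis",
                             panel(7.4, 40, 24, ag = 8),
                             "physiological", ranges = ranges)
  expect_equal(e$center, 40)

  # acute respiratory alkalosis at PaCO2 27: expected HCO3- 21.4
  e <- expected_compensation("respiratory_alkalosis",
                             panel(7.522, 27, 21.4, ag = 11),
                             "physiological", chronicity = "acute",
                             ranges = ranges)
  expect_equal(e$center, 21.4)

  # Winter-type rule for metabolic acidosis
  e <- expected_compensation("metabolic_acidosis",
                             panel(7.06, 28, 8, ag = 10),
                             "physiological", ranges = ranges)
  expect_equal(e$center, 20)
  expect_equal(e$band_halfwidth, 2)

  expect_error(expected_compensation("unknown_kind", p, "physiological"),
               "unknown")
  expect_error(expected_compensation("metabolic_acidosis", p, "chemical"),
               "SBE")
})
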