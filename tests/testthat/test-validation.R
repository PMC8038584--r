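test_that("missing required values reject and missing albumin only informs", {
  f <- check_required(list(ph = 7.4, paco2 = 40, hco3 = NA, ag = 12))
  expect_true(any(f$severity == "reject" & f$code == "missing_hco3"))

  f <- check_required(list(ph = 7.4, paco2 = 40, hco3 = 24,
                           ag = NA, sodium = NA, chloride = 100))
  expect_true(any(f$code == "missing_ag" & f$severity == "reject"))

  f <- check_required(panel(7.4, 40, 24, ag = 11))
  expect_identical(f$severity, "info")
  expect_identical(f$code, "albumin_absent")

  f <- check_required(panel(7.4, 40, 24, ag = 11, alb = 40))
  expect_identical(nrow(f), 0L)
})

test_that("plausibility screening warns on extreme values and never rejects", {
  f <- check_plausibility(panel(9.2, 40, 24, ag = 11))
  expect_true(all(f$severity == "warning"))
  expect_true("extreme_ph" %in% f$code)

  f <- check_plausibility(panel(7.2, 5, 18, ag = 11))
  expect_true("extreme_paco2" %in% f$code)
  expect_false(any(f$severity == "reject"))

  expect_identical(nrow(check_plausibility(panel(7.4, 40, 24, ag = 11))), 0L)
})

test_that("consistency screening grades the pH discrepancy into none/warning/reject", {
  expect_identical(nrow(check_hh_consistency(panel(7.40, 40, 24, ag = 11))), 0L)
  expect_identical(nrow(check_hh_consistency(panel(7.419, 20, 12.5, ag = 18.5))), 0L)

  f <- check_hh_consistency(panel(7.36, 22, 11, ag = 25))  # d ~ 0.038
  expect_identical(f$severity, "warning")

  f <- check_hh_consistency(panel(7.438, 38, 18, ag = 17))  # d ~ 0.140
  expect_identical(f$severity, "reject")
  expect_match(f$message, "incorrect data")
})

test_that("consistency severity is monotone in the discrepancy and always single-valued", {
  base_ph <- hh_ph(40, 24)
  sev_rank <- function(off) {
    f <- check_hh_consistency(panel(base_ph + off, 40, 24, ag = 8))
    if (nrow(f) == 0L) 0L else match(f$severity, c("warning", "reject"))
  }
  offsets <- c(0, 0.005, 0.019, 0.021, 0.05, 0.099, 0.101, 0.2, 0.5)
  ranks <- vapply(offsets, sev_rank, integer(1))
  expect_true(all(diff(ranks) >= 0))
  # negative offsets are graded identically
  expect_identical(ranks, vapply(-offsets, sev_rank, integer(1)))
})

test_that("supplied base excess disagreement is informational only", {
  p <- panel(7.4, 40, 24, sbe = 8, ag = 11)  # van Slyke estimate ~ -0.37
  f <- validate_panel(p)
  expect_true("sbe_disagreement" %in% f$code)
  expect_identical(f$severity[f$code == "sbe_disagreement"], "info")
  expect_false(any(f$severity %in% c("warning", "reject")))
})
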