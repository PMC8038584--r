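test_that("generation is deterministic in the seed and leaves the RNG state alone", {
  a <- abg_synthesize("metabolic_alkalosis", adequacy = "in_band", seed = 7)
  b <- abg_synthesize("metabolic_alkalosis", adequacy = "in_band", seed = 7)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)

  set.seed(123)
  before <- stats::runif(5)
  set.seed(123)
  invisible(abg_synthesize("respiratory_acidosis", seed = 42))
  after <- stats::runif(5)
  expect_identical(before, after)
})

test_that("generated panels are Henderson-Hasselbalch consistent unless an inconsistency is injected", {
  for (s in 1:25) {
    cs <- abg_synthesize("metabolic_acidosis", adequacy = "in_band", seed = s)
    expect_lt(abs(cs$panel$ph - hh_ph(cs$panel$paco2, cs$panel$hco3)), 1e-9)
    f <- validate_panel(cs$panel)
    expect_false(any(f$severity %in% c("warning", "reject")))
  }
  cs <- abg_synthesize("none", inconsistency = 0.15, seed = 3)
  expect_identical(cs$truth$validation, "reject")
  rep <- abg_interpret(cs$panel)
  expect_true(any(rep$validation$severity == "reject"))
  expect_length(rep$results, 0L)

  cs <- abg_synthesize("none", inconsistency = 0.05, seed = 3)
  expect_identical(cs$truth$validation, "warning")
  expect_true(any(validate_panel(cs$panel)$severity == "warning"))
})

test_that("unsatisfiable construction requests raise generation errors", {
  expect_error(abg_synthesize("respiratory_acidosis", adequacy = "probable"),
               "unsatisfiable")
  expect_error(abg_synthesize("none", adequacy = "definite"),
               "unsatisfiable")
  expect_error(abg_synthesize("respiratory_alkalosis", ag_profile = "masked"),
               "unsatisfiable")
})

test_that("the masked-gap scenario hides a high gap behind low albumin", {
  for (s in c(2, 9, 31)) {
    cs <- abg_synthesize("metabolic_acidosis", adequacy = "in_band",
                         ag_profile = "masked", seed = s)
    expect_lte(cs$panel$ag, 11)
    expect_lt(cs$panel$albumin, 35)
    agc <- corrected_anion_gap(cs$panel$ag, cs$panel$albumin)
    expect_gt(agc, 11)
    expect_true("nagma" %in% cs$truth$labels$kind)
    expect_true("hagma" %in% cs$truth$labels_agc$kind)
  }
})

test_that("the classifier recovers construction labels across the scenario grid", {
  specs <- synthetic_spec_grid()
  n_bad <- 0L
  for (si in seq_along(specs)) {
    for (seed in 1:6) {
      cs <- do.call(abg_synthesize,
                    c(specs[[si]], list(seed = 10000L + si * 100L + seed)))
      rep <- abg_interpret(cs$panel)
      if (!identical(label_key(cs$truth$labels),
                     label_key(rep$results$physiological)) ||
          !identical(label_key(cs$truth$labels_agc),
                     label_key(rep$results$physiological_agc))) {
        n_bad <- n_bad + 1L
      }
    }
  }
  expect_identical(n_bad, 0L)
})
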