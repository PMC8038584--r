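test_that("label rendering is canonical, pure and insensitive to emission order", {
  a <- bloodgas:::make_label("hagma")
  b <- bloodgas:::make_label("metabolic_alkalosis")
  c_ <- bloodgas:::make_label("respiratory_alkalosis", chronicity = "chronic")

  perm1 <- rbind(a, b, c_)
  perm2 <- rbind(c_, a, b)
  perm3 <- rbind(b, c_, a)
  r1 <- canonical_label_set(perm1)
  expect_identical(r1, canonical_label_set(perm2))
  expect_identical(r1, canonical_label_set(perm3))
  # repeated calls are byte-identical
  expect_identical(r1, canonical_label_set(perm1))
  expect_identical(r1, c("chronic respiratory alkalosis",
                         "high anion gap metabolic acidosis",
                         "metabolic alkalosis"))
})

test_that("the empty label set renders as correct results", {
  expect_identical(canonical_label_set(bloodgas:::empty_labels()),
                   "correct results")
  expect_identical(bloodgas:::render_result_sentence(bloodgas:::empty_labels()),
                   "correct results")
})

test_that("borderline labels carry the confidence phrasing by disorder axis", {
  labels <- rbind(
    bloodgas:::make_label("hagma"),
    bloodgas:::make_label("nagma", certainty = "probable"),
    bloodgas:::make_label("respiratory_acidosis", certainty = "probable"))
  rendered <- canonical_label_set(labels)
  expect_true("possible additional normal anion gap metabolic acidosis"
              %in% rendered)
  expect_true("probably with respiratory acidosis" %in% rendered)
  # definite labels precede probable ones
  expect_identical(rendered[1], "high anion gap metabolic acidosis")
})

test_that("adding a duplicate kind keeps one entry and upgrades certainty", {
  l <- bloodgas:::make_label("metabolic_alkalosis", certainty = "probable")
  l <- bloodgas:::add_label(l, bloodgas:::make_label("metabolic_alkalosis"))
  expect_identical(nrow(l), 1L)
  expect_identical(l$certainty, "definite")
  # a probable duplicate never downgrades a definite label
  l <- bloodgas:::add_label(
    l, bloodgas:::make_label("metabolic_alkalosis", certainty = "probable"))
  expect_identical(l$certainty, "definite")
})

test_that("chronicity is restricted to respiratory kinds", {
  expect_error(bloodgas:::make_label("metabolic_alkalosis",
                                     chronicity = "acute"),
               "respiratory")
  expect_silent(bloodgas:::make_label("respiratory_acidosis",
                                      chronicity = "chronic"))
})
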