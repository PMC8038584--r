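test_that("the packaged case files are intact", {
  csv <- system.file("extdata", "printed_cases.csv", package = "bloodgas")
  js <- system.file("extdata", "printed_expectations.json",
                    package = "bloodgas")
  expect_identical(unname(tools::md5sum(csv)),
                   "b3a4e68211c909d3b161ae61ee2b6ddd")
  expect_identical(unname(tools::md5sum(js)),
                   "df3da443f44fc98c57985d8d04a177ca")
})

test_that("every packaged record builds a valid panel and every expectation is well-formed", {
  pc <- abg_printed_cases()
  expect_identical(nrow(pc$records), 25L)
  expect_setequal(pc$records$case_id, names(pc$expectations))
  approaches <- c("physiological", "physiological_agc", "chemical",
                  "chemical_agc")
  for (i in seq_len(nrow(pc$records))) {
    p <- panel_from_record(pc$records[i, , drop = FALSE])
    expect_s3_class(p, "abg_panel")
  }
  for (id in names(pc$expectations)) {
    e <- pc$expectations[[id]]
    expect_true(all(names(e$expected) %in% approaches))
    for (a in names(e$expected)) {
      # decoding validates kind/chronicity/certainty vocabulary
      expect_s3_class(parse_label_strings(unlist(e$expected[[a]])),
                      "data.frame")
    }
  }
})

test_that("the two application-comparison panels derive their gaps from electrolytes", {
  pc <- abg_printed_cases()
  hag <- panel_from_record(pc$records[pc$records$case_id == "d42_hagma", ])
  nrm <- panel_from_record(pc$records[pc$records$case_id == "d42_normal", ])
  expect_equal(hag$ag, 21)
  expect_equal(nrm$ag, 11)
  expect_true(hag$ag_derived && nrm$ag_derived)
})
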