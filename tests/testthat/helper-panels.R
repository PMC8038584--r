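# shared helpers: quick panel construction and label-set comparison

panel <- function(ph, paco2, hco3, sbe = NA, ag = NA, na = NA, cl = NA,
                  alb = NA) {
  abg_panel(ph = ph, paco2 = paco2, hco3 = hco3, sbe = sbe, ag = ag,
            sodium = na, chloride = cl, albumin = alb)
}

label_key <- function(x) paste(canonical_label_set(x), collapse = " | ")

# compare an approach result against expected "kind|chronicity|certainty"
# strings as sets (canonical rendering of both sides)
expect_labels <- function(result, strings) {
  expect_identical(label_key(result),
                   label_key(parse_label_strings(strings)))
}

synthetic_spec_grid <- function() {
  list(
    list(primary = "none"),
    list(primary = "none", ag_profile = "elevated"),
    list(primary = "metabolic_acidosis", adequacy = "in_band"),
    list(primary = "metabolic_acidosis", adequacy = "in_band",
         ag_profile = "elevated"),
    list(primary = "metabolic_acidosis", adequacy = "definite", side = "high"),
    list(primary = "metabolic_acidosis", adequacy = "definite", side = "low"),
    list(primary = "metabolic_acidosis", adequacy = "in_band",
         ag_profile = "masked"),
    list(primary = "metabolic_alkalosis", adequacy = "in_band"),
    list(primary = "metabolic_alkalosis", adequacy = "definite", side = "low"),
    list(primary = "metabolic_alkalosis", adequacy = "definite", side = "high"),
    list(primary = "respiratory_acidosis", chronicity = "acute"),
    list(primary = "respiratory_acidosis", chronicity = "chronic"),
    list(primary = "respiratory_acidosis", adequacy = "definite",
         side = "beyond_chronic"),
    list(primary = "respiratory_acidosis", adequacy = "definite",
         side = "short_of_acute"),
    list(primary = "respiratory_alkalosis", chronicity = "acute"),
    list(primary = "respiratory_alkalosis", chronicity = "chronic"),
    list(primary = "respiratory_alkalosis", adequacy = "definite",
         side = "beyond_chronic"),
    list(primary = "respiratory_alkalosis", adequacy = "definite",
         side = "short_of_acute")
  )
}
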