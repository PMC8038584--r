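.approaches <- c("physiological", "physiological_agc",
                 "chemical", "chemical_agc")

.approach_title <- c(
  physiological = "physiological approach",
  physiological_agc = "physiological approach with AGc",
  chemical = "chemical approach",
  chemical_agc = "chemical approach with AGc"
)

range_status <- function(x, lo, hi) {
  if (x < lo) "low" else if (x > hi) "high" else "normal"
}

# Zone of a measured value relative to a compensation expectation:
# "in_band", "probable_low"/"probable_high" (beyond an edge by at most
# the fractional margin, measured relative to the edge value), or
# "low"/"high". Returns the zone plus the deviation fraction.
compensation_zone <- function(measured, expectation, margin) {
  lo <- expectation$center - expectation$band_halfwidth
  hi <- expectation$center + expectation$band_halfwidth
  if (measured >= lo && measured <= hi) {
    return(list(zone = "in_band", deviation = 0, edge = NA_real_))
  }
  if (measured > hi) {
    dev <- if (hi == 0) Inf else (measured - hi) / abs(hi)
    zone <- if (dev <= margin) "probable_high" else "high"
    list(zone = zone, deviation = dev, edge = hi)
  } else {
    dev <- if (lo == 0) Inf else (lo - measured) / abs(lo)
    zone <- if (dev <= margin) "probable_low" else "low"
    list(zone = zone, deviation = dev, edge = lo)
  }
}

# Secondary-response evaluation for a single primary disorder.
# For metabolic primaries: judges the measured PaCO2 against the
# expected compensation; a value beyond the band adds the respiratory
# disorder implied by the deviation direction, "probable" within the
# 5% borderline zone and definite beyond it.
# For respiratory primaries: places the metabolic marker against the
# acute and chronic expectations (each widened by the 5% margin);
# within the acute zone -> acute, within the chronic zone -> chronic,
# beyond chronic in the adaptation direction -> chronic plus an
# additional metabolic disorder in that direction, short of the acute
# zone on the baseline side -> no chronicity plus the opposing
# metabolic disorder, and between the zones -> indeterminate.
evaluate_secondary <- function(primary, panel, base_approach, marker_value,
                               sbe_used, ranges) {
  margin <- ranges$probable_margin
  labels <- empty_labels()
  notes <- character(0)
  evidence <- list()
  chronicity <- "none"

  if (primary %in% c("metabolic_acidosis", "metabolic_alkalosis")) {
    e <- expected_compensation(primary, panel, base_approach,
                               sbe = sbe_used, ranges = ranges)
    z <- compensation_zone(panel$paco2, e, margin)
    evidence$expected_paco2_center <- e$center
    evidence$expected_paco2_lo <- e$center - e$band_halfwidth
    evidence$expected_paco2_hi <- e$center + e$band_halfwidth
    evidence$paco2_deviation_fraction <- z$deviation
    if (z$zone != "in_band") {
      kind <- if (z$zone %in% c("high", "probable_high")) {
        e$direction_if_high
      } else {
        e$direction_if_low
      }
      certainty <- if (startsWith(z$zone, "probable")) "probable" else "definite"
      labels <- add_label(labels, make_label(kind, certainty = certainty))
    }
  } else {
    ea <- expected_compensation(primary, panel, base_approach,
                                chronicity = "acute", ranges = ranges)
    ec <- expected_compensation(primary, panel, base_approach,
                                chronicity = "chronic", ranges = ranges)
    za <- compensation_zone(marker_value, ea, margin)
    zc <- compensation_zone(marker_value, ec, margin)
    evidence$expected_marker_acute <- ea$center
    evidence$expected_marker_chronic <- ec$center
    evidence$marker_measured <- marker_value
    adapt_up <- ec$center >= ea$center  # chronic adaptation raises the marker
    if (za$zone %in% c("in_band", "probable_low", "probable_high")) {
      chronicity <- "acute"
    } else if (zc$zone %in% c("in_band", "probable_low", "probable_high")) {
      chronicity <- "chronic"
    } else if (adapt_up && zc$zone == "high") {
      chronicity <- "chronic"
      labels <- add_label(labels, make_label(ec$direction_if_high))
    } else if (!adapt_up && zc$zone == "low") {
      chronicity <- "chronic"
      labels <- add_label(labels, make_label(ec$direction_if_low))
    } else if (adapt_up && za$zone == "low") {
      labels <- add_label(labels, make_label(ea$direction_if_low))
    } else if (!adapt_up && za$zone == "high") {
      labels <- add_label(labels, make_label(ea$direction_if_high))
    } else {
      notes <- c(notes, "indeterminate chronicity: marker between acute and chronic expectations")
    }
  }
  list(labels = labels, chronicity = chronicity, notes = notes,
       evidence = evidence)
}

# Anion-gap logic, applied after the pH/component branching:
# (a) a detected metabolic acidosis becomes high- or normal-anion-gap
#     according to the gap in use;
# (b) an elevated gap with no metabolic component at all asserts an
#     occult high anion gap metabolic acidosis (an elevated gap in the
#     presence of, e.g., metabolic alkalosis is tolerated below the
#     escalation thresholds - such fluctuations accompany that
#     disorder);
# (c) gap >= 25 mEq/L adds a "consider an additional disorder" note;
#     gap >= 30 mEq/L asserts high anion gap metabolic acidosis
#     regardless of other findings;
# (d) whenever high anion gap metabolic acidosis is present, the delta
#     ratio (always on bicarbonate) screens for a coexisting normal
#     anion gap acidosis or metabolic alkalosis.
apply_ag_logic <- function(labels, panel, ag_used, ranges) {
  notes <- character(0)
  evidence <- list(ag_used = ag_used)

  i <- match("metabolic_acidosis", labels$kind)
  if (!is.na(i)) {
    labels$kind[i] <- if (ag_used > ranges$ag_hi) "hagma" else "nagma"
  } else if (ag_used > ranges$ag_hi &&
             !any(labels$kind %in% c("hagma", "nagma", "metabolic_alkalosis"))) {
    labels <- add_label(labels, make_label("hagma"))
    notes <- c(notes, sprintf(
      "elevated anion gap (%g mEq/L) without a detected metabolic component: occult high anion gap metabolic acidosis",
      ag_used))
  }
  if (ag_used >= ranges$ag_consider_threshold) {
    notes <- c(notes, sprintf(
      "anion gap %g mEq/L >= %g: consider the presence of an additional disorder",
      ag_used, ranges$ag_consider_threshold))
  }
  if (ag_used >= ranges$ag_certain_threshold) {
    labels <- add_label(labels, make_label("hagma"))
  }
  if ("hagma" %in% labels$kind) {
    dr <- delta_ratio(ag_used, panel$hco3, ranges)
    evidence$delta_ratio <- dr$value
    evidence$delta_ratio_band <- dr$band
    extra <- switch(dr$band,
      below_0p8 = make_label("nagma", certainty = "probable"),
      b0p8_1p2 = NULL,
      b1p2_2 = make_label("metabolic_alkalosis", certainty = "probable"),
      above_2 = make_label("metabolic_alkalosis"),
      not_applicable = NULL)
    if (!is.null(extra)) labels <- add_label(labels, extra)
    if (dr$band == "not_applicable") {
      notes <- c(notes, "delta ratio not applicable (gap and bicarbonate both at or beyond baseline)")
    }
  }
  list(labels = labels, notes = notes, evidence = evidence)
}

#' Classify a blood gas panel under one analysis approach
#'
#' Runs the rule engine for a single approach. The physiological
#' approaches use bicarbonate as the metabolic marker; the chemical
#' approaches use the standard base excess (supplied, or the van Slyke
#' estimate when absent). The `_agc` variants replace the anion gap
#' with its albumin-corrected value and require albumin.
#'
#' Decision procedure: (1) pH against its reference interval; (2)
#' component status of PaCO2 and the metabolic marker; (3) branch -
#' an abnormal pH with one explaining component yields a single primary
#' disorder whose secondary response is then checked; an abnormal pH
#' with both components deranged concordantly yields both disorders; a
#' normal pH with abnormal components yields every indicated disorder
#' (no disturbance is ever fully compensated, so an abnormal panel with
#' normal pH is a mixed disorder); a fully normal panel is screened on
#' the anion gap alone; (4) the anion-gap logic resolves metabolic
#' acidoses into high/normal gap, escalates at 25 and 30 mEq/L, and
#' applies the delta-ratio bands. An empty label set means "correct
#' results".
#'
#' @param panel An [abg_panel()]; it must already have passed
#'   validation (no reject finding).
#' @param approach One of `"physiological"`, `"physiological_agc"`,
#'   `"chemical"`, `"chemical_agc"`.
#' @param ranges An [abg_ranges()] object.
#' @return An object of class `abg_approach_result`: list with
#'   `approach`, `labels` (data.frame of kind/chronicity/certainty),
#'   `evidence` (named numeric intermediates such as `ag_used`,
#'   `delta_ratio`, expected compensation values) and `notes`.
#' @examples
#' p <- abg_panel(ph = 7.36, paco2 = 22, hco3 = 11, ag = 25)
#' classify_approach(p, "physiological")
#' @export
classify_approach <- function(panel, approach, ranges = abg_ranges()) {
  approach <- match.arg(approach, .approaches)
  chem <- grepl("^chemical", approach)
  agc <- grepl("_agc$", approach)
  base_approach <- if (chem) "chemical" else "physiological"

  sbe_used <- if (!is.na(panel$sbe)) panel$sbe else {
    van_slyke_sbe(panel$ph, panel$hco3)
  }
  if (agc && is.na(panel$albumin)) {
    stop("approach '", approach, "' requires albumin")
  }
  ag_used <- if (agc) {
    corrected_anion_gap(panel$ag, panel$albumin, ranges$alb_normal,
                        ranges$comp$agc_slope)
  } else {
    panel$ag
  }

  if (chem) {
    marker_value <- sbe_used
    marker_lo <- ranges$sbe_lo; marker_hi <- ranges$sbe_hi
    marker_baseline <- 0
  } else {
    marker_value <- panel$hco3
    marker_lo <- ranges$hco3_lo; marker_hi <- ranges$hco3_hi
    marker_baseline <- ranges$hco3_baseline
  }

  ph_st <- range_status(panel$ph, ranges$ph_lo, ranges$ph_hi)
  pc_st <- range_status(panel$paco2, ranges$paco2_lo, ranges$paco2_hi)
  mk_st <- range_status(marker_value, marker_lo, marker_hi)

  labels <- empty_labels()
  notes <- character(0)
  evidence <- list(sbe_used = sbe_used)

  resp_kind <- function(st) if (st == "high") "respiratory_acidosis" else "respiratory_alkalosis"
  met_kind <- function(st) if (st == "high") "metabolic_alkalosis" else "metabolic_acidosis"

  if (ph_st != "normal") {
    resp_explains <- (ph_st == "low" && pc_st == "high") ||
      (ph_st == "high" && pc_st == "low")
    met_explains <- (ph_st == "low" && mk_st == "low") ||
      (ph_st == "high" && mk_st == "high")
    if (!resp_explains && !met_explains) {
      # components within range yet pH abnormal (a thin sliver that can
      # survive the consistency screen): fall back to baseline-relative
      # directions
      notes <- c(notes, "abnormal pH with both components inside their reference intervals; primary assigned from baseline deviations")
      resp_explains <- (ph_st == "low" && panel$paco2 > ranges$paco2_baseline) ||
        (ph_st == "high" && panel$paco2 < ranges$paco2_baseline)
      met_explains <- (ph_st == "low" && marker_value < marker_baseline) ||
        (ph_st == "high" && marker_value > marker_baseline)
    }
    if (resp_explains && met_explains) {
      # concordant double derangement: both primary, no adequacy check
      labels <- add_label(labels, make_label(
        if (ph_st == "low") "respiratory_acidosis" else "respiratory_alkalosis"))
      labels <- add_label(labels, make_label(
        if (ph_st == "low") "metabolic_acidosis" else "metabolic_alkalosis"))
    } else if (resp_explains || met_explains) {
      primary <- if (resp_explains) {
        if (ph_st == "low") "respiratory_acidosis" else "respiratory_alkalosis"
      } else {
        if (ph_st == "low") "metabolic_acidosis" else "metabolic_alkalosis"
      }
      sec <- evaluate_secondary(primary, panel, base_approach, marker_value,
                                sbe_used, ranges)
      labels <- add_label(labels, make_label(primary, chronicity = sec$chronicity))
      for (j in seq_len(nrow(sec$labels))) {
        labels <- add_label(labels, sec$labels[j, , drop = FALSE])
      }
      notes <- c(notes, sec$notes)
      evidence <- c(evidence, sec$evidence)
    }
  } else {
    # normal pH: every abnormal component is reported as its disorder;
    # no compensation adequacy or chronicity is assessed
    if (pc_st != "normal") labels <- add_label(labels, make_label(resp_kind(pc_st)))
    if (mk_st != "normal") labels <- add_label(labels, make_label(met_kind(mk_st)))
  }

  agl <- apply_ag_logic(labels, panel, ag_used, ranges)
  labels <- agl$labels
  notes <- c(notes, agl$notes)
  evidence <- c(evidence, agl$evidence)

  structure(list(approach = approach, labels = labels,
                 evidence = evidence, notes = notes),
            class = "abg_approach_result")
}

#' @export
print.abg_approach_result <- function(x, ...) {
  cat(.approach_title[[x$approach]], ":\n  ",
      render_result_sentence(x), "\n", sep = "")
  if (length(x$notes)) cat(paste0("  note: ", x$notes, "\n"), sep = "")
  invisible(x)
}

#' Interpret a blood gas panel by all available approaches
#'
#' Validates the panel, runs every approach the data permit (all four
#' when albumin is present, otherwise the two uncorrected ones), and
#' aggregates the per-approach label sets into a compliance
#' percentage: `100 * (size of the largest group of identical label
#' sets) / (number of approaches run)`. Identity is canonical label-set
#' equality (kind, chronicity and certainty), not prose order.
#'
#' A validation finding of severity `"reject"` (a missing required
#' value or a Henderson-Hasselbalch discrepancy above 0.1) suppresses
#' interpretation: the report then carries the findings and an empty
#' result list.
#'
#' @param panel An [abg_panel()].
#' @param ranges An [abg_ranges()] object.
#' @return An object of class `abg_report`: list with `panel`,
#'   `validation` (findings data.frame), `results` (named list of
#'   `abg_approach_result`), `skipped` (named character vector of
#'   reasons for approaches not run) and `compliance_pct` (`NA` when
#'   rejected).
#' @examples
#' report <- abg_interpret(abg_panel(7.06, 28, 8, ag = 10, albumin = 23))
#' report$compliance_pct  # 50: the corrected approaches disagree
#' @export
abg_interpret <- function(panel, ranges = abg_ranges()) {
  stopifnot(inherits(panel, "abg_panel"))
  validation <- validate_panel(panel, ranges)
  if (any(validation$severity == "reject")) {
    return(structure(list(panel = panel, validation = validation,
                          results = list(),
                          skipped = c(all = "panel rejected by validation"),
                          compliance_pct = NA_real_),
                     class = "abg_report"))
  }
  run <- c("physiological", "chemical")
  skipped <- character(0)
  if (!is.na(panel$albumin)) {
    run <- c("physiological", "physiological_agc", "chemical", "chemical_agc")
  } else {
    skipped <- c(
      physiological_agc = "albumin not entered - anion gap not corrected",
      chemical_agc = "albumin not entered - anion gap not corrected")
  }
  results <- lapply(run, function(a) classify_approach(panel, a, ranges))
  names(results) <- run
  keys <- vapply(results, label_set_key, character(1))
  compliance <- 100 * max(table(keys)) / length(keys)
  structure(list(panel = panel, validation = validation, results = results,
                 skipped = skipped, compliance_pct = compliance),
            class = "abg_report")
}

#' @export
print.abg_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
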