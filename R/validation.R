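# Pre-analysis screening. Findings are rows of a data.frame with
# columns code, severity (info/warning/reject), message, measured,
# computed. A reject finding suppresses all interpretation output.

finding <- function(code, severity, message,
                    measured = NA_real_, computed = NA_real_) {
  data.frame(code = code, severity = severity, message = message,
             measured = measured, computed = computed,
             stringsAsFactors = FALSE)
}

empty_findings <- function() {
  finding(character(0), character(0), character(0), numeric(0), numeric(0))
}

#' Check that a panel carries the values the interpreter needs
#'
#' pH, PaCO2, bicarbonate and an anion gap (direct or derivable from
#' Na/Cl) are mandatory; their absence is a rejection. A missing
#' albumin is only informational: the two corrected-anion-gap
#' approaches are skipped and interpretation proceeds with the other
#' two.
#'
#' @param panel An [abg_panel()] (whose constructor already enforces
#'   the hard requirements) or a plain named list, which allows this
#'   check to report what a malformed record lacks.
#' @return A data.frame of findings (possibly empty) with columns
#'   `code`, `severity`, `message`, `measured`, `computed`.
#' @examples
#' p <- abg_panel(ph = 7.4, paco2 = 40, hco3 = 24, ag = 11)
#' check_required(p)  # one info finding: albumin absent
#' @export
check_required <- function(panel) {
  out <- empty_findings()
  miss <- function(x) is.null(x) || length(x) == 0L || is.na(x)
  for (nm in c("ph", "paco2", "hco3")) {
    if (miss(panel[[nm]])) {
      out <- rbind(out, finding(
        paste0("missing_", nm), "reject",
        sprintf("required value '%s' is missing; analysis cannot start", nm)))
    }
  }
  if (miss(panel$ag) && (miss(panel$sodium) || miss(panel$chloride))) {
    out <- rbind(out, finding(
      "missing_ag", "reject",
      "anion gap is missing and cannot be derived (need 'ag' or both 'sodium' and 'chloride')"))
  }
  if (miss(panel$albumin)) {
    out <- rbind(out, finding(
      "albumin_absent", "info",
      "albumin absent - corrected anion gap approaches skipped (2 of 4 methods)"))
  }
  out
}

#' Screen a panel for physiologically implausible values
#'
#' Values outside generous survivable extremes point to transcription
#' or unit errors. Each breach yields a warning finding; plausibility
#' alone never rejects a panel. Default windows: pH 6.5-8.0, PaCO2
#' 10-150 mm Hg, HCO3- 1-60 mmol/L, SBE -35 to 35 mmol/L, AG -5 to 60
#' mEq/L, albumin 5-70 g/L (all configurable via [abg_ranges()]).
#'
#' @param panel An [abg_panel()].
#' @param ranges An [abg_ranges()] object carrying the `plaus` windows.
#' @return A data.frame of warning findings, empty when all present
#'   values are inside their windows.
#' @examples
#' p <- abg_panel(ph = 7.2, paco2 = 5, hco3 = 18, ag = 12)
#' check_plausibility(p)
#' @export
check_plausibility <- function(panel, ranges = abg_ranges()) {
  out <- empty_findings()
  fields <- c(ph = "ph", paco2 = "paco2", hco3 = "hco3", sbe = "sbe",
              ag = "ag", albumin = "albumin")
  for (nm in names(fields)) {
    v <- panel[[fields[[nm]]]]
    if (is.null(v) || is.na(v)) next
    w <- ranges$plaus[[nm]]
    if (v < w[1L] || v > w[2L]) {
      out <- rbind(out, finding(
        paste0("extreme_", nm), "warning",
        sprintf("extreme value: %s = %g outside plausible window [%g, %g]",
                nm, v, w[1L], w[2L]),
        measured = v))
    }
  }
  out
}

#' Henderson-Hasselbalch consistency of an entered panel
#'
#' Compares the entered pH with the pH recomputed from PaCO2 and
#' bicarbonate via [hh_ph()]. A discrepancy `d = |pH - pH_calc|` up to
#' 0.02 is accepted silently; `0.02 < d <= 0.1` warns that the result
#' may be incorrect; `d > 0.1` rejects the panel as incorrect data.
#' Values are compared at full floating precision.
#'
#' @param panel An [abg_panel()].
#' @param ranges An [abg_ranges()] object (thresholds `ph_warn`,
#'   `ph_reject`).
#' @return A one-row findings data.frame, or an empty one when the
#'   panel is consistent.
#' @examples
#' check_hh_consistency(abg_panel(7.40, 40, 24, ag = 11))        # empty
#' check_hh_consistency(abg_panel(7.438, 38, 18, ag = 17))       # reject
#' @export
check_hh_consistency <- function(panel, ranges = abg_ranges()) {
  calc <- hh_ph(panel$paco2, panel$hco3, ranges$comp)
  d <- abs(panel$ph - calc)
  if (d <= ranges$ph_warn) return(empty_findings())
  severity <- if (d <= ranges$ph_reject) "warning" else "reject"
  msg <- if (severity == "warning") {
    sprintf("entered pH %.3f differs from the calculated pH %.3f by %.3f; the result may be incorrect",
            panel$ph, calc, d)
  } else {
    sprintf("incorrect data: entered pH %.3f differs from the calculated pH %.3f by %.3f",
            panel$ph, calc, d)
  }
  finding("hh_consistency", severity, msg, measured = panel$ph, computed = calc)
}

# Supplied SBE vs the van Slyke estimate: disagreement is expected
# across analysers, so it is reported as info only.
check_sbe_agreement <- function(panel, ranges = abg_ranges()) {
  if (is.na(panel$sbe)) return(empty_findings())
  est <- van_slyke_sbe(panel$ph, panel$hco3)
  d <- abs(panel$sbe - est)
  if (d <= ranges$sbe_info_delta) return(empty_findings())
  finding("sbe_disagreement", "info",
          sprintf("supplied SBE %g differs from the van Slyke estimate %.2f by %.2f mmol/L (analyser formulas vary)",
                  panel$sbe, est, d),
          measured = panel$sbe, computed = est)
}

#' Run the full pre-analysis validation of a panel
#'
#' Combines [check_required()], [check_plausibility()],
#' [check_hh_consistency()] and the supplied-SBE agreement note into
#' one findings table.
#'
#' @param panel An [abg_panel()].
#' @param ranges An [abg_ranges()] object.
#' @return A findings data.frame; any row with severity `"reject"`
#'   suppresses interpretation in [abg_interpret()].
#' @examples
#' validate_panel(abg_panel(7.06, 28, 8, ag = 10, albumin = 23))
#' @export
validate_panel <- function(panel, ranges = abg_ranges()) {
  out <- check_required(panel)
  if (any(out$severity == "reject")) return(out)
  rbind(out,
        check_plausibility(panel, ranges),
        check_hh_consistency(panel, ranges),
        check_sbe_agreement(panel, ranges))
}
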