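#' Construct a blood gas panel
#'
#' A panel is one patient's arterial blood gas measurement set. pH,
#' PaCO2 and bicarbonate are mandatory; the anion gap may be given
#' directly or derived from sodium and chloride; standard base excess
#' and albumin are optional. Standard bicarbonate is preferred, but
#' actual bicarbonate is accepted in its place (the usual clinical
#' practice when a standardised value is unavailable).
#'
#' Units are fixed: PaCO2 in mm Hg; HCO3-, SBE in mmol/L; AG, Na, Cl in
#' mEq/L; albumin in g/L.
#'
#' @param ph Arterial pH.
#' @param paco2 Partial pressure of CO2, mm Hg.
#' @param hco3 Bicarbonate, mmol/L.
#' @param sbe Standard base excess, mmol/L, or `NA` to have it
#'   estimated by [van_slyke_sbe()] at interpretation time.
#' @param ag Anion gap, mEq/L, or `NA` to derive it as
#'   `sodium - (chloride + hco3)`.
#' @param sodium,chloride Serum electrolytes, mEq/L; only required when
#'   `ag` is missing.
#' @param albumin Serum albumin, g/L; without it the two corrected-
#'   anion-gap approaches are skipped.
#'
#' @return An object of class `abg_panel`: a named list with the fields
#'   above plus `ag_derived` (logical, `TRUE` when the anion gap was
#'   computed from electrolytes).
#'
#' @examples
#' # worked case: severe metabolic acidosis with hypoalbuminaemia
#' abg_panel(ph = 7.06, paco2 = 28, hco3 = 8, ag = 10, albumin = 23)
#' # anion gap from electrolytes
#' abg_panel(ph = 7.4, paco2 = 40, hco3 = 24, sodium = 145, chloride = 100)
#' @export
abg_panel <- function(ph, paco2, hco3, sbe = NA_real_, ag = NA_real_,
                      sodium = NA_real_, chloride = NA_real_,
                      albumin = NA_real_) {
  num1 <- function(x, nm, required = FALSE) {
    if (is.null(x) || length(x) == 0L) x <- NA_real_
    if (length(x) != 1L) stop("field '", nm, "' must be a single value")
    if (is.na(x)) {
      if (required) stop("required field '", nm, "' is missing")
      return(NA_real_)
    }
    if (!is.numeric(x)) stop("field '", nm, "' must be numeric, got '", x, "'")
    if (!is.finite(x)) stop("field '", nm, "' must be finite")
    as.numeric(x)
  }
  p <- list(
    ph = num1(ph, "ph", required = TRUE),
    paco2 = num1(paco2, "paco2", required = TRUE),
    hco3 = num1(hco3, "hco3", required = TRUE),
    sbe = num1(sbe, "sbe"),
    ag = num1(ag, "ag"),
    sodium = num1(sodium, "sodium"),
    chloride = num1(chloride, "chloride"),
    albumin = num1(albumin, "albumin")
  )
  p$ag_derived <- FALSE
  if (is.na(p$ag)) {
    if (is.na(p$sodium) || is.na(p$chloride)) {
      stop("anion gap missing: supply 'ag' or both 'sodium' and 'chloride'")
    }
    p$ag <- anion_gap(p$sodium, p$chloride, p$hco3)
    p$ag_derived <- TRUE
  }
  structure(p, class = "abg_panel")
}

#' @export
print.abg_panel <- function(x, ...) {
  cat("Arterial blood gas panel\n")
  cat(sprintf("  pH %.3f | PaCO2 %g mm Hg | HCO3- %g mmol/L\n",
              x$ph, x$paco2, x$hco3))
  opt <- character(0)
  if (!is.na(x$sbe)) opt <- c(opt, sprintf("SBE %g mmol/L", x$sbe))
  opt <- c(opt, sprintf("AG %g mEq/L%s", x$ag,
                        if (x$ag_derived) " (from Na/Cl)" else ""))
  if (!is.na(x$albumin)) opt <- c(opt, sprintf("albumin %g g/L", x$albumin))
  cat(" ", paste(opt, collapse = " | "), "\n")
  invisible(x)
}
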