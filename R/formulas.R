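#' Henderson-Hasselbalch pH from PaCO2 and bicarbonate
#'
#' Computes the pH implied by the carbonic acid equilibrium,
#' `pH = pK + log10(HCO3- / (s * PaCO2))`, with pK 6.1 and a CO2
#' solubility coefficient s of 0.03 (mmol/L)/mm Hg. Used to screen a
#' panel for internal consistency: the entered pH and the computed pH
#' should agree closely on a correctly measured sample.
#'
#' @param paco2 PaCO2 in mm Hg, strictly positive.
#' @param hco3 Bicarbonate in mmol/L, strictly positive.
#' @param comp Optional coefficient list (from `abg_ranges()$comp`) for
#'   overriding pK or the solubility coefficient.
#' @return Computed pH.
#' @examples
#' hh_ph(40, 24)    # 7.401, consistent with an entered pH of 7.40
#' hh_ph(20, 12.5)  # 7.4188
#' @export
hh_ph <- function(paco2, hco3, comp = NULL) {
  if (is.null(comp)) comp <- abg_ranges()$comp
  if (any(!is.finite(paco2)) || any(!is.finite(hco3)) ||
      any(paco2 <= 0) || any(hco3 <= 0)) {
    stop("hh_ph requires finite, positive paco2 and hco3")
  }
  comp$hh_pk + log10(hco3 / (comp$hh_co2_solubility * paco2))
}

#' Standard base excess by the van Slyke estimate
#'
#' `SBE = 0.9287 * (HCO3- - 24.4 + 14.83 * (pH - 7.4))`, in mmol/L.
#' Used when the analyser's own SBE was not entered. Analysers apply a
#' variety of base-excess formulas, so an estimated value may differ
#' slightly from a reported one; the interpreter treats such
#' disagreement as informational only.
#'
#' @param ph Arterial pH.
#' @param hco3 Bicarbonate in mmol/L.
#' @return Standard base excess, mmol/L.
#' @examples
#' van_slyke_sbe(7.6, 51)    # 27.458
#' van_slyke_sbe(7.4, 24.4)  # 0, the formula's zero point
#' @export
van_slyke_sbe <- function(ph, hco3) {
  if (any(!is.finite(ph)) || any(!is.finite(hco3))) {
    stop("van_slyke_sbe requires finite inputs")
  }
  0.9287 * (hco3 - 24.4 + 14.83 * (ph - 7.4))
}

#' Anion gap from electrolytes
#'
#' The potassium-free simplification `AG = Na+ - (Cl- + HCO3-)`, mEq/L.
#'
#' @param sodium Serum sodium, mEq/L.
#' @param chloride Serum chloride, mEq/L.
#' @param hco3 Bicarbonate, mmol/L.
#' @return Anion gap, mEq/L.
#' @examples
#' anion_gap(145, 100, 24)  # 21
#' anion_gap(140, 105, 24)  # 11
#' @export
anion_gap <- function(sodium, chloride, hco3) {
  sodium - (chloride + hco3)
}

#' Albumin-corrected anion gap
#'
#' Unmeasured-anion load is underestimated in hypoalbuminaemia because
#' albumin itself carries negative charge. The correction adds
#' 0.25 mEq/L per g/L of albumin below the normal value:
#' `AGc = AG + 0.25 * (alb_normal - albumin)`.
#'
#' @param ag Observed anion gap, mEq/L.
#' @param albumin Observed albumin, g/L.
#' @param alb_normal Normal albumin, g/L (default 40).
#' @param slope Correction slope in mEq/L per g/L (default 0.25).
#' @return Corrected anion gap, mEq/L.
#' @examples
#' corrected_anion_gap(10, 23)  # 14.25
#' corrected_anion_gap(8, 40)   # unchanged at normal albumin
#' @export
corrected_anion_gap <- function(ag, albumin, alb_normal = 40, slope = 0.25) {
  if (any(is.na(albumin))) {
    stop("albumin is required for the corrected anion gap")
  }
  ag + slope * (alb_normal - albumin)
}

#' Delta ratio for triple-disorder detection
#'
#' The rise of the anion gap above its baseline relative to the fall of
#' bicarbonate below its baseline,
#' `(AG - 7) / (24 - HCO3-)` with the default reference set. In high
#' anion gap metabolic acidosis the band of this ratio flags coexisting
#' disorders:
#' \describe{
#'   \item{below_0p8}{ratio < 0.8: possible additional normal anion gap
#'     metabolic acidosis.}
#'   \item{b0p8_1p2}{0.8 <= ratio <= 1.2: uncomplicated high anion gap
#'     metabolic acidosis.}
#'   \item{b1p2_2}{1.2 < ratio <= 2: possible additional metabolic
#'     alkalosis.}
#'   \item{above_2}{ratio > 2: additional metabolic alkalosis.}
#' }
#' When bicarbonate has not fallen below baseline (denominator <= 0)
#' while the anion gap is elevated, the ratio is taken as `+Inf`
#' (band `above_2`): the bicarbonate that the acid load should have
#' consumed has been replenished, which is itself the signature of a
#' concurrent metabolic alkalosis.
#'
#' @param ag_used Anion gap in use (AG or AGc), mEq/L.
#' @param hco3 Bicarbonate, mmol/L.
#' @param ranges An [abg_ranges()] object supplying the baselines.
#' @return A list with class `abg_delta_ratio`: `value` (dimensionless,
#'   possibly `Inf`) and `band` (one of the four band names), or band
#'   `"not_applicable"` with `value = NA` when both numerator and
#'   denominator are non-positive.
#' @examples
#' delta_ratio(14.25, 8)  # 0.4531, band "below_0p8"
#' delta_ratio(19, 24)    # Inf, band "above_2"
#' delta_ratio(43, 6)     # exactly 2, band "b1p2_2"
#' @export
delta_ratio <- function(ag_used, hco3, ranges = abg_ranges()) {
  num <- ag_used - ranges$ag_baseline
  den <- ranges$hco3_baseline - hco3
  if (den <= 0 && num <= 0) {
    out <- list(value = NA_real_, band = "not_applicable")
  } else if (den <= 0) {
    out <- list(value = Inf, band = "above_2")
  } else {
    v <- num / den
    band <- if (v < 0.8) "below_0p8"
            else if (v <= 1.2) "b0p8_1p2"
            else if (v <= 2) "b1p2_2"
            else "above_2"
    out <- list(value = v, band = band)
  }
  structure(out, class = "abg_delta_ratio")
}

#' Expected secondary (compensatory) response for a simple disorder
#'
#' Every simple acid-base disorder elicits a predictable shift of the
#' opposite axis. This returns the expectation against which the
#' measured value is judged, as a center plus a symmetric band
#' (halfwidth 0 means a point estimate).
#'
#' Physiological (bicarbonate-based) rules, target PaCO2 for metabolic
#' primaries and HCO3- for respiratory primaries:
#' \itemize{
#'   \item metabolic acidosis: `PaCO2 = 1.5 * HCO3- + 8, +/- 2` (the
#'     Winter-type rule).
#'   \item metabolic alkalosis: `PaCO2 = 0.7 * (HCO3- - 24) + 40, +/- 2`.
#'   \item respiratory acidosis: `HCO3- = 24 + 0.1 * dPaCO2` acute,
#'     `24 + 0.4 * dPaCO2` chronic, with `dPaCO2 = PaCO2 - 40`.
#'   \item respiratory alkalosis: `HCO3- = 24 - 0.2 * |dPaCO2|` acute,
#'     `24 - 0.4 * |dPaCO2|` chronic.
#' }
#' Chemical (SBE-based) rules:
#' \itemize{
#'   \item metabolic acidosis: `PaCO2 = 40 + 1.0 * SBE`, point estimate.
#'   \item metabolic alkalosis: `PaCO2 = 40 + 0.6 * SBE`, point estimate.
#'   \item respiratory, acute: `SBE = 0 +/- 2`.
#'   \item respiratory, chronic: `SBE = 0.4 * dPaCO2 +/- 2`.
#' }
#'
#' @param primary One of `"metabolic_acidosis"`, `"metabolic_alkalosis"`,
#'   `"respiratory_acidosis"`, `"respiratory_alkalosis"`.
#' @param panel An [abg_panel()].
#' @param approach `"physiological"` or `"chemical"`.
#' @param chronicity For respiratory primaries, `"acute"` or `"chronic"`.
#' @param sbe The SBE in use (supplied or van Slyke estimate); required
#'   for the chemical metabolic rules.
#' @param ranges An [abg_ranges()] object.
#' @return A list of class `abg_compensation`: `target` ("paco2",
#'   "hco3" or "sbe"), `center`, `band_halfwidth`, `direction_if_low`
#'   and `direction_if_high` (the disorder implied when the measured
#'   value falls beyond the respective edge).
#' @examples
#' p <- abg_panel(ph = 7.6, paco2 = 45, hco3 = 51, ag = 14)
#' e <- expected_compensation("metabolic_alkalosis", p, "physiological")
#' c(e$center - e$band_halfwidth, e$center + e$band_halfwidth)  # 56.9-60.9
#' @export
expected_compensation <- function(primary, panel, approach,
                                  chronicity = c("acute", "chronic"),
                                  sbe = NULL, ranges = abg_ranges()) {
  chronicity <- match.arg(chronicity)
  cf <- ranges$comp
  dpaco2 <- panel$paco2 - ranges$paco2_baseline
  exp_obj <- function(target, center, half, low, high) {
    structure(list(target = target, center = center,
                   band_halfwidth = half,
                   direction_if_low = low, direction_if_high = high),
              class = "abg_compensation")
  }
  if (approach == "physiological") {
    switch(primary,
      metabolic_acidosis = exp_obj(
        "paco2",
        cf$met_acid_slope * panel$hco3 + cf$met_acid_intercept,
        cf$met_acid_band,
        "respiratory_alkalosis", "respiratory_acidosis"),
      metabolic_alkalosis = exp_obj(
        "paco2",
        cf$met_alk_slope * (panel$hco3 - ranges$hco3_baseline) +
          ranges$paco2_baseline,
        cf$met_alk_band,
        "respiratory_alkalosis", "respiratory_acidosis"),
      respiratory_acidosis = exp_obj(
        "hco3",
        ranges$hco3_baseline +
          (if (chronicity == "acute") cf$resp_acid_acute_slope
           else cf$resp_acid_chronic_slope) * dpaco2,
        0,
        "metabolic_acidosis", "metabolic_alkalosis"),
      respiratory_alkalosis = exp_obj(
        "hco3",
        ranges$hco3_baseline -
          (if (chronicity == "acute") cf$resp_alk_acute_slope
           else cf$resp_alk_chronic_slope) * abs(dpaco2),
        0,
        "metabolic_acidosis", "metabolic_alkalosis"),
      stop("unknown primary disorder kind: ", primary)
    )
  } else if (approach == "chemical") {
    if (primary %in% c("metabolic_acidosis", "metabolic_alkalosis") &&
        is.null(sbe)) {
      stop("chemical metabolic expectations require an SBE value")
    }
    switch(primary,
      metabolic_acidosis = exp_obj(
        "paco2",
        ranges$paco2_baseline + cf$chem_met_acid_slope * sbe,
        0,
        "respiratory_alkalosis", "respiratory_acidosis"),
      metabolic_alkalosis = exp_obj(
        "paco2",
        ranges$paco2_baseline + cf$chem_met_alk_slope * sbe,
        0,
        "respiratory_alkalosis", "respiratory_acidosis"),
      respiratory_acidosis = ,
      respiratory_alkalosis = exp_obj(
        "sbe",
        if (chronicity == "acute") 0 else cf$chem_resp_chronic_slope * dpaco2,
        cf$chem_resp_band,
        "metabolic_acidosis", "metabolic_alkalosis"),
      stop("unknown primary disorder kind: ", primary)
    )
  } else {
    stop("approach must be 'physiological' or 'chemical'")
  }
}
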