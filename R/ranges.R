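#' Reference ranges and rule constants for blood gas interpretation
#'
#' Builds the full set of constants the interpreter uses: reference
#' intervals for each analyte, the baselines the compensation and
#' delta-ratio formulas are anchored to, escalation thresholds for the
#' anion gap, the borderline ("probable") margin, the
#' Henderson-Hasselbalch consistency thresholds, plausibility windows
#' for input screening, and every compensation coefficient. All values
#' can be overridden, either programmatically or from a YAML/JSON
#' configuration file (see [read_abg_config()]).
#'
#' Reference intervals are closed: a value equal to either bound is
#' normal. Defaults: pH 7.34-7.44, PaCO2 36-44 mm Hg, HCO3- 22-26
#' mmol/L, SBE -2 to 2 mmol/L, AG 3-11 mEq/L (the modern ion-selective
#' electrode range), albumin 35-50 g/L.
#'
#' @param ... Named overrides of any default listed in Details, e.g.
#'   `abg_ranges(ag_hi = 12)`. Compensation coefficients live in the
#'   nested list `comp` and are overridden by passing a partial list:
#'   `abg_ranges(comp = list(resp_acid_chronic_slope = 0.35))`.
#'
#' @return An object of class `abg_ranges`: a named list with elements
#' \describe{
#'   \item{ph_lo, ph_hi}{normal pH interval (7.34, 7.44).}
#'   \item{paco2_lo, paco2_hi}{normal PaCO2, mm Hg (36, 44).}
#'   \item{hco3_lo, hco3_hi}{normal bicarbonate, mmol/L (22, 26).}
#'   \item{sbe_lo, sbe_hi}{normal standard base excess, mmol/L (-2, 2).}
#'   \item{ag_lo, ag_hi}{normal anion gap, mEq/L (3, 11).}
#'   \item{alb_lo, alb_hi}{normal albumin, g/L (35, 50).}
#'   \item{alb_normal}{albumin baseline for the corrected anion gap, 40 g/L.}
#'   \item{hco3_baseline, paco2_baseline}{compensation baselines 24 mmol/L, 40 mm Hg.}
#'   \item{ag_baseline}{delta-ratio numerator offset, 7 mEq/L.}
#'   \item{ag_consider_threshold, ag_certain_threshold}{AG escalation at 25 and 30 mEq/L.}
#'   \item{probable_margin}{fractional borderline zone beyond a compensation
#'     edge, default 0.05.}
#'   \item{ph_warn, ph_reject}{Henderson-Hasselbalch discrepancy thresholds
#'     0.02 (warn) and 0.1 (reject).}
#'   \item{sbe_info_delta}{absolute disagreement between a supplied SBE and
#'     the van Slyke estimate that triggers an informational note, 2 mmol/L.}
#'   \item{plaus}{plausibility windows used by [check_plausibility()].}
#'   \item{comp}{compensation coefficients, see [expected_compensation()].}
#' }
#'
#' @examples
#' r <- abg_ranges()
#' r$ag_hi
#' wide <- abg_ranges(ag_hi = 12, comp = list(resp_acid_chronic_slope = 0.35))
#' wide$comp$resp_acid_chronic_slope
#' @export
abg_ranges <- function(...) {
  defaults <- list(
    ph_lo = 7.34, ph_hi = 7.44,
    paco2_lo = 36, paco2_hi = 44,
    hco3_lo = 22, hco3_hi = 26,
    sbe_lo = -2, sbe_hi = 2,
    ag_lo = 3, ag_hi = 11,
    alb_lo = 35, alb_hi = 50,
    alb_normal = 40,
    hco3_baseline = 24,
    paco2_baseline = 40,
    ag_baseline = 7,
    ag_consider_threshold = 25,
    ag_certain_threshold = 30,
    probable_margin = 0.05,
    ph_warn = 0.02,
    ph_reject = 0.1,
    sbe_info_delta = 2,
    plaus = list(
      ph = c(6.5, 8.0), paco2 = c(10, 150), hco3 = c(1, 60),
      sbe = c(-35, 35), ag = c(-5, 60), albumin = c(5, 70)
    ),
    comp = list(
      # Henderson-Hasselbalch constants
      hh_pk = 6.1, hh_co2_solubility = 0.03,
      # albumin correction slope, mEq/L per g/L
      agc_slope = 0.25,
      # physiological (bicarbonate-based) expectations for PaCO2
      met_acid_slope = 1.5, met_acid_intercept = 8, met_acid_band = 2,
      met_alk_slope = 0.7, met_alk_band = 2,
      # physiological expectations for HCO3- in respiratory disorders,
      # slopes per mm Hg PaCO2 deviation from baseline
      resp_acid_acute_slope = 0.1, resp_acid_chronic_slope = 0.4,
      resp_alk_acute_slope = 0.2, resp_alk_chronic_slope = 0.4,
      # chemical (SBE-based) expectations for PaCO2 (point estimates)
      chem_met_acid_slope = 1.0, chem_met_alk_slope = 0.6,
      # chemical expectations for SBE in respiratory disorders
      chem_resp_chronic_slope = 0.4, chem_resp_band = 2
    )
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown reference-range field(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(overrides)) {
      if (nm %in% c("plaus", "comp")) {
        sub <- overrides[[nm]]
        bad <- setdiff(names(sub), names(defaults[[nm]]))
        if (length(bad)) {
          stop("unknown ", nm, " field(s): ", paste(bad, collapse = ", "))
        }
        defaults[[nm]] <- utils::modifyList(defaults[[nm]], sub)
      } else {
        defaults[[nm]] <- overrides[[nm]]
      }
    }
  }
  validate_abg_ranges(defaults)
  structure(defaults, class = "abg_ranges")
}

validate_abg_ranges <- function(r) {
  pairs <- list(
    c("ph_lo", "ph_hi"), c("paco2_lo", "paco2_hi"), c("hco3_lo", "hco3_hi"),
    c("sbe_lo", "sbe_hi"), c("ag_lo", "ag_hi"), c("alb_lo", "alb_hi")
  )
  for (p in pairs) {
    if (!(r[[p[1L]]] < r[[p[2L]]])) {
      stop("reference interval must satisfy lo < hi: ", p[1L], "/", p[2L])
    }
  }
  positive <- c("alb_normal", "hco3_baseline", "paco2_baseline", "ag_baseline",
                "ag_consider_threshold", "ag_certain_threshold",
                "probable_margin", "ph_warn", "ph_reject", "sbe_info_delta")
  for (nm in positive) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("reference constant must be a positive finite number: ", nm)
    }
  }
  if (r$ph_warn >= r$ph_reject) {
    stop("ph_warn must be below ph_reject")
  }
  if (r$ag_consider_threshold > r$ag_certain_threshold) {
    stop("ag_consider_threshold must not exceed ag_certain_threshold")
  }
  for (nm in names(r$plaus)) {
    w <- r$plaus[[nm]]
    if (length(w) != 2L || !all(is.finite(w)) || w[1L] >= w[2L]) {
      stop("plausibility window must be a finite (lo, hi) pair: ", nm)
    }
  }
  invisible(r)
}

#' @export
print.abg_ranges <- function(x, ...) {
  cat("Blood gas reference ranges\n")
  fmt <- function(lo, hi, unit) sprintf("%g-%g %s", x[[lo]], x[[hi]], unit)
  cat("  pH      ", fmt("ph_lo", "ph_hi", ""), "\n")
  cat("  PaCO2   ", fmt("paco2_lo", "paco2_hi", "mm Hg"), "\n")
  cat("  HCO3-   ", fmt("hco3_lo", "hco3_hi", "mmol/L"), "\n")
  cat("  SBE     ", fmt("sbe_lo", "sbe_hi", "mmol/L"), "\n")
  cat("  AG      ", fmt("ag_lo", "ag_hi", "mEq/L"), "\n")
  cat("  Albumin ", fmt("alb_lo", "alb_hi", "g/L"), "\n")
  cat(sprintf("  AG escalation at %g / %g mEq/L; probable margin %g%%\n",
              x$ag_consider_threshold, x$ag_certain_threshold,
              100 * x$probable_margin))
  cat(sprintf("  H-H consistency: warn > %g, reject > %g\n",
              x$ph_warn, x$ph_reject))
  invisible(x)
}

#' Read an interpreter configuration file
#'
#' Reads a YAML or JSON file whose top-level keys are [abg_ranges()]
#' fields (with nested `plaus` and `comp` sections) and returns the
#' resulting `abg_ranges` object. Fields not mentioned keep their
#' defaults, which reproduce the published rule set.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `abg_ranges` object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("ag_hi: 12", cfg)
#' read_abg_config(cfg)$ag_hi
#' @export
read_abg_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(overrides)) overrides <- list()
  do.call(abg_ranges, as.list(overrides))
}
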