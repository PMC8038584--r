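#' Generate a synthetic blood gas panel with known ground truth
#'
#' Constructs a panel by inverting the interpreter's own rule set: a
#' primary disorder severity is sampled, the opposite axis is placed in
#' a requested compensation-adequacy zone relative to the expected
#' secondary response, the pH is derived from the Henderson-Hasselbalch
#' equation (so generated panels are internally consistent to machine
#' precision unless an inconsistency is injected), and the anion gap
#' and albumin realise a requested gap scenario. The expected
#' physiological-approach label set is recorded alongside, which makes
#' generated cases usable as classifier-recovery fixtures.
#'
#' Sampling is rejection-based inside clinically bounded severity
#' windows (for example, bicarbonate 4-18 mmol/L for a primary
#' metabolic acidosis): candidates whose derived pH or component status
#' would leave the intended decision branch are redrawn, so the ground
#' truth fully determines the expected output under default ranges.
#' The draw is deterministic for a fixed seed; the caller's RNG state
#' is left untouched.
#'
#' @param primary `"none"` (normal panel), `"metabolic_acidosis"`,
#'   `"metabolic_alkalosis"`, `"respiratory_acidosis"` or
#'   `"respiratory_alkalosis"`.
#' @param chronicity For respiratory primaries: `"acute"` or
#'   `"chronic"`.
#' @param adequacy Compensation adequacy of the secondary response:
#'   `"in_band"` (adequate), `"probable"` (just beyond the expected
#'   edge, within the 5 percent borderline zone) or `"definite"`
#'   (clearly beyond). Metabolic primaries support all three;
#'   respiratory primaries support `"in_band"` and `"definite"` (the
#'   rule set has no borderline zone on the chronicity axis, so
#'   `"probable"` is unsatisfiable and raises an error).
#' @param side For metabolic primaries, which side of the expectation
#'   the measured PaCO2 falls on: `"high"` (additional respiratory
#'   acidosis) or `"low"` (additional respiratory alkalosis). For
#'   respiratory primaries with `adequacy = "definite"`:
#'   `"beyond_chronic"` (marker past the chronic expectation, adding
#'   the metabolic disorder in the adaptation direction) or
#'   `"short_of_acute"` (marker short of the acute expectation, adding
#'   the opposing metabolic disorder).
#' @param ag_profile Gap scenario: `"normal"` (gap inside its
#'   reference interval), `"elevated"` (high anion gap with the delta
#'   ratio in its neutral 0.8-1.2 band where a metabolic acidosis is
#'   present), or `"masked"` (normal measured gap whose albumin
#'   correction reveals a high gap; sets a low albumin).
#' @param inconsistency pH offset injected on top of the
#'   Henderson-Hasselbalch value; 0 gives a perfectly consistent panel,
#'   an offset above 0.1 produces a panel the validator must reject.
#' @param seed Integer seed; recorded in the result.
#'
#' @return An object of class `abg_synthetic_case`: a list with
#'   `panel` ([abg_panel()]), `truth` (construction parameters plus
#'   `labels` and `labels_agc`, the expected label tables for the
#'   plain and corrected physiological approaches, and `validation`,
#'   one of `"ok"`, `"warning"`, `"reject"`), and `seed`.
#' @examples
#' case <- abg_synthesize("metabolic_alkalosis", adequacy = "in_band", seed = 7)
#' canonical_label_set(case$truth$labels)
#' canonical_label_set(classify_approach(case$panel, "physiological"))
#' @export
abg_synthesize <- function(primary = c("none", "metabolic_acidosis",
                                       "metabolic_alkalosis",
                                       "respiratory_acidosis",
                                       "respiratory_alkalosis"),
                           chronicity = c("acute", "chronic"),
                           adequacy = c("in_band", "probable", "definite"),
                           side = NULL,
                           ag_profile = c("normal", "elevated", "masked"),
                           inconsistency = 0,
                           seed = 1L) {
  primary <- match.arg(primary)
  chronicity <- match.arg(chronicity)
  adequacy <- match.arg(adequacy)
  ag_profile <- match.arg(ag_profile)
  respiratory <- grepl("^respiratory", primary)
  metabolic <- grepl("^metabolic", primary)
  if (is.null(side)) side <- if (respiratory) "beyond_chronic" else "high"
  if (respiratory && adequacy == "probable") {
    stop("unsatisfiable spec: respiratory primaries have no borderline ",
         "(probable) compensation zone under the rule set")
  }
  if (metabolic) side <- match.arg(side, c("high", "low"))
  if (respiratory) side <- match.arg(side, c("beyond_chronic", "short_of_acute"))
  if (primary == "none" && adequacy != "in_band") {
    stop("unsatisfiable spec: a normal panel has no compensation zone")
  }
  if (ag_profile == "masked" && !metabolic && primary != "none") {
    stop("unsatisfiable spec: the masking scenario needs a metabolic ",
         "acidosis (or silent) gap pattern")
  }

  ranges <- abg_ranges()
  cf <- ranges$comp

  # deterministic local RNG, caller state restored on exit
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  draw_components <- function() {
    if (primary == "none") {
      hco3 <- stats::runif(1, 22.5, 25.5)
      paco2 <- stats::runif(1, 37, 43)
      return(list(hco3 = hco3, paco2 = paco2, chron = "none",
                  extra = NULL))
    }
    if (primary == "metabolic_acidosis") {
      hco3 <- switch(paste(adequacy, side),
        "probable low" = stats::runif(1, 4, 9),
        "definite low" = stats::runif(1, 4, 8),
        stats::runif(1, 4, 18))
      center <- cf$met_acid_slope * hco3 + cf$met_acid_intercept
      lo <- center - cf$met_acid_band; hi <- center + cf$met_acid_band
      paco2 <- switch(adequacy,
        in_band = center + stats::runif(1, -0.9, 0.9) * cf$met_acid_band,
        probable = if (side == "high") hi * (1 + stats::runif(1, 0.01, 0.045))
                   else lo * (1 - stats::runif(1, 0.01, 0.04)),
        definite = if (side == "high") hi * (1 + stats::runif(1, 0.07, 0.3))
                   else lo * (1 - stats::runif(1, 0.07, 0.12)))
      extra <- if (adequacy == "in_band") NULL else {
        make_label(if (side == "high") "respiratory_acidosis"
                   else "respiratory_alkalosis",
                   certainty = if (adequacy == "probable") "probable"
                               else "definite")
      }
      return(list(hco3 = hco3, paco2 = paco2, chron = "none", extra = extra))
    }
    if (primary == "metabolic_alkalosis") {
      hco3 <- stats::runif(1, 32, 45)
      center <- cf$met_alk_slope * (hco3 - ranges$hco3_baseline) +
        ranges$paco2_baseline
      lo <- center - cf$met_alk_band; hi <- center + cf$met_alk_band
      paco2 <- switch(adequacy,
        in_band = center + stats::runif(1, -0.9, 0.9) * cf$met_alk_band,
        probable = if (side == "high") hi * (1 + stats::runif(1, 0.01, 0.045))
                   else lo * (1 - stats::runif(1, 0.01, 0.04)),
        definite = if (side == "high") hi * (1 + stats::runif(1, 0.07, 0.15))
                   else lo * (1 - stats::runif(1, 0.07, 0.25)))
      extra <- if (adequacy == "in_band") NULL else {
        make_label(if (side == "high") "respiratory_acidosis"
                   else "respiratory_alkalosis",
                   certainty = if (adequacy == "probable") "probable"
                               else "definite")
      }
      return(list(hco3 = hco3, paco2 = paco2, chron = "none", extra = extra))
    }
    # respiratory primaries
    acid <- primary == "respiratory_acidosis"
    paco2 <- if (acid) {
      if (adequacy == "definite" && side == "beyond_chronic") {
        # over-compensation on top of hypercapnia pulls the pH back
        # toward normal; only severe chronic hypercapnia keeps the
        # panel acidaemic with the marker beyond the chronic zone
        stats::runif(1, 100, 115)
      } else if (chronicity == "chronic") {
        stats::runif(1, 65, 95)
      } else {
        stats::runif(1, 55, 90)
      }
    } else {
      if (chronicity == "chronic" || side == "beyond_chronic") {
        stats::runif(1, 18, 24)
      } else {
        stats::runif(1, 18, 30)
      }
    }
    dp <- paco2 - ranges$paco2_baseline
    acute_c <- if (acid) ranges$hco3_baseline + cf$resp_acid_acute_slope * dp
               else ranges$hco3_baseline - cf$resp_alk_acute_slope * abs(dp)
    chron_c <- if (acid) ranges$hco3_baseline + cf$resp_acid_chronic_slope * dp
               else ranges$hco3_baseline - cf$resp_alk_chronic_slope * abs(dp)
    if (adequacy == "in_band") {
      target <- if (chronicity == "acute") acute_c else chron_c
      hco3 <- target * (1 + stats::runif(1, -0.04, 0.04))
      return(list(hco3 = hco3, paco2 = paco2, chron = chronicity,
                  extra = NULL))
    }
    # definite deviations
    if (side == "beyond_chronic") {
      hco3 <- if (acid) chron_c * (1 + stats::runif(1, 0.06, 0.09))
              else chron_c * (1 - stats::runif(1, 0.07, 0.2))
      extra <- make_label(if (acid) "metabolic_alkalosis"
                          else "metabolic_acidosis")
      return(list(hco3 = hco3, paco2 = paco2, chron = "chronic",
                  extra = extra))
    }
    hco3 <- if (acid) acute_c * (1 - stats::runif(1, 0.07, 0.3))
            else acute_c * (1 + stats::runif(1, 0.07, 0.2))
    extra <- make_label(if (acid) "metabolic_acidosis"
                        else "metabolic_alkalosis")
    list(hco3 = hco3, paco2 = paco2, chron = "none", extra = extra)
  }

  draw_gap <- function(hco3) {
    albumin <- 40
    if (ag_profile == "normal") {
      ag <- stats::runif(1, 4, 10.5)
    } else if (ag_profile == "elevated") {
      if (hco3 < ranges$hco3_baseline - 4) {
        # place the delta ratio in its neutral band so the gap adds no
        # further labels beyond the high-gap call itself
        ag <- ranges$ag_baseline +
          stats::runif(1, 0.85, 1.15) * (ranges$hco3_baseline - hco3)
      } else {
        # bicarbonate near baseline: any elevated gap drives the ratio
        # past 2 (the occult high-gap pattern); the truth set carries
        # the implied metabolic alkalosis
        ag <- stats::runif(1, 12.5, 24)
      }
    } else {
      ag <- stats::runif(1, 5, 9)
      agc_target <- ranges$ag_baseline +
        stats::runif(1, 0.85, 1.15) * (ranges$hco3_baseline - hco3)
      albumin <- ranges$alb_normal - (agc_target - ag) / cf$agc_slope
    }
    list(ag = ag, albumin = albumin)
  }

  # analytic mirror of the gap logic, used to complete the truth set
  finish_truth <- function(labels, ag_used, hco3) {
    i <- match("metabolic_acidosis", labels$kind)
    if (!is.na(i)) {
      labels$kind[i] <- if (ag_used > ranges$ag_hi) "hagma" else "nagma"
    } else if (ag_used > ranges$ag_hi &&
               !any(labels$kind %in% c("hagma", "nagma", "metabolic_alkalosis"))) {
      labels <- add_label(labels, make_label("hagma"))
    }
    if (ag_used >= ranges$ag_certain_threshold) {
      labels <- add_label(labels, make_label("hagma"))
    }
    if ("hagma" %in% labels$kind) {
      den <- ranges$hco3_baseline - hco3
      num <- ag_used - ranges$ag_baseline
      band <- if (den <= 0 && num > 0) "above_2"
              else if (den <= 0) "not_applicable"
              else {
                v <- num / den
                if (v < 0.8) "below_0p8" else if (v <= 1.2) "b0p8_1p2"
                else if (v <= 2) "b1p2_2" else "above_2"
              }
      extra <- switch(band,
        below_0p8 = make_label("nagma", certainty = "probable"),
        b1p2_2 = make_label("metabolic_alkalosis", certainty = "probable"),
        above_2 = make_label("metabolic_alkalosis"),
        NULL)
      if (!is.null(extra)) labels <- add_label(labels, extra)
    }
    labels
  }

  # the decision branch the construction is aiming for must be the one
  # the derived pH actually lands in
  branch_ok <- function(ph, paco2, hco3) {
    # candidates falling inside a small buffer around any reference
    # bound are discarded: there the intended branch and the realised
    # branch could differ by rounding alone
    status_safe <- function(x, lo, hi, eps) {
      if (x < lo - eps) "low"
      else if (x > hi + eps) "high"
      else if (x >= lo + eps && x <= hi - eps) "normal"
      else "ambiguous"
    }
    ph_st <- status_safe(ph, ranges$ph_lo, ranges$ph_hi, 0.003)
    pc_st <- status_safe(paco2, ranges$paco2_lo, ranges$paco2_hi, 0.15)
    mk_st <- status_safe(hco3, ranges$hco3_lo, ranges$hco3_hi, 0.15)
    if (ph_st == "ambiguous" || pc_st == "ambiguous" ||
        mk_st == "ambiguous") {
      return(FALSE)
    }
    if (primary == "none") {
      return(ph_st == "normal" && pc_st == "normal" && mk_st == "normal")
    }
    if (primary == "metabolic_acidosis") {
      if (ph_st != "low" || mk_st != "low") return(FALSE)
      # a concordant high PaCO2 switches branch but only reproduces the
      # intended set when the extra respiratory call is already definite
      if (pc_st == "high" && adequacy != "definite") return(FALSE)
      if (pc_st == "high" && side != "high") return(FALSE)
      return(TRUE)
    }
    if (primary == "metabolic_alkalosis") {
      if (mk_st != "high") return(FALSE)
      if (adequacy == "definite" && side == "low") {
        return(ph_st == "high")   # concordant low PaCO2 keeps the same set
      }
      if (adequacy == "definite" && side == "high") {
        # single-primary (alkalaemic) or normal-pH mixed listing both
        # yield the same definite pair
        return(ph_st == "high" || (ph_st == "normal" && pc_st == "high"))
      }
      if (ph_st != "high") return(FALSE)
      if (pc_st == "low") return(FALSE)
      return(TRUE)
    }
    # respiratory primaries: single-primary branch required
    acid <- primary == "respiratory_acidosis"
    if (acid && (ph_st != "low" || pc_st != "high")) return(FALSE)
    if (!acid && (ph_st != "high" || pc_st != "low")) return(FALSE)
    if (acid && mk_st == "low") return(FALSE)
    if (!acid && mk_st == "high") return(FALSE)
    # the marker must sit in the zone the construction intended
    dp <- paco2 - ranges$paco2_baseline
    acute_c <- if (acid) ranges$hco3_baseline + cf$resp_acid_acute_slope * dp
               else ranges$hco3_baseline - cf$resp_alk_acute_slope * abs(dp)
    chron_c <- if (acid) ranges$hco3_baseline + cf$resp_acid_chronic_slope * dp
               else ranges$hco3_baseline - cf$resp_alk_chronic_slope * abs(dp)
    in_zone <- function(center) abs(hco3 - center) <= 0.049 * abs(center)
    if (adequacy == "in_band" && chronicity == "acute") return(in_zone(acute_c))
    if (adequacy == "in_band") return(!in_zone(acute_c) && in_zone(chron_c))
    if (side == "beyond_chronic") {
      beyond <- if (acid) hco3 > chron_c * 1.051 else hco3 < chron_c * 0.949
      return(!in_zone(acute_c) && beyond)
    }
    short <- if (acid) hco3 < acute_c * 0.949 else hco3 > acute_c * 1.051
    !in_zone(chron_c) && short
  }

  for (attempt in seq_len(1000L)) {
    comp <- draw_components()
    gap <- draw_gap(comp$hco3)
    ph_true <- hh_ph(comp$paco2, comp$hco3, cf)
    ph <- ph_true + inconsistency
    # the branch is judged on the consistent pH: an injected offset is
    # a measurement-error simulation, and the truth labels are only
    # guaranteed when the validator accepts the panel silently
    if (!branch_ok(ph_true, comp$paco2, comp$hco3)) next
    if (ph < ranges$plaus$ph[1] || ph > ranges$plaus$ph[2]) next
    if (gap$albumin < ranges$plaus$albumin[1]) next
    if (ag_profile == "elevated" && gap$ag <= ranges$ag_hi + 0.3) next

    base_labels <- empty_labels()
    if (primary != "none") {
      base_labels <- add_label(base_labels,
                               make_label(primary, chronicity = comp$chron))
    }
    if (!is.null(comp$extra)) base_labels <- add_label(base_labels, comp$extra)
    ag_plain <- gap$ag
    ag_corr <- gap$ag + cf$agc_slope * (ranges$alb_normal - gap$albumin)
    truth <- list(
      primary = primary,
      chronicity = if (respiratory) comp$chron else "none",
      adequacy = adequacy, side = side, ag_profile = ag_profile,
      inconsistency = inconsistency,
      labels = finish_truth(base_labels, ag_plain, comp$hco3),
      labels_agc = finish_truth(base_labels, ag_corr, comp$hco3),
      validation = if (abs(inconsistency) > ranges$ph_reject) "reject"
                   else if (abs(inconsistency) > ranges$ph_warn) "warning"
                   else "ok")
    panel <- abg_panel(ph = ph, paco2 = comp$paco2, hco3 = comp$hco3,
                       ag = gap$ag, albumin = gap$albumin)
    return(structure(list(panel = panel, truth = truth, seed = seed),
                     class = "abg_synthetic_case"))
  }
  stop("could not realise the requested construction in 1000 draws; ",
       "the specification may be unsatisfiable")
}

#' @export
print.abg_synthetic_case <- function(x, ...) {
  cat("Synthetic blood gas case (seed ", x$seed, ")\n", sep = "")
  print(x$panel)
  cat("  truth:", paste(canonical_label_set(x$truth$labels),
                        collapse = " | "), "\n")
  invisible(x)
}
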