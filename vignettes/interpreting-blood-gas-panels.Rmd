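---
title: "Interpreting arterial blood gas panels by four concurrent approaches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting arterial blood gas panels by four concurrent approaches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodgas)
```

## The problem

An arterial blood gas (ABG) panel — pH, PaCO~2~, bicarbonate, and
usually a base excess, an anion gap and albumin — is the standard
bedside window on acid-base physiology. Simple disorders are easy to
read; the clinically dangerous cases are the mixed ones, where two or
three disturbances partially cancel and the panel looks deceptively
mild. Two schools interpret the metabolic axis differently: the
*physiological* (Boston) school reasons on bicarbonate with empirical
compensation rules, while the *chemical* (Copenhagen) school reasons on
the standard base excess (SBE). Neither is universally accepted, and on
some panels they disagree.

`bloodgas` runs both schools side by side, each with and without an
albumin-corrected anion gap, and reports how many of the (up to four)
approaches agree — the *compliance* percentage. Low compliance is
itself the clinically useful signal: the patient sits in a grey zone
where the diagnosis depends on the school used.

## The rule engine

### Input screening

Interpretation refuses to start without pH, PaCO~2~, bicarbonate and an
anion gap (entered directly or derived as
$\mathrm{AG} = \mathrm{Na}^+ - (\mathrm{Cl}^- + \mathrm{HCO_3^-})$).
Values are then screened twice:

* **Plausibility.** Each value outside a generous survivable window
  (pH 6.5–8.0, PaCO~2~ 10–150 mm Hg, HCO~3~^−^ 1–60 mmol/L, SBE ±35
  mmol/L, AG −5–60 mEq/L, albumin 5–70 g/L) draws a warning. These
  windows are our own choice — the requirement is only that extreme
  entries be flagged — and every one is configurable.
* **Henderson–Hasselbalch consistency.** The entered pH is compared
  with $6.1 + \log_{10}(\mathrm{HCO_3^-} / (0.03 \cdot
  \mathrm{PaCO_2}))$ at full floating precision. A discrepancy above
  0.02 warns that the result may be incorrect; above 0.1 the panel is
  rejected as incorrect data and nothing is interpreted. The constants
  pK = 6.1 and CO~2~ solubility 0.03 (mmol/L)/mm Hg reproduce every
  internally consistent published evaluation panel to the printed
  precision.

A supplied SBE that disagrees with the van Slyke estimate
$0.9287(\mathrm{HCO_3^-} - 24.4 + 14.83(\mathrm{pH} - 7.4))$ by more
than 2 mmol/L is noted informationally only: analysers use different
base-excess formulas, so disagreement is expected, not an error.

### Classification

Reference intervals are closed (a value on the bound is normal): pH
7.34–7.44, PaCO~2~ 36–44 mm Hg, HCO~3~^−^ 22–26 mmol/L, SBE ±2 mmol/L,
AG 3–11 mEq/L (the modern ion-selective-electrode interval), albumin
35–50 g/L. Each approach then walks the same tree:

1. **Abnormal pH, one explaining component** — that component is the
   primary disorder and its expected secondary response is checked
   (below).
2. **Abnormal pH, both components explaining** (e.g. acidaemia with
   both hypercapnia and a low marker) — both are primary; no adequacy
   check is meaningful.
3. **Normal pH, any abnormal component** — every indicated disorder is
   listed. No disturbance is ever fully compensated, so an abnormal
   panel with a normal pH is by definition mixed; no chronicity or
   adequacy is assessed.
4. **Everything normal** — only the anion gap screen can still fire;
   an empty label set prints "correct results".

A thin sliver remains where the pH is abnormal while both components
sit inside their intervals (possible only near the interval corners,
and usually caught by the consistency screen first). We assign the
primary from the component whose deviation from its baseline (PaCO~2~
40 mm Hg, HCO~3~^−^ 24 mmol/L, SBE 0) explains the pH and attach an
explanatory note; no published case reaches this branch.

### Secondary responses

Expected compensations, with PaCO~2~ in mm Hg and
$\Delta\mathrm{PaCO_2} = \mathrm{PaCO_2} - 40$:

| primary | physiological (HCO~3~^−^-based) | chemical (SBE-based) |
|---|---|---|
| metabolic acidosis | PaCO~2~ = 1.5·HCO~3~^−^ + 8 ± 2 | PaCO~2~ = 40 + 1.0·SBE (point) |
| metabolic alkalosis | PaCO~2~ = 0.7·(HCO~3~^−^ − 24) + 40 ± 2 | PaCO~2~ = 40 + 0.6·SBE (point) |
| respiratory, acute | HCO~3~^−^ = 24 + 0.1·ΔPaCO~2~ (acidosis) / 24 − 0.2·\|ΔPaCO~2~\| (alkalosis) | SBE = 0 ± 2 |
| respiratory, chronic | HCO~3~^−^ = 24 ± 0.4·\|ΔPaCO~2~\| | SBE = 0.4·ΔPaCO~2~ ± 2 |

The metabolic-alkalosis rules and the van Slyke formula are stated by
the source algorithm; the remaining coefficients are the standard
companion rules of the same rule family, and each one was verified to
reproduce the published evaluation panels exactly (for example, the
acute slopes 0.1 and 0.2 are pinned by two survey panels whose markers
sit precisely on the acute expectation). The chronic respiratory
acidosis slope cannot be pinned by any published panel; we use 0.4 and
expose it, like every other coefficient, in the configuration object.

**Borderline zone.** A measured value beyond the expected band but by
no more than 5 % of the band edge yields a *probable* additional
disorder ("probably with respiratory acidosis"); beyond 5 %, a
definite one. The margin is computed relative to the edge value (not
the center) — the source narration does not distinguish the two; we
chose the edge and expose the fraction as `probable_margin`.

**Chronicity.** For respiratory primaries the marker is placed against
the acute and chronic expectations, each widened by the same 5 %
margin: acute zone → acute; chronic zone → chronic; beyond the chronic
zone in the adaptation direction → chronic *plus* the metabolic
disorder in that direction; short of the acute zone on the baseline
side → no chronicity plus the opposing metabolic disorder; between the
zones → an explicit "indeterminate chronicity" note. The acute zone is
tested first, so a panel falling in an overlap (possible for mild
derangements) is read as acute, the weaker claim.

### The anion gap and the delta ratio

After the pH branch, the gap logic runs with the gap in use — the raw
AG, or the albumin-corrected
$\mathrm{AG_c} = \mathrm{AG} + 0.25(40 - \mathrm{albumin})$ for the
corrected approaches:

* a detected metabolic acidosis becomes high-gap (AG > 11) or
  normal-gap;
* an elevated gap with *no* metabolic component at all asserts an
  occult high-gap acidosis. An elevated gap alongside a metabolic
  alkalosis is tolerated below the thresholds — such fluctuations
  accompany that disorder and are not themselves evidence of acidosis;
* a gap ≥ 25 mEq/L adds a "consider an additional disorder" note, and
  ≥ 30 mEq/L asserts the high-gap acidosis regardless of other
  findings;
* whenever a high-gap acidosis is present the delta ratio
  $(\mathrm{AG} - 7)/(24 - \mathrm{HCO_3^-})$ — always on bicarbonate,
  in every approach — screens for a third disorder: < 0.8 suggests an
  additional normal-gap acidosis (probable); 0.8–1.2 is neutral;
  1.2–2 suggests an additional metabolic alkalosis (probable); > 2
  asserts one. Both edges 0.8 and 1.2 belong to the neutral band and
  2.0 to the intermediate band, as pinned by two published panels that
  land exactly on 0.8125 and 2.0. When bicarbonate has not fallen
  below baseline while the gap is elevated, the ratio is taken as
  $+\infty$: the bicarbonate the acid load should have consumed has
  been replenished, which is the signature of a concurrent metabolic
  alkalosis. The 1.2–2 band is mapped to a *probable* alkalosis
  because the published evaluation tables consistently print "possible
  additional metabolic alkalosis" for ratios of 1.385, 1.8 and 2.0,
  although one narrative sentence reads the opposite way; we follow
  the tables.

### Compliance

Label sets are compared as sets of (kind, chronicity, certainty) —
sentence order is presentation only. Compliance is
$100 \cdot \max_g |g| / n$ over groups $g$ of identical sets among the
$n$ approaches run, which reproduces both published values (100 % and
50 %) and gives 75 % for a 3-vs-1 split — a value no published case
pins, fixed here by the definition.

## A worked example

The masked-gap case: severe acidaemia with a seemingly normal anion
gap, but albumin 23 g/L.

```{r}
report <- abg_interpret(abg_panel(ph = 7.06, paco2 = 28, hco3 = 8,
                                  ag = 10, albumin = 23))
report
```

The plain approaches read a normal-gap acidosis with inadequate
respiratory compensation; the corrected gap (14.25 mEq/L) reveals a
high-gap acidosis whose delta ratio (0.45) suggests a normal-gap
acidosis on top. Compliance 50 % flags the disagreement.

## The synthetic generator

`abg_synthesize()` inverts the rule set: it samples a primary-disorder
severity inside a clinically bounded window (e.g. HCO~3~^−^ 4–18
mmol/L for metabolic acidosis, PaCO~2~ 55–90 mm Hg for acute
respiratory acidosis), places the opposite axis in a requested
adequacy zone (in-band, borderline, or definitely beyond), derives the
pH from the Henderson–Hasselbalch equation — so generated panels are
consistent to machine precision unless an inconsistency offset is
injected — and chooses gap and albumin to realise a requested gap
scenario (normal, elevated with a neutral delta ratio, or a low-albumin
masked gap). Candidates whose derived pH or component status would
leave the intended decision branch, or would sit within a small buffer
of a reference bound, are redrawn; this rejection step uses only the
analytic gate conditions, never the classifier itself, so
classifier-recovery tests remain meaningful for the compensation and
gap logic. The expected label set is recorded analytically during
construction.

Two scenarios are refused as unsatisfiable rather than silently bent:
a *probable* zone for respiratory primaries (the chronicity rules have
no borderline band) and over-compensation beyond the chronic
expectation for respiratory acidosis at moderate PaCO~2~ (the pH
returns to normal and the branch changes; the generator therefore uses
severe hypercapnia, PaCO~2~ 100–115 mm Hg, for that scenario).

What generated panels deliberately do **not** emulate: analyser
measurement noise, biological covariance between albumin and the gap,
and the warning-level (0.02–0.1) consistency zone of real analysers —
generated panels are either exact or explicitly offset. Recovery
results on synthetic panels therefore certify the rule engine, not the
behaviour of real laboratory data.

## Numerical choices and degenerate inputs

* Comparisons against reference bounds and consistency thresholds use
  full floating precision; nothing is rounded before comparison.
* A compensation edge of exactly zero (possible for chemical
  respiratory expectations at PaCO~2~ 35 mm Hg) makes the edge-relative
  margin degenerate; any deviation beyond such an edge is treated as
  definite.
* The delta ratio with gap at baseline *and* bicarbonate at or above
  baseline is reported "not applicable" rather than 0/0.
* Problem sizes: the test suite runs the full published evaluation set
  (25 panels), a 18 000-point delta-ratio grid scan, and just over
  1000 seeded synthetic recoveries; all are recomputed at test time,
  nothing is cached.

## Known limitations

* No clinical context: ketoacidosis with alkalaemia (pH > 7.44 and a
  gap below 25 mEq/L) reads as plain metabolic alkalosis; the
  coexisting high-gap acidosis that a clinician would suspect from the
  history is invisible to the rule set.
* One published discordant case reports a *probable* respiratory
  alkalosis from the chemical approach where the stated point-estimate
  rule and 5 % margin give a definite one (deviation 6.25 %); the
  original application's exact chemical tolerance is not recoverable,
  and that approach's output for the shipped case `d43` is marked
  known-divergent rather than asserted.
* One survey panel prints its base excess to a single decimal; the van
  Slyke recomputation agrees at that printed precision but not to
  ±0.01, unlike the other nine panels.
* Oxygenation, temperature correction, lactate and the physicochemical
  (Stewart) framework are out of scope.
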