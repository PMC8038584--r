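# bloodgas

Rule-based interpretation of arterial blood gas (ABG) panels by four
concurrent approaches, for laboratory-medicine and clinical
decision-support work where the question is not only *which* acid-base
disorder a panel shows, but *whether the answer depends on the school
of analysis used*.

Two traditions read the metabolic axis of an ABG differently: the
physiological (Boston) school reasons on bicarbonate with empirical
compensation rules, the chemical (Copenhagen) school on the standard
base excess (SBE). `bloodgas` runs both, each with and without an
albumin-corrected anion gap (AGc), and reports the **compliance** — the
percentage of approaches returning the identical diagnosis set. Low
compliance flags the grey-zone panels that deserve a second look.

## The rules at the core

* Henderson–Hasselbalch consistency screen on every panel,
  `pH = 6.1 + log10(HCO3- / (0.03 * PaCO2))`: a discrepancy above 0.02
  warns, above 0.1 rejects the panel as incorrect data.
* van Slyke SBE estimate when the analyser value is absent:
  `SBE = 0.9287 * (HCO3- - 24.4 + 14.83 * (pH - 7.4))`.
* Anion gap `AG = Na+ - (Cl- + HCO3-)`, corrected for hypoalbuminaemia
  as `AGc = AG + 0.25 * (40 - albumin)`.
* Compensation expectations per primary disorder (e.g. Winter-type
  `PaCO2 = 1.5 * HCO3- + 8 ± 2` for metabolic acidosis, `PaCO2 =
  0.7 * (HCO3- - 24) + 40 ± 2` for metabolic alkalosis, SBE-based point
  estimates for the chemical school), with a 5 % borderline zone that
  grades near-miss additional disorders as "probable".
* Anion-gap escalation at 25 and 30 mEq/L, and delta-ratio
  `(AG - 7)/(24 - HCO3-)` banding (&lt;0.8 / 0.8–1.2 / 1.2–2 / &gt;2)
  for triple-disorder detection in high-gap metabolic acidosis.

The methods vignette
(`vignettes/interpreting-blood-gas-panels.Rmd`) derives every rule,
band edge and default, and documents the deliberate design choices.

## A worked example

A severely acidaemic panel whose anion gap looks normal — until the
albumin correction is applied:

```r
library(bloodgas)
report <- abg_interpret(abg_panel(ph = 7.06, paco2 = 28, hco3 = 8,
                                  ag = 10, albumin = 23))
report
#> The compliance of the results is 50%.
#> physiological approach: respiratory acidosis and normal anion gap metabolic acidosis
#> physiological approach with AGc: respiratory acidosis and high anion gap metabolic acidosis, possible additional normal anion gap metabolic acidosis
#> chemical approach: respiratory acidosis and normal anion gap metabolic acidosis
#> chemical approach with AGc: respiratory acidosis and high anion gap metabolic acidosis, possible additional normal anion gap metabolic acidosis
```

Reading: the measured PaCO2 (28 mm Hg) exceeds the expected
compensation for a bicarbonate of 8 mmol/L (20 ± 2 mm Hg), so every
approach adds a respiratory acidosis. The plain approaches see a
normal gap (10 mEq/L); the corrected gap is 14.25 mEq/L, i.e. a
high-gap acidosis, and its delta ratio (7.25/16 = 0.45, below 0.8)
suggests a normal-gap acidosis on top. Two approaches agree with two
others — compliance 50 % — which is exactly the signal that this
patient's diagnosis depends on the analysis school.

Batch processing and a CLI are included:

```sh
Rscript exec/abg analyze --ph 7.06 --paco2 28 --hco3 8 --ag 10 --alb 23
Rscript exec/abg batch inst/extdata/printed_cases.csv --out reports.json
```

The packaged `inst/extdata/printed_cases.csv` holds the 25 published
evaluation panels (literature comparison, survey cases including one
intentionally inconsistent panel, worked examples and the
application-comparison pair), with their expected per-approach label
sets in `printed_expectations.json`.

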