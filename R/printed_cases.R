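#' Packaged published evaluation cases
#'
#' The package ships the published evaluation panels: the nine
#' literature-comparison cases (`t1_*`), the ten survey cases
#' (`t2_*`, one of which is intentionally inconsistent and must be
#' rejected), the three worked examples (`ex1`-`ex3`) and the
#' application-comparison and discordant-approaches panels (`d42_*`,
#' `d43`). Each case carries the expected disorder label set per
#' approach where the publication pins one down.
#'
#' Expected labels are encoded as `"kind|chronicity|certainty"`
#' strings (`chronicity` and `certainty` default to `"none"` and
#' `"definite"`). `reject = TRUE` marks a case the consistency screen
#' must refuse; `known_divergent` names approaches whose published
#' output the stated rule set cannot reproduce (their sets are shipped
#' for reference, not asserted).
#'
#' @return A list with elements
#'   \describe{
#'     \item{records}{character data.frame of case records (see
#'       [read_abg_cases()]).}
#'     \item{expectations}{named list keyed by `case_id` with elements
#'       `source`, `expected` (per-approach label-string vectors) and
#'       optionally `reject`, `compliance`, `known_divergent`.}
#'   }
#' @examples
#' pc <- abg_printed_cases()
#' nrow(pc$records)
#' pc$expectations$ex3$compliance
#' @export
abg_printed_cases <- function() {
  csv <- system.file("extdata", "printed_cases.csv", package = "bloodgas",
                     mustWork = TRUE)
  js <- system.file("extdata", "printed_expectations.json",
                    package = "bloodgas", mustWork = TRUE)
  records <- read_abg_cases(csv)
  expectations <- jsonlite::read_json(js, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE)
  list(records = records, expectations = expectations)
}

#' Decode expected-label strings into a label table
#'
#' Turns `"kind|chronicity|certainty"` strings (as used in the packaged
#' expectations and by [abg_synthesize()]) into the label data.frame
#' layout produced by [classify_approach()], so the two can be compared
#' as sets via [canonical_label_set()].
#'
#' @param strings Character vector, possibly empty (the empty set means
#'   "correct results").
#' @return A label data.frame with columns `kind`, `chronicity`,
#'   `certainty`.
#' @examples
#' parse_label_strings(c("hagma", "respiratory_alkalosis|chronic"))
#' @export
parse_label_strings <- function(strings) {
  out <- empty_labels()
  for (s in strings) {
    parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
    kind <- parts[1L]
    chronicity <- if (length(parts) >= 2L && nzchar(parts[2L])) parts[2L] else "none"
    certainty <- if (length(parts) >= 3L && nzchar(parts[3L])) parts[3L] else "definite"
    out <- add_label(out, make_label(kind, chronicity, certainty))
  }
  out
}
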