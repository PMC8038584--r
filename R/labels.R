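# Disorder labels are rows of a data.frame with columns
# kind, chronicity, certainty. Kinds: respiratory_acidosis,
# respiratory_alkalosis, metabolic_acidosis (internal, resolved to
# hagma/nagma by the anion-gap logic before rendering), hagma, nagma,
# metabolic_alkalosis. chronicity: none/acute/chronic (respiratory
# kinds only). certainty: definite/probable.

.kind_order <- c("respiratory_acidosis", "respiratory_alkalosis",
                 "metabolic_acidosis", "hagma", "nagma",
                 "metabolic_alkalosis")

.kind_phrase <- c(
  respiratory_acidosis = "respiratory acidosis",
  respiratory_alkalosis = "respiratory alkalosis",
  metabolic_acidosis = "metabolic acidosis",
  hagma = "high anion gap metabolic acidosis",
  nagma = "normal anion gap metabolic acidosis",
  metabolic_alkalosis = "metabolic alkalosis"
)

empty_labels <- function() {
  data.frame(kind = character(0), chronicity = character(0),
             certainty = character(0), stringsAsFactors = FALSE)
}

make_label <- function(kind, chronicity = "none", certainty = "definite") {
  stopifnot(kind %in% .kind_order,
            chronicity %in% c("none", "acute", "chronic"),
            certainty %in% c("definite", "probable"))
  if (chronicity != "none" && !grepl("^respiratory", kind)) {
    stop("chronicity applies only to respiratory disorders")
  }
  data.frame(kind = kind, chronicity = chronicity, certainty = certainty,
             stringsAsFactors = FALSE)
}

# Add a label, keeping each kind at most once. A definite label wins
# over a probable one for the same kind; chronicity is kept from
# whichever entry carries one.
add_label <- function(labels, new) {
  i <- match(new$kind, labels$kind)
  if (is.na(i)) return(rbind(labels, new))
  if (labels$certainty[i] == "probable" && new$certainty == "definite") {
    labels$certainty[i] <- "definite"
  }
  if (labels$chronicity[i] == "none" && new$chronicity != "none") {
    labels$chronicity[i] <- new$chronicity
  }
  labels
}

# Deterministic ordering: definite before probable, then a fixed kind
# precedence (respiratory, then acidoses, then metabolic alkalosis).
sort_labels <- function(labels) {
  if (nrow(labels) == 0L) return(labels)
  ord <- order(match(labels$certainty, c("definite", "probable")),
               match(labels$kind, .kind_order))
  out <- labels[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

render_one_label <- function(kind, chronicity, certainty) {
  phrase <- .kind_phrase[[kind]]
  if (chronicity != "none") phrase <- paste(chronicity, phrase)
  if (certainty == "probable") {
    marker <- if (grepl("^respiratory", kind)) "probably with"
              else "possible additional"
    phrase <- paste(marker, phrase)
  }
  phrase
}

#' Canonical rendering of a disorder label set
#'
#' Renders an approach result's label set as an ordered character
#' vector, one rendered phrase per disorder. The ordering is canonical
#' - definite before probable, respiratory before metabolic within each
#' certainty - so that equal label sets always render identically,
#' regardless of the order in which the rules emitted them. An empty
#' set renders as `"correct results"`.
#'
#' Borderline ("probable") disorders carry the phrasing used in the
#' report text: `"probably with ..."` for respiratory disorders flagged
#' by a near-miss compensation check, `"possible additional ..."` for
#' metabolic disorders flagged by the delta-ratio bands.
#'
#' @param result An `abg_approach_result` (from [classify_approach()]),
#'   or a bare label data.frame.
#' @return Character vector of rendered label phrases.
#' @examples
#' panel <- abg_panel(ph = 7.39, paco2 = 39, hco3 = 22, ag = 19)
#' res <- classify_approach(panel, "physiological")
#' canonical_label_set(res)
#' @export
canonical_label_set <- function(result) {
  labels <- if (is.data.frame(result)) result else result$labels
  labels <- sort_labels(labels)
  if (nrow(labels) == 0L) return("correct results")
  vapply(seq_len(nrow(labels)), function(i) {
    render_one_label(labels$kind[i], labels$chronicity[i],
                     labels$certainty[i])
  }, character(1))
}

# One-sentence rendering in the report style: definite phrases joined
# with "and", probable phrases appended after a comma.
render_result_sentence <- function(result) {
  labels <- if (is.data.frame(result)) result else result$labels
  labels <- sort_labels(labels)
  if (nrow(labels) == 0L) return("correct results")
  definite <- labels[labels$certainty == "definite", , drop = FALSE]
  probable <- labels[labels$certainty == "probable", , drop = FALSE]
  parts <- vapply(seq_len(nrow(definite)), function(i) {
    render_one_label(definite$kind[i], definite$chronicity[i], "definite")
  }, character(1))
  sentence <- paste(parts, collapse = " and ")
  if (nrow(probable)) {
    extras <- vapply(seq_len(nrow(probable)), function(i) {
      render_one_label(probable$kind[i], probable$chronicity[i], "probable")
    }, character(1))
    sentence <- if (nzchar(sentence)) {
      paste0(sentence, ", ", paste(extras, collapse = ", "))
    } else {
      paste(extras, collapse = ", ")
    }
  }
  sentence
}

# Key used for label-set equality (compliance grouping and tests).
label_set_key <- function(result) {
  paste(canonical_label_set(result), collapse = " | ")
}
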