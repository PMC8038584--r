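# Batch I/O. Case records use the fixed column set below; values are
# kept as decimal strings at the record layer so that CSV -> JSON ->
# CSV round trips are bit-exact, and are converted to numbers only
# when a panel is built.

.case_columns <- c("case_id", "ph", "paco2", "hco3", "sbe", "ag",
                   "na", "cl", "alb")

#' Read a batch of case records from CSV or JSON
#'
#' The CSV dialect is comma-separated, UTF-8, with a header row naming
#' a subset of the columns `case_id, ph, paco2, hco3, sbe, ag, na, cl,
#' alb`; an empty cell is a missing value. A JSON batch is an array of
#' objects with the same keys. Unknown columns are rejected with a
#' clear message. Values are returned as character strings exactly as
#' read.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A data.frame of character columns (all nine columns present,
#'   missing ones filled with `NA`), one row per case.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("case_id,ph,paco2,hco3,ag", "a,7.4,40,24,11"), f)
#' read_abg_cases(f)
#' @export
read_abg_cases <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(recs) == 0L) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(.case_columns)), .case_columns),
        stringsAsFactors = FALSE)
      return(df)
    }
    rows <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      unknown <- setdiff(names(r), .case_columns)
      if (length(unknown)) {
        stop("unknown column(s) in record ", i, ": ",
             paste(unknown, collapse = ", "))
      }
      vapply(.case_columns, function(cn) {
        v <- r[[cn]]
        if (is.null(v) || (length(v) == 1L && is.na(v))) NA_character_
        else as.character(v)
      }, character(1))
    })
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- .case_columns
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
    unknown <- setdiff(names(df), .case_columns)
    if (length(unknown)) {
      stop("unknown column(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    for (cn in setdiff(.case_columns, names(df))) {
      df[[cn]] <- rep(NA_character_, nrow(df))
    }
    df <- df[, .case_columns, drop = FALSE]
    df[df == ""] <- NA_character_
  }
  if (anyDuplicated(stats::na.omit(df$case_id))) {
    stop("duplicate case_id in ", path)
  }
  df
}

#' Write case records to CSV or JSON
#'
#' The inverse of [read_abg_cases()]: values are written exactly as the
#' decimal strings held in the record table, so a round trip through
#' either format preserves them bit-exactly.
#'
#' @param records A character data.frame as returned by
#'   [read_abg_cases()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_abg_cases <- function(records, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(records)), function(i) {
      r <- as.list(records[i, , drop = FALSE])
      r[!is.na(unlist(r))]
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    out <- records
    out[is.na(out)] <- ""
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Build a panel from one case record
#'
#' Converts the decimal strings of a record row to numbers, deriving
#' the anion gap from sodium and chloride when `ag` is absent.
#' Unparseable numbers raise an error naming the field and case.
#'
#' @param record A one-row data.frame or named list/character vector
#'   with (a subset of) the record columns.
#' @return An [abg_panel()].
#' @examples
#' panel_from_record(list(case_id = "x", ph = "7.4", paco2 = "40",
#'                        hco3 = "24", na = "145", cl = "100"))
#' @export
panel_from_record <- function(record) {
  record <- as.list(record)
  id <- if (!is.null(record$case_id) && !is.na(record$case_id)) {
    record$case_id
  } else "<unnamed>"
  num <- function(cn) {
    v <- record[[cn]]
    if (is.null(v) || length(v) == 0L || is.na(v) ||
        (is.character(v) && !nzchar(v))) {
      return(NA_real_)
    }
    if (is.numeric(v)) return(as.numeric(v))
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) {
      stop("case '", id, "': field '", cn, "' is not a number: '", v, "'")
    }
    x
  }
  abg_panel(ph = num("ph"), paco2 = num("paco2"), hco3 = num("hco3"),
            sbe = num("sbe"), ag = num("ag"), sodium = num("na"),
            chloride = num("cl"), albumin = num("alb"))
}

# ---- report serialization ------------------------------------------------

report_header <- function(report) {
  if (any(report$validation$severity == "reject")) {
    return("Incorrect data - the analysis was not performed.")
  }
  n <- length(report$results)
  line <- sprintf("The compliance of the results is %g%%.",
                  report$compliance_pct)
  if (n == 2L) paste("Comparing two approaches.", line) else line
}

#' Convert a report to a plain list following the report schema
#'
#' Key order is fixed: `case_id`, `validation`, `approaches`,
#' `skipped`, `compliance_pct`; within each approach: `name`, `labels`,
#' `evidence`, `notes`. Serialising the same report twice is
#' byte-identical.
#'
#' @param report An `abg_report`.
#' @param case_id Optional case identifier stored in the report.
#' @return A nested list ready for [jsonlite::toJSON()].
#' @export
report_to_list <- function(report, case_id = NULL) {
  approaches <- lapply(names(report$results), function(nm) {
    r <- report$results[[nm]]
    ev <- r$evidence[order(names(r$evidence))]
    list(name = nm,
         labels = as.list(canonical_label_set(r)),
         evidence = ev,
         notes = as.list(r$notes))
  })
  v <- report$validation
  validation <- lapply(seq_len(nrow(v)), function(i) {
    list(code = v$code[i], severity = v$severity[i], message = v$message[i])
  })
  list(case_id = if (is.null(case_id)) NA_character_ else case_id,
       validation = validation,
       approaches = approaches,
       skipped = as.list(report$skipped),
       compliance_pct = report$compliance_pct)
}

format_report_text <- function(report, case_id = NULL) {
  out <- character(0)
  if (!is.null(case_id)) out <- c(out, paste0("Case: ", case_id))
  out <- c(out, report_header(report))
  for (nm in names(report$results)) {
    r <- report$results[[nm]]
    out <- c(out, paste0(.approach_title[[nm]], ": ",
                         render_result_sentence(r)))
    if (length(r$notes)) out <- c(out, paste0("  note: ", r$notes))
  }
  for (nm in names(report$skipped)) {
    if (nm == "all") next
    out <- c(out, paste0(.approach_title[[nm]], ": skipped - ",
                         report$skipped[[nm]]))
  }
  v <- report$validation
  if (nrow(v)) {
    out <- c(out, paste0("[", v$severity, "] ", v$message))
  }
  out
}

#' Serialize an analysis report
#'
#' Text format prints the compliance header first, then each
#' approach's rendered diagnosis, then validation findings. JSON
#' format follows the fixed report schema (see [report_to_list()]).
#' Both are byte-identical across runs on the same report.
#'
#' @param report An `abg_report` from [abg_interpret()].
#' @param format `"text"` or `"json"`.
#' @param case_id Optional case identifier.
#' @param path Optional output file; when `NULL` the serialized report
#'   is returned as a character vector (text) or JSON string.
#' @return The serialized report, invisibly when written to `path`.
#' @examples
#' rep <- abg_interpret(abg_panel(7.4, 40, 24, ag = 11, sbe = 0, albumin = 40))
#' cat(write_abg_report(rep, "text"), sep = "\n")
#' @export
write_abg_report <- function(report, format = c("text", "json"),
                             case_id = NULL, path = NULL) {
  format <- match.arg(format)
  out <- if (format == "text") {
    format_report_text(report, case_id)
  } else {
    as.character(jsonlite::toJSON(report_to_list(report, case_id),
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null", pretty = TRUE))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Analyse a batch of cases from a CSV or JSON file
#'
#' Runs [abg_interpret()] on every record. A case that fails
#' validation (including Henderson-Hasselbalch rejection) is a result,
#' not an error: its report carries the findings and the summary marks
#' it rejected.
#'
#' @param input Path to a `.csv` or `.json` batch (see
#'   [read_abg_cases()]).
#' @param config Optional path to a YAML/JSON configuration file (see
#'   [read_abg_config()]).
#' @param out Optional path for a JSON file holding all reports.
#' @return A list with `reports` (named by case_id) and `summary`, a
#'   data.frame with columns `case_id`, `rejected`, `n_approaches`,
#'   `compliance_pct`, and one diagnosis column per approach.
#' @export
abg_batch <- function(input, config = NULL, out = NULL) {
  ranges <- if (is.null(config)) abg_ranges() else read_abg_config(config)
  records <- read_abg_cases(input)
  reports <- list()
  rows <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$case_id[i]
    if (is.na(id)) id <- paste0("case_", i)
    rep_i <- tryCatch({
      panel <- panel_from_record(records[i, , drop = FALSE])
      abg_interpret(panel, ranges)
    }, error = function(e) {
      structure(list(panel = NULL,
                     validation = finding("input_error", "reject",
                                          conditionMessage(e)),
                     results = list(), skipped = c(all = "input error"),
                     compliance_pct = NA_real_),
                class = "abg_report")
    })
    reports[[id]] <- rep_i
    row <- list(case_id = id,
                rejected = any(rep_i$validation$severity == "reject"),
                n_approaches = length(rep_i$results),
                compliance_pct = rep_i$compliance_pct)
    for (a in .approaches) {
      row[[a]] <- if (a %in% names(rep_i$results)) {
        render_result_sentence(rep_i$results[[a]])
      } else {
        NA_character_
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(case_id = character(0), rejected = logical(0),
               n_approaches = integer(0), compliance_pct = numeric(0))
  }
  if (!is.null(out)) {
    payload <- lapply(names(reports), function(id) {
      report_to_list(reports[[id]], case_id = id)
    })
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  list(reports = reports, summary = summary)
}
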