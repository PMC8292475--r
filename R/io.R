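# Reader / writer for the standardized dataset as delimited text (CSV per
# RFC 4180, or TSV), UTF-8, header row mandatory. The ten canonical columns
# follow the published table layout; two machine-readability extensions
# carry the structured agent list and the primary identifier, and a third
# optional extension preserves the pre-planned-continuation flag so that a
# written file reads back to an identical history.

.col_canon <- c(
  serial   = "Serial No.",
  setting  = "Clinical setting",
  intent   = "Treatment intent",
  cpd      = "Date of most recent clinical progression of disease (cPD)",
  modality = "Anti-cancer modality",
  start    = "Start date",
  stop     = "Stop date",
  reason   = "Reason for stopping",
  comments = "Comments",
  label    = "Line of therapy N (CLoT + PLoT)",
  agents   = "Agents",
  primary  = "Primary ID",
  preplanned = "Preplanned with previous"
)

.norm_header <- function(h) gsub("[^a-z]", "", tolower(h))

# Map actual headers to canonical keys; returns named integer index vector.
.match_columns <- function(headers) {
  norm <- .norm_header(headers)
  find <- function(patterns, exact = FALSE) {
    for (p in patterns) {
      hit <- if (exact) which(norm == p) else which(grepl(p, norm, fixed = TRUE))
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  c(
    serial   = find(c("serialno", "serial"), exact = TRUE) %|NA|% find("serial"),
    setting  = find("clinicalsetting") %|NA|% find(c("setting"), exact = TRUE),
    intent   = find("intent"),
    cpd      = find("cpd") %|NA|% find("progression"),
    modality = find("modality"),
    start    = find(c("startdate", "start"), exact = TRUE),
    stop     = find(c("stopdate", "stop", "enddate"), exact = TRUE),
    reason   = find("reason"),
    comments = find(c("comments", "comment"), exact = TRUE),
    label    = find("lineoftherapy") %|NA|% find(c("lot"), exact = TRUE),
    agents   = find(c("agents"), exact = TRUE),
    primary  = find("primaryid") %|NA|% find(c("primary"), exact = TRUE),
    preplanned = find("preplanned")
  )
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

# "name|class|category|flags" entries separated by ";".
.parse_agents_cell <- function(cell) {
  cell <- trimws(cell %||% "")
  if (is.na(cell) || !nzchar(cell)) return(list(agents = list(), error = NULL))
  entries <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  agents <- list()
  for (e in entries) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    f <- c(trimws(f), rep("", max(0, 4 - length(f))))
    if (!nzchar(f[1])) return(list(agents = NULL, error = sprintf("agent entry without a name: '%s'", e)))
    category <- if (nzchar(f[3])) f[3] else "v"
    if (!category %in% names(.lot_subcategories)) {
      return(list(agents = NULL,
                  error = sprintf("unknown SACT subcategory '%s' in agent entry '%s'", f[3], e)))
    }
    flags <- tolower(strsplit(f[4], "[,[:space:]]+")[[1]])
    flags <- flags[nzchar(flags)]
    known <- c("experimental", "supportive", "supportive_only", "placebo",
               "subtherapeutic", "sub-therapeutic")
    unknown <- setdiff(flags, known)
    if (length(unknown)) {
      return(list(agents = NULL,
                  error = sprintf("unknown agent flag(s) %s in entry '%s'",
                                  paste(unknown, collapse = ", "), e)))
    }
    agents[[length(agents) + 1L]] <- agent_record(
      name = f[1],
      class = if (nzchar(f[2])) f[2] else NA_character_,
      category = category,
      experimental = "experimental" %in% flags,
      supportive_only = any(c("supportive", "supportive_only") %in% flags),
      placebo = "placebo" %in% flags,
      clinically_relevant = !any(c("subtherapeutic", "sub-therapeutic") %in% flags)
    )
  }
  list(agents = agents, error = NULL)
}

.serialize_agents <- function(agents) {
  if (!length(agents)) return("")
  paste(vapply(agents, function(a) {
    flags <- c(if (a$experimental) "experimental",
               if (a$supportive_only) "supportive",
               if (a$placebo) "placebo",
               if (!a$clinically_relevant) "subtherapeutic")
    paste(a$name,
          if (is.na(a$class)) "" else a$class,
          a$category,
          paste(flags, collapse = " "),
          sep = "|")
  }, ""), collapse = ";")
}

# Modality cell: codes 5A-5E anywhere in the cell; 5A/5B take the roman
# subcategories that follow them (before the next code). Accepts both the
# canonical "5A: i, ii; 5C" and looser renderings such as
# "5A: i, ii SACT: Cytotoxic, Endocrine 5C: Surgery".
.parse_modalities_cell <- function(cell) {
  cell <- trimws(cell %||% "")
  if (is.na(cell) || !nzchar(cell)) {
    return(list(modalities = NULL, error = "empty anti-cancer modality cell"))
  }
  locs <- gregexpr("5[A-E]", cell)[[1]]
  if (locs[1] == -1L) {
    return(list(modalities = NULL,
                error = sprintf("no modality code (5A-5E) found in '%s'", cell)))
  }
  out <- character()
  ends <- c(locs[-1] - 1L, nchar(cell))
  for (k in seq_along(locs)) {
    code <- substr(cell, locs[k], locs[k] + 1L)
    if (code %in% c("5C", "5D", "5E")) {
      out <- c(out, code)
    } else {
      rest <- substr(cell, locs[k] + 2L, ends[k])
      subs <- regmatches(rest, gregexpr("\\b(iv|iii|ii|i|v)\\b", rest))[[1]]
      subs <- unique(subs)
      if (!length(subs)) {
        return(list(modalities = NULL, error = sprintf(
          "modality %s requires a subcategory (i-v) in '%s'", code, cell)))
      }
      out <- c(out, paste0(code, ":", subs))
    }
  }
  list(modalities = unique(out), error = NULL)
}

.serialize_modalities <- function(modalities) {
  syst <- grep("^5[AB]:", modalities, value = TRUE)
  local <- setdiff(modalities, syst)
  parts <- character()
  for (code in c("5A", "5B")) {
    subs <- sub("^5[AB]:", "", grep(paste0("^", code, ":"), syst, value = TRUE))
    if (length(subs)) parts <- c(parts, paste0(code, ": ", paste(subs, collapse = ", ")))
  }
  paste(c(parts, sort(local)), collapse = "; ")
}

#' Read a standardized treatment-history file
#'
#' Reads a delimited (CSV or TSV, UTF-8) rendering of the standardized
#' dataset. The header must contain the canonical columns Serial No.,
#' Clinical setting, Treatment intent, the cPD date column, Anti-cancer
#' modality, Start date, Stop date, Reason for stopping, Comments, and the
#' machine-readability extension `Agents` (semicolon-separated
#' `name|class|category|flags` entries). `Primary ID`,
#' `Preplanned with previous` and the label column are optional on input
#' (the label is the engine's output and is ignored when present). Coded
#' cells are parsed leniently: `"2A Early"`, `"2A"` and `"Early"` all map
#' to the early-setting code, and a modality cell may mix codes with prose
#' (`"5A: i, ii SACT: Cytotoxic, Endocrine 5C: Surgery"`).
#'
#' @param path Path to the file.
#' @param dialect Date dialect: `"auto"` (default), `"paper"`
#'   (`YYYY MMM DD`) or `"iso8601"`.
#' @param delimiter `"comma"` or `"tab"`.
#' @param patient_id Identifier for the returned history.
#' @return A list with elements `history` (a [patient_history()]) and
#'   `report` (a `"lot_validation"` data frame combining per-row parse
#'   issues with the [validate_history()] report). Unparseable rows are
#'   dropped from the history and reported as `ERROR`s.
#' @section Errors: A missing required column is a hard error naming the
#'   column; cell-level problems are returned in the report instead.
#' @examples
#' path <- system.file("extdata", "breast_example.csv", package = "lotengine")
#' res <- read_history(path)
#' length(res$history)
#' @export
read_history <- function(path, dialect = c("auto", "paper", "iso8601"),
                         delimiter = c("comma", "tab"),
                         patient_id = "patient") {
  dialect <- match.arg(dialect)
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "comma") "," else "\t"
  if (!file.exists(path)) {
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           comment.char = "", na.strings = NULL)
  idx <- .match_columns(names(raw))
  required <- c("serial", "setting", "intent", "cpd", "modality",
                "start", "stop", "reason", "comments", "agents")
  missing <- required[is.na(idx[required])]
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s",
                 paste(.col_canon[missing], collapse = "; ")), call. = FALSE)
  }

  issues <- list(.empty_report())
  err <- function(row, serial, msg) {
    issues[[length(issues) + 1L]] <<-
      .issue("ERROR", serial, sprintf("row %d: %s", row, msg))
  }

  cell <- function(i, key) {
    if (is.na(idx[[key]])) "" else trimws(raw[i, idx[[key]]])
  }

  segments <- list()
  for (i in seq_len(nrow(raw))) {
    serial <- suppressWarnings(as.integer(cell(i, "serial")))
    if (is.na(serial) || serial < 1L) {
      err(i, NA, sprintf("unparseable serial number '%s'", cell(i, "serial")))
      next
    }

    setting <- .parse_code(cell(i, "setting"), .lot_settings)
    if (.code_invalid(setting)) {
      err(i, serial, sprintf("unrecognized clinical setting '%s'", cell(i, "setting")))
      setting <- NA_character_
    }
    intent <- .parse_code(cell(i, "intent"), .lot_intents)
    if (.code_invalid(intent)) {
      err(i, serial, sprintf("unrecognized treatment intent '%s'", cell(i, "intent")))
      intent <- NA_character_
    }
    reason <- .parse_code(cell(i, "reason"), .lot_stop_reasons)
    if (.code_invalid(reason)) {
      err(i, serial, sprintf("unrecognized stop reason '%s'", cell(i, "reason")))
      reason <- NA_character_
    }

    dates <- list(cpd = as.Date(NA), start = as.Date(NA), stop = as.Date(NA))
    date_ok <- TRUE
    for (key in names(dates)) {
      d <- tryCatch(parse_date(cell(i, key), dialect), error = function(e) e)
      if (inherits(d, "error")) {
        err(i, serial, conditionMessage(d))
        date_ok <- FALSE
      } else {
        dates[[key]] <- d
      }
    }

    mods <- .parse_modalities_cell(cell(i, "modality"))
    if (!is.null(mods$error)) {
      err(i, serial, mods$error)
      next
    }
    ag <- .parse_agents_cell(cell(i, "agents"))
    if (!is.null(ag$error)) {
      err(i, serial, ag$error)
      next
    }
    if (!date_ok) next

    pre_cell <- tolower(cell(i, "preplanned"))
    preplanned <- pre_cell %in% c("true", "yes", "1", "t", "y")
    if (nzchar(pre_cell) && !pre_cell %in%
        c("true", "yes", "1", "t", "y", "false", "no", "0", "f", "n")) {
      err(i, serial, sprintf("unrecognized pre-planned flag '%s'", pre_cell))
      next
    }

    primary <- cell(i, "primary")
    segments[[length(segments) + 1L]] <- therapy_segment(
      serial_no = serial,
      primary_id = if (nzchar(primary)) primary else "P1",
      clinical_setting = setting,
      treatment_intent = intent,
      cpd_date = dates$cpd,
      modalities = mods$modalities,
      agents = ag$agents,
      start_date = dates$start,
      stop_date = dates$stop,
      stop_reason = reason,
      preplanned_with_previous = preplanned,
      comments = cell(i, "comments")
    )
  }

  history <- patient_history(segments, patient_id = patient_id)
  parse_report <- do.call(rbind, issues)
  report <- rbind(parse_report, as.data.frame(validate_history(history)))
  list(history = history, report = .as_validation(report))
}

#' Write an annotated (or plain) history as a standardized dataset file
#'
#' Writes the canonical columns in the published order, with the label
#' column filled by [format_label()] for qualifying segments and left
#' empty for skipped ones, followed by the `Agents`, `Primary ID` and
#' `Preplanned with previous` extension columns. Dates are serialized in
#' the dialect's canonical form (`"2000 Jan 01"` or ISO). An absent cPD
#' date is written as `"NA"` (matching the published rendering); absent
#' stop dates/reasons are written as empty strings. The writer preserves
#' the (chronological) segment order and never re-sorts serial numbers, so
#' output stays auditable against source records, and
#' `read_history(write_annotated(x))` reproduces every typed field of `x`.
#'
#' @param x An `"lot_annotated"` object from [assign_lines()], or a bare
#'   [patient_history()] (label column then left empty).
#' @param path Output file path.
#' @param dialect `"paper"` (default) or `"iso8601"` date serialization.
#' @param delimiter `"comma"` or `"tab"`.
#' @return `x`, invisibly.
#' @export
write_annotated <- function(x, path, dialect = c("paper", "iso8601"),
                            delimiter = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  delimiter <- match.arg(delimiter)
  history <- if (inherits(x, "lot_annotated")) x$history else x
  stopifnot(inherits(history, "lot_history"))
  labels <- if (inherits(x, "lot_annotated")) {
    stats::setNames(x$assignments$label, as.character(x$assignments$serial_no))
  } else {
    character()
  }

  rows <- lapply(history$segments, function(s) {
    data.frame(
      check.names = FALSE, stringsAsFactors = FALSE,
      `Serial No.` = s$serial_no,
      `Clinical setting` = if (is.na(s$clinical_setting)) "" else
        paste(s$clinical_setting, .lot_settings[[s$clinical_setting]]),
      `Treatment intent` = if (is.na(s$treatment_intent)) "" else
        paste(s$treatment_intent, .lot_intents[[s$treatment_intent]]),
      `Date of most recent clinical progression of disease (cPD)` =
        .format_date(s$cpd_date, dialect, absent = "NA"),
      `Anti-cancer modality` = .serialize_modalities(s$modalities),
      `Start date` = .format_date(s$start_date, dialect),
      `Stop date` = .format_date(s$stop_date, dialect),
      `Reason for stopping` = if (is.na(s$stop_reason)) "" else
        paste(s$stop_reason, .lot_stop_reasons[[s$stop_reason]]),
      `Comments` = s$comments,
      `Line of therapy N (CLoT + PLoT)` =
        labels[as.character(s$serial_no)] %|NA|% "",
      `Agents` = .serialize_agents(s$agents),
      `Primary ID` = s$primary_id,
      `Preplanned with previous` = tolower(as.character(s$preplanned_with_previous))
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else {
    as.data.frame(stats::setNames(rep(list(character()), length(.col_canon)),
                                  unname(.col_canon[c("serial", "setting", "intent", "cpd",
                                                      "modality", "start", "stop", "reason",
                                                      "comments", "label", "agents",
                                                      "primary", "preplanned")])),
                  check.names = FALSE)
  }
  sep <- if (delimiter == "comma") "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double",
                     fileEncoding = "UTF-8", quote = TRUE)
  invisible(x)
}
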