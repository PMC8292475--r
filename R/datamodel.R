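#' lotengine: deterministic enumeration of lines of therapy in solid cancers
#'
#' Tools to represent standardized treatment histories of patients with
#' solid cancers, decide which therapy segments qualify as systemic
#' anti-cancer therapy (SACT), group segments into lines of therapy (LoT)
#' under a transparent rule cascade, and report each line in the cumulative
#' `N (CLoT + PLoT)` format, where CLoT counts curative-track lines, PLoT
#' counts palliative-track lines and N is their sum.
#'
#' The main entry points are [read_history()] to ingest a delimited dataset,
#' [assign_lines()] to enumerate lines, [write_annotated()] to export the
#' annotated table, and [generate_history()] to simulate histories with
#' known ground truth.
#'
#' @keywords internal
"_PACKAGE"

# ---- coded vocabularies -----------------------------------------------------

# Clinical setting: maximum extent of spread experienced to date.
.lot_settings <- c(
  "2A" = "Early",
  "2B" = "Locally advanced",
  "2C" = "Metastatic"
)

# Treatment intent in the opinion of the treating clinician.
.lot_intents <- c(
  "3A" = "Curative",
  "3B" = "Palliative"
)

# Anti-cancer modality. 5A/5B carry a roman subcategory (i-v).
.lot_modalities <- c(
  "5A" = "SACT",
  "5B" = "Experimental SACT",
  "5C" = "Surgery",
  "5D" = "Radiotherapy",
  "5E" = "Other"
)

# SACT subcategories for modality codes 5A and 5B.
.lot_subcategories <- c(
  "i"   = "Cytotoxic",
  "ii"  = "Endocrine",
  "iii" = "Targeted",
  "iv"  = "Immunotherapy",
  "v"   = "Other"
)

# Reason the therapy segment stopped.
.lot_stop_reasons <- c(
  "8A" = "cPD",
  "8B" = "Completed",
  "8C" = "Toxicity",
  "8D" = "Choice",
  "8E" = "Death",
  "8F" = "Other"
)

#' Coded vocabularies of the standardized dataset
#'
#' Returns the named code-to-label vector for one of the five coded
#' vocabularies used by the dataset: clinical setting (`2A`-`2C`), treatment
#' intent (`3A`/`3B`), anti-cancer modality (`5A`-`5E`), SACT subcategory
#' (`i`-`v`) and stop reason (`8A`-`8F`).
#'
#' @param which One of `"setting"`, `"intent"`, `"modality"`,
#'   `"subcategory"`, `"stop_reason"`.
#' @return Named character vector; names are codes, values human labels.
#' @examples
#' lot_vocabulary("setting")
#' @export
lot_vocabulary <- function(which = c("setting", "intent", "modality",
                                     "subcategory", "stop_reason")) {
  which <- match.arg(which)
  switch(which,
    setting     = .lot_settings,
    intent      = .lot_intents,
    modality    = .lot_modalities,
    subcategory = .lot_subcategories,
    stop_reason = .lot_stop_reasons
  )
}

# Lenient single-cell code parser shared by the reader: a leading code wins,
# otherwise the human label is matched case-insensitively. Returns the code,
# NA_character_ for an empty cell, or a "lot_parse_error" condition message
# attached as an attribute when the cell is unrecognizable.
.parse_code <- function(cell, vocab) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_character_)
  cell <- trimws(cell)
  codes <- names(vocab)
  pat <- paste0("^(", paste(codes, collapse = "|"), ")\\b")
  m <- regmatches(cell, regexpr(pat, cell))
  if (length(m) == 1L) return(m)
  hit <- which(vapply(vocab, function(lbl)
    grepl(paste0("^", lbl, "$"), cell, ignore.case = TRUE), logical(1)))
  if (length(hit) == 1L) return(codes[hit])
  structure(NA_character_, invalid = cell)
}

.code_invalid <- function(x) !is.null(attr(x, "invalid"))

# ---- dates ------------------------------------------------------------------

#' Parse a date of the standardized dataset
#'
#' Dates in the standardized dataset are day-resolution and written
#' `"YYYY MMM DD"` with English three-letter month abbreviations
#' (e.g. `"2021 Jan 01"`). ISO-8601 `"YYYY-MM-DD"` is accepted as an
#' alternative dialect. Month names are resolved against R's built-in
#' English [month.abb] constant so parsing does not depend on the locale.
#'
#' @param text A single string; the literal `"NA"` (optionally followed by a
#'   parenthetical note) or an empty string denotes an absent date.
#' @param dialect `"paper"` for `"YYYY MMM DD"`, `"iso8601"` for
#'   `"YYYY-MM-DD"`, or `"auto"` (default) to try both in that order.
#' @return A [Date], or `NA` (of class Date) when the date is absent.
#' @examples
#' parse_date("2000 Jan 01")
#' parse_date("2019-06-22", dialect = "iso8601")
#' parse_date("NA")
#' @export
parse_date <- function(text, dialect = c("auto", "paper", "iso8601")) {
  dialect <- match.arg(dialect)
  if (length(text) != 1L) stop("parse_date() expects a single string")
  if (is.na(text)) return(as.Date(NA))
  text <- trimws(text)
  if (!nzchar(text) || grepl("^NA\\b", text)) return(as.Date(NA))

  try_paper <- function(x) {
    m <- regmatches(x, regexec("^(\\d{4})\\s+([A-Za-z]{3})\\s+(\\d{1,2})$", x))[[1]]
    if (length(m) == 0L) return(as.Date(NA))
    mon <- match(tolower(m[3]), tolower(month.abb))
    if (is.na(mon)) return(as.Date(NA))
    as.Date(sprintf("%s-%02d-%02d", m[2], mon, as.integer(m[4])),
            format = "%Y-%m-%d")
  }
  try_iso <- function(x) {
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) return(as.Date(NA))
    as.Date(x, format = "%Y-%m-%d")
  }

  out <- switch(dialect,
    paper   = try_paper(text),
    iso8601 = try_iso(text),
    auto    = {
      d <- try_paper(text)
      if (is.na(d)) d <- try_iso(text)
      d
    }
  )
  if (is.na(out)) {
    expected <- switch(dialect,
      paper   = "'YYYY MMM DD'",
      iso8601 = "'YYYY-MM-DD'",
      auto    = "'YYYY MMM DD' or 'YYYY-MM-DD'"
    )
    stop(sprintf("cannot parse date '%s' (expected %s)", text, expected),
         call. = FALSE)
  }
  out
}

# Serialize a Date in a dialect's canonical form; absent dates render as
# `absent` (the reader accepts both "" and "NA").
.format_date <- function(d, dialect = "paper", absent = "") {
  if (is.na(d)) return(absent)
  lt <- as.POSIXlt(d)
  if (dialect == "iso8601") return(format(d, "%Y-%m-%d"))
  sprintf("%04d %s %02d", lt$year + 1900L, month.abb[lt$mon + 1L], lt$mday)
}

# ---- agents -----------------------------------------------------------------

#' Describe one anti-cancer agent within a therapy segment
#'
#' An agent record carries the facts the rule engine needs: the drug name,
#' its (free-text) pharmacological class used for same-class substitution
#' decisions, the SACT subcategory code, and flags asserting whether the
#' agent was experimental (unapproved for any cancer at the start date),
#' given for supportive/symptomatic care only, a blinded placebo, or given
#' below a clinically relevant exposure. All flags are caller-asserted
#' clinical facts, never inferred.
#'
#' @param name Drug name (free text, non-empty).
#' @param class Pharmacological class, e.g. `"taxane"`; `NA` when unknown.
#' @param category SACT subcategory code `"i"` (cytotoxic), `"ii"`
#'   (endocrine), `"iii"` (targeted), `"iv"` (immunotherapy) or `"v"` (other).
#' @param experimental `TRUE` if the agent lacked FDA/EMA approval for any
#'   cancer when therapy started.
#' @param supportive_only `TRUE` when the agent was used for supportive or
#'   symptomatic care (such agents never count toward a line).
#' @param placebo `TRUE` for a blinded placebo; model unblinding by setting
#'   this back to `FALSE`.
#' @param clinically_relevant `FALSE` when, in the clinician's opinion, the
#'   dose/duration could not exert a systemic anti-cancer effect.
#' @return An object of class `"lot_agent"`.
#' @examples
#' agent_record("paclitaxel", class = "taxane", category = "i")
#' @export
agent_record <- function(name, class = NA_character_, category = "v",
                         experimental = FALSE, supportive_only = FALSE,
                         placebo = FALSE, clinically_relevant = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(class) || !nzchar(trimws(as.character(class) %||% ""))) {
    class <- NA_character_
  }
  category <- as.character(category)
  if (!category %in% names(.lot_subcategories)) {
    stop(sprintf("unknown SACT subcategory '%s' for agent '%s'", category, name),
         call. = FALSE)
  }
  structure(
    list(
      name = name,
      class = as.character(class),
      category = category,
      experimental = isTRUE(experimental),
      supportive_only = isTRUE(supportive_only),
      placebo = isTRUE(placebo),
      clinically_relevant = !isFALSE(clinically_relevant)
    ),
    class = "lot_agent"
  )
}

#' @export
print.lot_agent <- function(x, ...) {
  flags <- c(
    if (x$experimental) "experimental",
    if (x$supportive_only) "supportive-only",
    if (x$placebo) "placebo",
    if (!x$clinically_relevant) "sub-therapeutic"
  )
  cat(sprintf("<agent> %s [%s, %s]%s\n", x$name,
              if (is.na(x$class)) "class unknown" else x$class,
              x$category,
              if (length(flags)) paste0(" (", paste(flags, collapse = ", "), ")") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.norm_name <- function(x) tolower(trimws(x))

# ---- therapy segments -------------------------------------------------------

.valid_modality <- function(m) {
  grepl("^5[CDE]$", m) | grepl("^5[AB]:(i|ii|iii|iv|v)$", m)
}

#' Construct one therapy segment (one row of the standardized dataset)
#'
#' A segment is a contiguous period of one therapeutic approach, possibly a
#' pre-planned multimodal sequence (e.g. neoadjuvant chemotherapy followed
#' by surgery, radiotherapy and endocrine therapy recorded as a single
#' row). Cross-field consistency (stop before start, progression date after
#' start, SACT without agents, ...) is checked by [validate_history()], not
#' here, so that imperfect real-world records can be represented and
#' audited.
#'
#' @param serial_no Positive integer, unique within a history.
#' @param start_date,stop_date [Date]s; `stop_date = NA` means ongoing.
#' @param modalities Character vector of modality codes: `"5C"`, `"5D"`,
#'   `"5E"`, or `"5A:<sub>"`/`"5B:<sub>"` with subcategory `i`-`v`
#'   (e.g. `c("5A:i", "5A:ii", "5C", "5D")`).
#' @param clinical_setting `"2A"` early, `"2B"` locally advanced, `"2C"`
#'   metastatic.
#' @param treatment_intent `"3A"` curative, `"3B"` palliative, or `NA` when
#'   not recorded.
#' @param cpd_date Date of the most recent clinical progression of disease
#'   (cPD) preceding this segment; `NA` at initial diagnosis.
#' @param stop_reason Stop-reason code `"8A"`-`"8F"`, or `NA` while ongoing.
#' @param agents List of [agent_record()] objects (may be empty for
#'   surgery/radiotherapy-only segments).
#' @param preplanned_with_previous `TRUE` marks this segment as a
#'   prospectively planned continuation of the previous segment's SACT
#'   (e.g. switch maintenance), which retains the line.
#' @param primary_id Identifier of the primary organ this segment treats;
#'   lines are numbered independently per primary.
#' @param comments Free text; never interpreted by the engine.
#' @return An object of class `"lot_segment"`.
#' @examples
#' therapy_segment(1, parse_date("2015 Feb 07"),
#'   modalities = "5A:ii", clinical_setting = "2B", treatment_intent = "3B",
#'   cpd_date = parse_date("2015 Feb 01"),
#'   stop_date = parse_date("2016 Sep 19"), stop_reason = "8A",
#'   agents = list(agent_record("anastrozole", "aromatase inhibitor", "ii")))
#' @export
therapy_segment <- function(serial_no, start_date, modalities,
                            clinical_setting, treatment_intent = NA_character_,
                            cpd_date = as.Date(NA), stop_date = as.Date(NA),
                            stop_reason = NA_character_, agents = list(),
                            preplanned_with_previous = FALSE,
                            primary_id = "P1", comments = "") {
  serial_no <- as.integer(serial_no)
  stopifnot(length(serial_no) == 1L, !is.na(serial_no), serial_no >= 1L)
  start_date <- as.Date(start_date)
  stop_date <- as.Date(stop_date)
  cpd_date <- as.Date(cpd_date)

  modalities <- unique(as.character(modalities))
  if (length(modalities) == 0L) stop("a segment needs at least one modality code")
  bad <- modalities[!.valid_modality(modalities)]
  if (length(bad)) {
    stop(sprintf("invalid modality code(s): %s (5A/5B require a subcategory, e.g. '5A:i')",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  if (!is.na(clinical_setting) && !clinical_setting %in% names(.lot_settings)) {
    stop(sprintf("unknown clinical setting code '%s'", clinical_setting), call. = FALSE)
  }
  if (!is.na(treatment_intent) && !treatment_intent %in% names(.lot_intents)) {
    stop(sprintf("unknown treatment intent code '%s'", treatment_intent), call. = FALSE)
  }
  if (!is.na(stop_reason) && !stop_reason %in% names(.lot_stop_reasons)) {
    stop(sprintf("unknown stop reason code '%s'", stop_reason), call. = FALSE)
  }
  if (!all(vapply(agents, inherits, logical(1), "lot_agent"))) {
    stop("`agents` must be a list of agent_record() objects", call. = FALSE)
  }

  structure(
    list(
      serial_no = serial_no,
      primary_id = as.character(primary_id),
      clinical_setting = as.character(clinical_setting),
      treatment_intent = as.character(treatment_intent),
      cpd_date = cpd_date,
      modalities = modalities,
      agents = agents,
      start_date = start_date,
      stop_date = stop_date,
      stop_reason = as.character(stop_reason),
      preplanned_with_previous = isTRUE(preplanned_with_previous),
      comments = as.character(comments)
    ),
    class = "lot_segment"
  )
}

# TRUE when the segment carries any systemic modality (5A or 5B).
.has_sact_modality <- function(segment) {
  any(grepl("^5[AB]:", segment$modalities))
}

# Agents that can count toward a line: anti-cancer exposure that is neither
# supportive-only nor blinded placebo nor sub-therapeutic.
.counted_agents <- function(segment) {
  Filter(function(a) !a$supportive_only && !a$placebo && a$clinically_relevant,
         segment$agents)
}

#' @export
print.lot_segment <- function(x, ...) {
  cat(sprintf("<segment %d> [%s] %s/%s %s -> %s %s\n",
              x$serial_no, x$primary_id,
              x$clinical_setting, x$treatment_intent,
              .format_date(x$start_date, absent = "?"),
              .format_date(x$stop_date, absent = "ongoing"),
              paste(x$modalities, collapse = " ")))
  if (length(x$agents)) {
    cat("  agents:", paste(vapply(x$agents, `[[`, "", "name"), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- patient history --------------------------------------------------------

#' Assemble a patient history from therapy segments
#'
#' Segments are sorted chronologically by start date, ties broken by serial
#' number ascending, which makes enumeration reproducible when two segments
#' start the same day.
#'
#' @param segments List of [therapy_segment()] objects.
#' @param patient_id Identifier for the patient.
#' @return An object of class `"lot_history"`.
#' @export
patient_history <- function(segments = list(), patient_id = "patient") {
  if (!all(vapply(segments, inherits, logical(1), "lot_segment"))) {
    stop("`segments` must be a list of therapy_segment() objects", call. = FALSE)
  }
  if (length(segments)) {
    starts <- as.Date(vapply(segments, function(s) as.numeric(s$start_date), 0),
                      origin = "1970-01-01")
    serials <- vapply(segments, `[[`, 0L, "serial_no")
    ord <- order(starts, serials, na.last = TRUE)
    segments <- segments[ord]
  }
  structure(list(patient_id = as.character(patient_id), segments = segments),
            class = "lot_history")
}

#' @export
length.lot_history <- function(x) length(x$segments)

#' @export
print.lot_history <- function(x, ...) {
  cat(sprintf("<patient history '%s'> %d segment(s)\n", x$patient_id,
              length(x$segments)))
  for (s in x$segments) print(s)
  invisible(x)
}

#' @export
as.data.frame.lot_history <- function(x, ...) {
  if (!length(x$segments)) {
    return(data.frame(serial_no = integer(), primary_id = character(),
                      clinical_setting = character(), treatment_intent = character(),
                      start_date = as.Date(character()), stop_date = as.Date(character()),
                      stop_reason = character(), n_agents = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$segments, function(s) {
    data.frame(serial_no = s$serial_no, primary_id = s$primary_id,
               clinical_setting = s$clinical_setting,
               treatment_intent = s$treatment_intent,
               start_date = s$start_date, stop_date = s$stop_date,
               stop_reason = s$stop_reason, n_agents = length(s$agents),
               stringsAsFactors = FALSE)
  }))
}

# ---- validation -------------------------------------------------------------

.issue <- function(severity, serial_no, message) {
  data.frame(severity = severity,
             serial_no = if (is.null(serial_no)) NA_integer_ else as.integer(serial_no),
             message = message, stringsAsFactors = FALSE)
}

.empty_report <- function() {
  data.frame(severity = character(), serial_no = integer(),
             message = character(), stringsAsFactors = FALSE)
}

.as_validation <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("lot_validation", "data.frame"))
}

# Structural checks only (no line reconstruction); used by both
# validate_history() and assign_lines().
.validate_structural <- function(history) {
  issues <- list(.empty_report())
  segs <- history$segments
  if (!length(segs)) return(do.call(rbind, issues))

  serials <- vapply(segs, `[[`, 0L, "serial_no")
  dup <- unique(serials[duplicated(serials)])
  for (d in dup) {
    issues[[length(issues) + 1L]] <-
      .issue("ERROR", d, sprintf("serial number %d is not unique within the history", d))
  }

  for (s in segs) {
    if (is.na(s$start_date)) {
      issues[[length(issues) + 1L]] <-
        .issue("ERROR", s$serial_no, "missing start date")
    }
    if (is.na(s$clinical_setting)) {
      issues[[length(issues) + 1L]] <-
        .issue("ERROR", s$serial_no, "missing or unrecognized clinical setting")
    }
    if (!is.na(s$stop_date) && !is.na(s$start_date) && s$stop_date < s$start_date) {
      issues[[length(issues) + 1L]] <-
        .issue("ERROR", s$serial_no, sprintf(
          "stop date %s precedes start date %s",
          .format_date(s$stop_date), .format_date(s$start_date)))
    }
    if (!is.na(s$cpd_date) && !is.na(s$start_date) && s$cpd_date > s$start_date) {
      issues[[length(issues) + 1L]] <-
        .issue("ERROR", s$serial_no,
               "cPD date is after the segment start (the column records the progression preceding the therapy)")
    }
    if (.has_sact_modality(s) && length(s$agents) == 0L) {
      issues[[length(issues) + 1L]] <-
        .issue("ERROR", s$serial_no, "systemic modality (5A/5B) but no agents recorded")
    }
    if (!is.na(s$stop_reason) && is.na(s$stop_date)) {
      issues[[length(issues) + 1L]] <-
        .issue("ERROR", s$serial_no, "stop reason recorded without a stop date")
    }
    if (is.na(s$stop_reason) && !is.na(s$stop_date)) {
      issues[[length(issues) + 1L]] <-
        .issue("WARNING", s$serial_no, "stop date recorded without a stop reason")
    }
    if (is.na(s$treatment_intent)) {
      issues[[length(issues) + 1L]] <-
        .issue("WARNING", s$serial_no,
               "treatment intent not recorded; track will default from the clinical setting")
    }
  }

  # cPD dates must be non-decreasing within one primary (the column records
  # the *most recent* progression, which can only move forward in time).
  by_primary <- split(segs, vapply(segs, `[[`, "", "primary_id"))
  for (pseg in by_primary) {
    last_cpd <- as.Date(NA)
    last_serial <- NA_integer_
    for (s in pseg) {
      if (!is.na(s$cpd_date)) {
        if (!is.na(last_cpd) && s$cpd_date < last_cpd) {
          issues[[length(issues) + 1L]] <-
            .issue("ERROR", s$serial_no, sprintf(
              "cPD date moves backwards relative to segment %d within primary '%s'",
              last_serial, s$primary_id))
        }
        last_cpd <- s$cpd_date
        last_serial <- s$serial_no
      }
    }
    # A segment stopped for progression (8A) should be followed by a later
    # documented cPD date somewhere downstream; its absence is suspicious
    # but does not block enumeration.
    for (k in seq_along(pseg)) {
      s <- pseg[[k]]
      if (identical(s$stop_reason, "8A") && k < length(pseg)) {
        later <- pseg[(k + 1L):length(pseg)]
        ref <- if (!is.na(s$cpd_date)) s$cpd_date else as.Date("0001-01-01")
        has_later <- any(vapply(later, function(z)
          !is.na(z$cpd_date) && z$cpd_date > ref, logical(1)))
        if (!has_later) {
          issues[[length(issues) + 1L]] <-
            .issue("WARNING", s$serial_no,
                   "stopped for cPD (8A) but no later cPD date is documented downstream")
        }
      }
    }
  }

  do.call(rbind, issues)
}

#' Validate a patient history against the dataset invariants
#'
#' Checks every cross-field invariant of the standardized dataset:
#' chronology (stop before start, cPD after start, backwards-moving cPD
#' dates), uniqueness of serial numbers, systemic segments without agents,
#' and stop-reason bookkeeping. `ERROR`-severity issues block enumeration by
#' [assign_lines()]; `WARNING`-severity issues (missing intent, a segment
#' stopped for progression with no later cPD on record, a continuing
#' segment whose intent differs from its line's opening segment) do not.
#'
#' The function is pure: problems are returned in the report, never thrown.
#'
#' @param history A [patient_history()].
#' @param config An [lot_config()]; used only to reconstruct lines for the
#'   warning-level line-consistency checks.
#' @return A data frame of class `"lot_validation"` with columns
#'   `severity`, `serial_no`, `message`.
#' @seealso [assign_lines()]
#' @export
validate_history <- function(history, config = lot_config()) {
  stopifnot(inherits(history, "lot_history"))
  rep <- .validate_structural(history)
  if (!any(rep$severity == "ERROR") && length(history$segments)) {
    fold <- .engine_fold(history, config)
    if (nrow(fold$warnings)) {
      rep <- rbind(rep,
                   data.frame(severity = "WARNING",
                              serial_no = fold$warnings$serial_no,
                              message = fold$warnings$message,
                              stringsAsFactors = FALSE))
    }
  }
  # intent warnings from the structural pass duplicate the fold's
  # track-default warnings; keep one copy of identical rows.
  rep <- rep[!duplicated(rep[c("severity", "serial_no", "message")]), , drop = FALSE]
  .as_validation(rep)
}

#' @export
print.lot_validation <- function(x, ...) {
  ne <- sum(x$severity == "ERROR")
  nw <- sum(x$severity == "WARNING")
  cat(sprintf("<validation report> %d error(s), %d warning(s)\n", ne, nw))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %-7s segment %s: %s\n", x$severity[i],
                  ifelse(is.na(x$serial_no[i]), "-", x$serial_no[i]),
                  x$message[i]))
    }
  }
  invisible(x)
}

# Number of blocking issues in a validation report.
.n_errors <- function(report) sum(report$severity == "ERROR")
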