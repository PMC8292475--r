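# Enumerator: folds the rule cascade over a chronological history,
# independently per primary organ, and emits the cumulative
# "N (CLoT + PLoT)" label for every qualifying segment.

#' Format a line-of-therapy label
#'
#' Renders the cumulative label `"N (C + P)"`, e.g. `"5 (2 + 3)"`, where
#' `N` is the line number, `C` the number of curative-track lines and `P`
#' the number of palliative-track lines to date. The identity
#' `N = C + P` is enforced.
#'
#' @param n Line number (positive integer).
#' @param clot,plot Cumulative curative- and palliative-track counts
#'   (non-negative integers).
#' @return A string such as `"5 (2 + 3)"`.
#' @examples
#' format_label(9, 2, 7)
#' @export
format_label <- function(n, clot, plot) {
  n <- as.integer(n); clot <- as.integer(clot); plot <- as.integer(plot)
  stopifnot(length(n) == 1L, length(clot) == 1L, length(plot) == 1L)
  if (is.na(n) || is.na(clot) || is.na(plot) || n < 1L || clot < 0L || plot < 0L) {
    stop("label components must be non-negative integers with n >= 1", call. = FALSE)
  }
  if (n != clot + plot) {
    stop(sprintf("label identity violated: N (%d) != CLoT (%d) + PLoT (%d)",
                 n, clot, plot), call. = FALSE)
  }
  sprintf("%d (%d + %d)", n, clot, plot)
}

.empty_assignments <- function() {
  data.frame(serial_no = integer(), primary_id = character(),
             line_number = integer(), track = character(),
             clot = integer(), plot = integer(), label = character(),
             action = character(), guideline = character(),
             rationale = character(), experimental = logical(),
             clause = character(), stringsAsFactors = FALSE)
}

.empty_skipped <- function() {
  data.frame(serial_no = integer(), primary_id = character(),
             clause = character(), stringsAsFactors = FALSE)
}

.empty_warn <- function() {
  data.frame(serial_no = integer(), message = character(), stringsAsFactors = FALSE)
}

# The core fold. Assumes structural validation has passed (no ERRORs).
# Returns assignments / skipped / warnings data frames. Non-qualifying
# segments are inert: they never touch the per-primary line state, so
# removing them cannot change any label.
.engine_fold <- function(history, config) {
  assignments <- list()
  skipped <- list()
  warnings <- list()
  warn <- function(serial, msg) {
    warnings[[length(warnings) + 1L]] <<-
      data.frame(serial_no = serial, message = msg, stringsAsFactors = FALSE)
  }

  state <- new.env(parent = emptyenv())  # per primary_id: line, clot, plot

  for (seg in history$segments) {
    q <- qualifies_for_lot(seg)
    if (!q$qualifies) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(serial_no = seg$serial_no, primary_id = seg$primary_id,
                   clause = q$clause, stringsAsFactors = FALSE)
      next
    }

    pid <- seg$primary_id
    st <- if (exists(pid, envir = state, inherits = FALSE)) {
      get(pid, envir = state, inherits = FALSE)
    } else {
      list(line = NULL, clot = 0L, plot = 0L)
    }

    decision <- classify_transition(st$line, seg, config)
    if (!is.null(decision$warning)) warn(seg$serial_no, decision$warning)

    if (decision$action == "NEW_LINE") {
      track <- assign_track(seg, config)
      if (!is.null(attr(track, "warning"))) warn(seg$serial_no, attr(track, "warning"))
      track <- as.character(track)
      if (track == "CURATIVE") st$clot <- st$clot + 1L else st$plot <- st$plot + 1L
      st$line <- list(
        line_number = st$clot + st$plot,
        track = track,
        opening_start = seg$start_date,
        opening_intent = seg$treatment_intent,
        current_agents = .counted_agents(seg),
        prev_stop_reason = seg$stop_reason,
        prev_stop_date = seg$stop_date,
        member_serials = seg$serial_no
      )
    } else {
      line <- st$line
      if (!is.na(seg$treatment_intent) && !is.na(line$opening_intent) &&
          seg$treatment_intent != line$opening_intent) {
        warn(seg$serial_no, sprintf(
          "intent (%s) differs from the line's opening segment (%s); the line keeps the track fixed at opening",
          seg$treatment_intent, line$opening_intent))
      }
      line$current_agents <- .counted_agents(seg)
      line$prev_stop_reason <- seg$stop_reason
      line$prev_stop_date <- seg$stop_date
      line$member_serials <- c(line$member_serials, seg$serial_no)
      st$line <- line
    }

    assignments[[length(assignments) + 1L]] <- data.frame(
      serial_no = seg$serial_no, primary_id = pid,
      line_number = st$line$line_number, track = st$line$track,
      clot = st$clot, plot = st$plot,
      label = format_label(st$line$line_number, st$clot, st$plot),
      action = decision$action, guideline = decision$guideline,
      rationale = decision$rationale, experimental = q$experimental,
      clause = q$clause, stringsAsFactors = FALSE
    )
    assign(pid, st, envir = state)
  }

  list(
    assignments = if (length(assignments)) do.call(rbind, assignments) else .empty_assignments(),
    skipped = if (length(skipped)) do.call(rbind, skipped) else .empty_skipped(),
    warnings = if (length(warnings)) do.call(rbind, warnings) else .empty_warn()
  )
}

#' Enumerate lines of therapy over a patient history
#'
#' Processes segments in chronological order, independently per primary
#' organ (each `primary_id` keeps its own N/CLoT/PLoT counters). Every
#' segment is first tested with [qualifies_for_lot()]; non-qualifying
#' segments (surgery, radiotherapy, supportive care, placebo, ...) are
#' recorded as skipped and never influence the line state. Each qualifying
#' segment is classified against the open line with [classify_transition()];
#' a new line takes its track from [assign_track()] and increments CLoT or
#' PLoT, a continuation reuses the open line's number and track. All SACT
#' count, whatever the setting: the counters span the patient's whole
#' recorded journey, early and advanced.
#'
#' @param history A [patient_history()] that passes [validate_history()]
#'   with no `ERROR`-severity issues.
#' @param config An [lot_config()].
#' @return An object of class `"lot_annotated"`: a list with elements
#'   `history`, `assignments` (one row per qualifying segment, with the
#'   label and full rule trace), `skipped` (non-qualifying segments and the
#'   clause that excluded them), `warnings` (character vector) and
#'   `config`.
#' @section Errors: If the history has `ERROR`-severity validation issues
#'   the function refuses to enumerate and signals a condition of class
#'   `"lot_validation_error"` whose `report` field carries the
#'   [validate_history()] report.
#' @examples
#' seg <- therapy_segment(1, parse_date("2015 Feb 07"), "5A:ii",
#'   clinical_setting = "2B", treatment_intent = "3B",
#'   agents = list(agent_record("anastrozole", "aromatase inhibitor", "ii")))
#' assign_lines(patient_history(list(seg)))$assignments$label
#' @export
assign_lines <- function(history, config = lot_config()) {
  stopifnot(inherits(history, "lot_history"), inherits(config, "lot_config"))
  report <- .as_validation(.validate_structural(history))
  if (.n_errors(report) > 0L) {
    cond <- structure(
      class = c("lot_validation_error", "error", "condition"),
      list(message = sprintf(
        "history has %d ERROR-severity validation issue(s); run validate_history() for the report",
        .n_errors(report)),
        call = sys.call(-1), report = report)
    )
    stop(cond)
  }
  fold <- .engine_fold(history, config)
  warnings <- if (nrow(fold$warnings)) {
    sprintf("segment %d: %s", fold$warnings$serial_no, fold$warnings$message)
  } else {
    character()
  }
  structure(
    list(history = history, assignments = fold$assignments,
         skipped = fold$skipped, warnings = warnings, config = config),
    class = "lot_annotated"
  )
}

#' @export
print.lot_annotated <- function(x, ...) {
  cat(sprintf("<annotated history '%s'> %d qualifying, %d skipped segment(s)\n",
              x$history$patient_id, nrow(x$assignments), nrow(x$skipped)))
  if (nrow(x$assignments)) {
    tab <- x$assignments[c("serial_no", "primary_id", "guideline", "action", "label")]
    print(tab, row.names = FALSE)
  }
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    for (i in seq_len(nrow(x$skipped))) {
      cat(sprintf("  segment %d: %s\n", x$skipped$serial_no[i], x$skipped$clause[i]))
    }
  }
  if (length(x$warnings)) {
    cat("warnings:\n")
    cat(paste0("  ", x$warnings), sep = "\n")
  }
  invisible(x)
}

#' Summarize an annotated history
#'
#' Per primary organ: the total number of distinct lines, the cumulative
#' CLoT and PLoT, the latest label, and the number of distinct lines whose
#' opening segment was in the metastatic setting (2C) - the count used by
#' eligibility queries such as "no more than two lines for metastatic
#' disease". Also returns, per consecutive pair of lines, the disease-free
#' (treatment-free) interval between one line's last stop date and the cPD
#' date that opened the next line, supporting queries that reclassify early
#' therapy when relapse follows within a protocol-specified interval.
#'
#' @param object An `"lot_annotated"` object from [assign_lines()].
#' @param ... Unused.
#' @return An object of class `"lot_summary"`: list with data frames
#'   `per_primary` (`primary_id`, `n_lines`, `clot`, `plot`,
#'   `current_label`, `metastatic_lines`) and `intervals` (`primary_id`,
#'   `line_number`, `line_stop`, `next_cpd`, `interval_days`).
#' @export
summary.lot_annotated <- function(object, ...) {
  a <- object$assignments
  segs <- object$history$segments
  seg_by_serial <- if (length(segs)) {
    stats::setNames(segs, vapply(segs, function(s) as.character(s$serial_no), ""))
  } else {
    list()
  }

  per_primary <- data.frame(primary_id = character(), n_lines = integer(),
                            clot = integer(), plot = integer(),
                            current_label = character(),
                            metastatic_lines = integer(),
                            stringsAsFactors = FALSE)
  intervals <- data.frame(primary_id = character(), line_number = integer(),
                          line_stop = as.Date(character()),
                          next_cpd = as.Date(character()),
                          interval_days = numeric(), stringsAsFactors = FALSE)

  for (pid in unique(a$primary_id)) {
    ap <- a[a$primary_id == pid, , drop = FALSE]
    openers <- ap[ap$action == "NEW_LINE", , drop = FALSE]
    open_settings <- vapply(openers$serial_no, function(sn)
      seg_by_serial[[as.character(sn)]]$clinical_setting, "")
    last <- ap[nrow(ap), , drop = FALSE]
    per_primary <- rbind(per_primary, data.frame(
      primary_id = pid,
      n_lines = max(ap$line_number),
      clot = last$clot, plot = last$plot,
      current_label = last$label,
      metastatic_lines = sum(open_settings == "2C", na.rm = TRUE),
      stringsAsFactors = FALSE))

    lines <- sort(unique(ap$line_number))
    for (k in seq_along(lines)) {
      if (k == length(lines)) break
      members <- ap$serial_no[ap$line_number == lines[k]]
      stops <- as.Date(vapply(members, function(sn)
        as.numeric(seg_by_serial[[as.character(sn)]]$stop_date), 0),
        origin = "1970-01-01")
      line_stop <- if (all(is.na(stops))) as.Date(NA) else max(stops, na.rm = TRUE)
      next_opener <- openers$serial_no[match(lines[k + 1L], openers$line_number)]
      next_cpd <- seg_by_serial[[as.character(next_opener)]]$cpd_date
      intervals <- rbind(intervals, data.frame(
        primary_id = pid, line_number = lines[k], line_stop = line_stop,
        next_cpd = next_cpd,
        interval_days = as.numeric(next_cpd - line_stop),
        stringsAsFactors = FALSE))
    }
  }

  structure(list(per_primary = per_primary, intervals = intervals),
            class = "lot_summary")
}

#' @export
print.lot_summary <- function(x, ...) {
  cat("<line-of-therapy summary>\n")
  if (nrow(x$per_primary)) {
    print(x$per_primary, row.names = FALSE)
  } else {
    cat("  no qualifying segments\n")
  }
  if (nrow(x$intervals)) {
    cat("treatment-free intervals (line stop -> next cPD):\n")
    print(x$intervals, row.names = FALSE)
  }
  invisible(x)
}
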