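# Rule layer: pure, traceable decision functions. Each function is a total
# function of its inputs; every verdict names the clause that produced it so
# the enumeration can be audited row by row.

#' Engine configuration
#'
#' Documented defaults for every judgement the line-of-therapy framework
#' leaves open. The configuration is a flat, serializable record so that
#' every run can log the exact rules in force.
#'
#' @param same_class_source How "same class" is decided for toxicity
#'   substitutions: `"agent_class"` (default) compares the free-text
#'   `class` fields case-insensitively and falls back to the SACT
#'   subcategory (`i`-`v`) with a warning when a class is missing;
#'   `"subcategory"` always uses the subcategory alone.
#' @param g2_stop_reasons Stop-reason codes of the discontinued agent that
#'   permit a same-class substitution to retain the line. Default `"8C"`
#'   (toxicity) only; substitutions after patient/clinician choice or
#'   financial discontinuation open a new line with a warning.
#' @param gap_resumption_continues Whether an unplanned resumption of the
#'   identical agent set after a treatment gap ("drug holiday"), with no
#'   intervening progression, continues the line (default `TRUE`). With an
#'   intervening progression a new line always opens.
#' @param unknown_intent_policy How a line's track is chosen when the
#'   opening segment has no recorded treatment intent. `"by_setting"`
#'   (the only policy): early setting (2A) maps to the curative track,
#'   locally advanced or metastatic (2B/2C) to the palliative track.
#' @return An object of class `"lot_config"`.
#' @examples
#' cfg <- lot_config()
#' cat(format(cfg), sep = "\n")
#' @export
lot_config <- function(same_class_source = c("agent_class", "subcategory"),
                       g2_stop_reasons = "8C",
                       gap_resumption_continues = TRUE,
                       unknown_intent_policy = "by_setting") {
  same_class_source <- match.arg(same_class_source)
  g2_stop_reasons <- as.character(g2_stop_reasons)
  bad <- setdiff(g2_stop_reasons, names(.lot_stop_reasons))
  if (length(bad)) stop(sprintf("unknown stop reason code(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  unknown_intent_policy <- match.arg(unknown_intent_policy)
  structure(
    list(same_class_source = same_class_source,
         g2_stop_reasons = g2_stop_reasons,
         gap_resumption_continues = isTRUE(gap_resumption_continues),
         unknown_intent_policy = unknown_intent_policy),
    class = "lot_config"
  )
}

#' @export
format.lot_config <- function(x, ...) {
  c(sprintf("same_class_source = %s", x$same_class_source),
    sprintf("g2_stop_reasons = %s", paste(x$g2_stop_reasons, collapse = ",")),
    sprintf("gap_resumption_continues = %s",
            tolower(as.character(x$gap_resumption_continues))),
    sprintf("unknown_intent_policy = %s", x$unknown_intent_policy))
}

#' @export
print.lot_config <- function(x, ...) {
  cat("<engine config>\n")
  cat(paste0("  ", format(x)), sep = "\n")
  invisible(x)
}

#' Write / read an engine configuration as flat key-value text
#'
#' @param config An [lot_config()].
#' @param path File path.
#' @return `write_config()` returns `config` invisibly; `read_config()`
#'   returns an [lot_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lot_config"))
  writeLines(format(config), path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")), "")
  get <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  lot_config(
    same_class_source = get("same_class_source", "agent_class"),
    g2_stop_reasons = strsplit(get("g2_stop_reasons", "8C"), ",")[[1]],
    gap_resumption_continues = tolower(get("gap_resumption_continues", "true")) %in%
      c("true", "yes", "1"),
    unknown_intent_policy = get("unknown_intent_policy", "by_setting")
  )
}

# ---- qualification ----------------------------------------------------------

#' Does a therapy segment qualify for a line of therapy?
#'
#' A segment counts toward the line numbering only when it delivers
#' systemic anti-cancer therapy: its modalities include SACT (5A) or
#' experimental SACT (5B) and at least one agent is a genuine anti-cancer
#' exposure (not supportive-only, not a blinded placebo, given at a
#' clinically relevant dose/duration). Local modalities alone - surgery
#' (5C), radiotherapy (5D) and other local-energy treatments (5E) - are
#' never assigned a line. A qualifying segment is flagged experimental when
#' every counted agent was unapproved for any cancer at the start date.
#'
#' @param segment A [therapy_segment()].
#' @return A list of class `"lot_qualification"` with elements `qualifies`
#'   (logical), `experimental` (logical) and `clause` (the rule applied).
#' @examples
#' surgery <- therapy_segment(1, parse_date("2011 Jan 01"), "5C",
#'                            clinical_setting = "2A")
#' qualifies_for_lot(surgery)
#' @export
qualifies_for_lot <- function(segment) {
  stopifnot(inherits(segment, "lot_segment"))
  out <- function(qualifies, experimental, clause) {
    structure(list(qualifies = qualifies, experimental = experimental,
                   clause = clause), class = "lot_qualification")
  }
  if (!.has_sact_modality(segment)) {
    return(out(FALSE, FALSE,
               "local modality only (surgery/radiotherapy/other local energy); not assigned a line"))
  }
  counted <- .counted_agents(segment)
  if (length(counted) == 0L) {
    if (length(segment$agents) == 0L) {
      return(out(FALSE, FALSE, "systemic modality but no agents recorded"))
    }
    placebo <- all(vapply(segment$agents, `[[`, TRUE, "placebo"))
    supportive <- all(vapply(segment$agents, `[[`, TRUE, "supportive_only"))
    clause <- if (placebo) {
      "placebo-only exposure (blinded control arm); not a SACT unless unblinded"
    } else if (supportive) {
      "supportive/symptomatic use only; not an anti-cancer agent exposure"
    } else {
      "no agent at a clinically relevant anti-cancer exposure"
    }
    return(out(FALSE, FALSE, clause))
  }
  experimental <- all(vapply(counted, `[[`, TRUE, "experimental"))
  clause <- if (experimental) {
    "experimental SACT: all counted agents unapproved at start; assigned a line with the 'experimental' flag"
  } else {
    "SACT with at least one anti-cancer agent at clinically relevant exposure"
  }
  out(TRUE, experimental, clause)
}

#' @export
print.lot_qualification <- function(x, ...) {
  cat(sprintf("<qualification> qualifies=%s experimental=%s\n  clause: %s\n",
              x$qualifies, x$experimental, x$clause))
  invisible(x)
}

# ---- progression ------------------------------------------------------------

#' Has a new progression been documented since the current line opened?
#'
#' The dataset's cPD column records the most recent documented clinical
#' progression preceding each segment. A progression is "new" for the open
#' line when that date falls strictly after the line's opening segment
#' started: it was documented during or after the current line and
#' therefore mandates a new line for the next SACT. A cPD date that
#' precedes the line's opening is the progression that motivated the
#' current line and does not count again (e.g. a toxicity substitution
#' carries its line's original cPD date forward).
#'
#' @param line A line state as carried by the enumerator (needs element
#'   `opening_start`, a [Date]).
#' @param segment A [therapy_segment()].
#' @return Logical scalar.
#' @export
is_new_progression <- function(line, segment) {
  if (is.null(line)) return(FALSE)
  isTRUE(!is.na(segment$cpd_date) && segment$cpd_date > line$opening_start)
}

# ---- transition cascade -----------------------------------------------------

.transition <- function(action, guideline, rationale, warning = NULL) {
  structure(list(action = action, guideline = guideline,
                 rationale = rationale, warning = warning),
            class = "lot_transition")
}

#' @export
print.lot_transition <- function(x, ...) {
  cat(sprintf("<transition> %s [%s]: %s\n", x$action, x$guideline, x$rationale))
  invisible(x)
}

# class key used for "same class" matching under the configured source;
# attr(, "fallback") flags that a missing class field forced subcategory use.
.class_keys <- function(agents, config) {
  fallback <- FALSE
  keys <- vapply(agents, function(a) {
    if (config$same_class_source == "agent_class" && !is.na(a$class)) {
      .norm_name(a$class)
    } else {
      if (config$same_class_source == "agent_class") fallback <<- TRUE
      paste0("subcategory:", a$category)
    }
  }, "")
  structure(keys, fallback = fallback)
}

#' Classify the transition from the open line to the next qualifying segment
#'
#' Applies the guideline cascade in strict order; the first matching clause
#' wins and is named in the returned decision:
#'
#' * `FIRST_SEGMENT` - no line is open for this primary: open line 1.
#' * `PREPLANNED` - the segment is a prospectively planned continuation of
#'   the previous segment's SACT and no new progression intervened: the
#'   pre-planned sequence is a single SACT, retain the line.
#' * `G1` - a clinical progression has been documented since the line
#'   opened: the next SACT receives a new line, whatever else changed.
#' * `G2` - no new progression, the previous segment stopped for a reason
#'   in `config$g2_stop_reasons` (default toxicity, 8C), and the new agent
#'   set replaces discontinued agent(s) with same-class substitute(s) while
#'   all other agents are unchanged: retain the line.
#' * `G3` - no new progression, but one or more agents were added to the
#'   ongoing SACT outside a pre-planned sequence (including a substitution
#'   that fails the same-class or stop-reason test): a new SACT, new line.
#' * `G4` - agents were discontinued and none added, irrespective of cPD:
#'   retain the line for the remaining agents.
#' * `G5` - the agent set is unchanged (dose/schedule/route modifications
#'   only), irrespective of cPD: retain the line.
#'
#' With `config$gap_resumption_continues = FALSE`, an identical agent set
#' resuming after a gap in therapy (no intervening progression) opens a new
#' line instead of falling through to `G5`; the decision carries a warning
#' either way because the framework leaves drug holidays open.
#'
#' @param line The open line state for the segment's primary, or `NULL`
#'   when no qualifying segment precedes it.
#' @param segment A qualifying [therapy_segment()].
#' @param config An [lot_config()].
#' @return A list of class `"lot_transition"`: `action`
#'   (`"NEW_LINE"`/`"CONTINUE_LINE"`), `guideline`, `rationale`, and
#'   optionally `warning`.
#' @export
classify_transition <- function(line, segment, config = lot_config()) {
  stopifnot(inherits(segment, "lot_segment"))

  # (a) first qualifying segment of this primary
  if (is.null(line)) {
    return(.transition("NEW_LINE", "FIRST_SEGMENT",
                       "first qualifying SACT for this primary; opens line 1"))
  }

  newprog <- is_new_progression(line, segment)

  # (b) pre-planned continuation: one SACT by definition
  if (segment$preplanned_with_previous && !newprog) {
    return(.transition("CONTINUE_LINE", "PREPLANNED",
                       "prospectively planned continuation of the ongoing SACT (single SACT by definition)"))
  }

  # (c) guideline 1: documented progression dominates everything else
  if (newprog) {
    return(.transition("NEW_LINE", "G1", sprintf(
      "cPD documented %s, after the line opened %s; next SACT receives a new line",
      .format_date(segment$cpd_date), .format_date(line$opening_start))))
  }

  prev <- line$current_agents
  cur <- .counted_agents(segment)
  prev_names <- vapply(prev, function(a) .norm_name(a$name), "")
  cur_names <- vapply(cur, function(a) .norm_name(a$name), "")
  added <- cur[!cur_names %in% prev_names]
  removed <- prev[!prev_names %in% cur_names]

  # (d) guideline 2: same-class substitution after a qualifying stop reason
  if (length(added) > 0L && length(removed) > 0L &&
      length(added) == length(removed) &&
      isTRUE(line$prev_stop_reason %in% config$g2_stop_reasons)) {
    ka <- .class_keys(added, config)
    kr <- .class_keys(removed, config)
    if (identical(sort(unname(ka)), sort(unname(kr)))) {
      warn <- if (attr(ka, "fallback") || attr(kr, "fallback")) {
        "agent class not recorded; same-class test fell back to the SACT subcategory"
      }
      return(.transition("CONTINUE_LINE", "G2", sprintf(
        "%s discontinued (%s) and substituted by same-class %s; line retained",
        paste(vapply(removed, `[[`, "", "name"), collapse = " + "),
        .lot_stop_reasons[[line$prev_stop_reason]],
        paste(vapply(added, `[[`, "", "name"), collapse = " + ")), warn))
    }
  }

  # (e) guideline 3: agents added to the ongoing SACT without progression
  if (length(added) > 0L) {
    warn <- if (length(removed) > 0L) {
      "agent substitution without cPD that does not meet the same-class/toxicity conditions; new line by default"
    }
    return(.transition("NEW_LINE", "G3", sprintf(
      "agent(s) added to the ongoing SACT without documented progression (%s); new SACT, new line",
      paste(vapply(added, `[[`, "", "name"), collapse = " + ")), warn))
  }

  # (f) guideline 4: agents dropped, none added
  if (length(removed) > 0L) {
    return(.transition("CONTINUE_LINE", "G4", sprintf(
      "agent(s) discontinued from the ongoing SACT (%s); line retained for the remaining agents",
      paste(vapply(removed, `[[`, "", "name"), collapse = " + "))))
  }

  # (g) guideline 5: identical agent set; only dose/schedule/route can differ
  gap <- !is.na(line$prev_stop_date) && !is.na(segment$start_date) &&
    segment$start_date > line$prev_stop_date
  if (gap && !config$gap_resumption_continues) {
    return(.transition("NEW_LINE", "G3",
                       "unplanned resumption of the same agent set after a treatment gap without cPD; new line per configuration",
                       "drug-holiday resumption treated as a new line (configurable)"))
  }
  .transition("CONTINUE_LINE", "G5",
              "agent set unchanged; dose/schedule/route modifications retain the line")
}

# ---- track ------------------------------------------------------------------

#' Curative or palliative track for a line-opening segment
#'
#' The recorded treatment intent takes precedence: curative intent (3A)
#' puts the line on the curative track and palliative intent (3B) on the
#' palliative track, whatever the clinical setting (a metastatic seminoma
#' treated with curative intent contributes to CLoT). When intent is not
#' recorded the track defaults from the setting - early (2A) to curative,
#' locally advanced or metastatic (2B/2C) to palliative - and the decision
#' carries a warning.
#'
#' @param segment A qualifying [therapy_segment()].
#' @param config An [lot_config()].
#' @return `"CURATIVE"` or `"PALLIATIVE"`; when the default policy was used
#'   the value carries a `"warning"` attribute describing it.
#' @export
assign_track <- function(segment, config = lot_config()) {
  stopifnot(inherits(segment, "lot_segment"))
  if (!is.na(segment$treatment_intent)) {
    return(if (segment$treatment_intent == "3A") "CURATIVE" else "PALLIATIVE")
  }
  track <- if (identical(segment$clinical_setting, "2A")) "CURATIVE" else "PALLIATIVE"
  structure(track, warning = sprintf(
    "treatment intent absent; track defaulted to %s from clinical setting %s",
    track, segment$clinical_setting))
}
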