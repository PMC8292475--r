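# Seeded generator of synthetic patient histories with known ground-truth
# line assignments. Every rule path of the transition cascade can be
# exercised without any real patient data: the generator knows which
# segments open lines, so its expected labels form an oracle that is
# independent of the enumerator.

#' Scenario configuration for the synthetic-history generator
#'
#' Describes one simulated patient journey: curative-track lines first
#' (early setting, curative intent), then palliative-track lines (locally
#' advanced or metastatic setting, palliative intent), each new line opened
#' by a documented progression. Within a line, optional extra segments
#' exercise the continuation rules: a same-class substitution after
#' toxicity, an agent drop, and a dose/schedule change. Non-qualifying
#' surgery/radiotherapy segments can be interleaved between lines; they
#' must never affect the labels.
#'
#' @param n_curative,n_palliative Numbers of curative- and palliative-track
#'   lines (non-negative; at least one line overall).
#' @param p_toxicity_substitution Per-line probability of a toxicity stop
#'   followed by a same-class substitute segment (continues via G2).
#' @param p_agent_drop Per-line probability of a segment that drops one
#'   agent (continues via G4); only fires when the line carries >= 2 agents.
#' @param p_dose_change Per-line probability of a dose-change segment with
#'   the identical agent set (continues via G5).
#' @param p_nonqualifying_interleave Per-line probability of inserting a
#'   surgery or radiotherapy segment after the line.
#' @param multi_primary When `TRUE`, a second primary organ (`"P2"`) with
#'   one palliative line of its own is interleaved; its counters are
#'   independent of `"P1"`'s.
#' @param seed Integer seed; the generator draws from its own stream and
#'   leaves the caller's random-number state untouched.
#' @return An object of class `"lot_scenario"`.
#' @export
scenario_config <- function(n_curative = 1, n_palliative = 1,
                            p_toxicity_substitution = 0, p_agent_drop = 0,
                            p_dose_change = 0, p_nonqualifying_interleave = 0,
                            multi_primary = FALSE, seed = 1L) {
  n_curative <- as.integer(n_curative)
  n_palliative <- as.integer(n_palliative)
  stopifnot(n_curative >= 0L, n_palliative >= 0L)
  if (n_curative + n_palliative < 1L) {
    stop("the scenario must contain at least one line overall", call. = FALSE)
  }
  probs <- c(p_toxicity_substitution, p_agent_drop, p_dose_change,
             p_nonqualifying_interleave)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(
    list(n_curative = n_curative, n_palliative = n_palliative,
         p_toxicity_substitution = p_toxicity_substitution,
         p_agent_drop = p_agent_drop, p_dose_change = p_dose_change,
         p_nonqualifying_interleave = p_nonqualifying_interleave,
         multi_primary = isTRUE(multi_primary), seed = as.integer(seed)),
    class = "lot_scenario"
  )
}

# Synthetic monthly date grid from 2000 Jan 01: only the order of events
# matters to the rules, so all dates fall on the first of a month.
.month_date <- function(i) {
  as.Date(sprintf("%04d-%02d-01", 2000L + i %/% 12L, i %% 12L + 1L))
}

# Synthetic agent dictionary: 12 classes, two interchangeable members each,
# with a fixed class -> subcategory map.
.synth_classes <- sprintf("class%02d", 1:12)
.synth_cats <- rep(c("i", "ii", "iii", "iv"), 3)

.synth_agent <- function(class_idx, member) {
  agent_record(sprintf("%s_%s", .synth_classes[class_idx], letters[member]),
               class = .synth_classes[class_idx],
               category = .synth_cats[class_idx])
}

#' Generate a synthetic patient history with known line assignments
#'
#' Builds a chronologically consistent history realizing the scenario and,
#' alongside it, the expected assignment for every qualifying segment. The
#' expectations come from the generator's own construction - it knows which
#' segments open lines and which continue them - so they are an oracle
#' that is independent of [assign_lines()]. By construction the final
#' cumulative label is `"(n_curative + n_palliative) (n_curative +
#' n_palliative)"` split across tracks, e.g. a scenario with 2 curative and
#' 7 palliative lines ends at `"9 (2 + 7)"`.
#'
#' Identical configurations (including the seed) yield identical output.
#'
#' @param scenario A [scenario_config()].
#' @return A list with elements `history` (a [patient_history()] that
#'   passes [validate_history()] with no errors) and `expected` (data frame
#'   with `serial_no`, `primary_id`, `line_number`, `track`, `clot`,
#'   `plot`, `label`, `guideline` for every qualifying segment).
#' @examples
#' sim <- generate_history(scenario_config(2, 7, seed = 42))
#' tail(sim$expected$label, 1)
#' @export
generate_history <- function(scenario) {
  stopifnot(inherits(scenario, "lot_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(scenario$seed)

  protos <- list()  # each: list(segment fields..., expected row or NULL)
  add_proto <- function(p) protos[[length(protos) + 1L]] <<- p

  gen_primary <- function(primary_id, n_cur, n_pal, month0) {
    t <- month0
    clot <- 0L; plot <- 0L
    n_lines <- n_cur + n_pal
    class_pool <- sample(seq_along(.synth_classes))
    pool_at <- 1L

    for (k in seq_len(n_lines)) {
      curative <- k <= n_cur
      setting <- if (curative) "2A" else sample(c("2B", "2C"), 1, prob = c(0.3, 0.7))
      intent <- if (curative) "3A" else "3B"
      if (curative) clot <- clot + 1L else plot <- plot + 1L
      n_line <- clot + plot
      track <- if (curative) "CURATIVE" else "PALLIATIVE"
      label <- format_label(n_line, clot, plot)

      cpd <- if (k == 1L) as.Date(NA) else .month_date(t)
      start_t <- t + 1L
      stop_t <- start_t + 2L

      n_agents <- sample(2:3, 1)
      if (pool_at + n_agents - 1L > length(class_pool)) {
        class_pool <- sample(seq_along(.synth_classes))
        pool_at <- 1L
      }
      classes <- class_pool[pool_at:(pool_at + n_agents - 1L)]
      pool_at <- pool_at + n_agents
      agents <- lapply(classes, .synth_agent, member = 1L)

      events <- c(
        sub  = stats::runif(1) < scenario$p_toxicity_substitution,
        drop = stats::runif(1) < scenario$p_agent_drop,
        dose = stats::runif(1) < scenario$p_dose_change,
        nonq = stats::runif(1) < scenario$p_nonqualifying_interleave
      )

      exp_row <- function(guideline) {
        list(primary_id = primary_id, line_number = n_line, track = track,
             clot = clot, plot = plot, label = label, guideline = guideline)
      }
      seg <- function(start_t, stop_t, agents, stop_reason, guideline,
                      comments = "") {
        add_proto(list(
          primary_id = primary_id, clinical_setting = setting,
          treatment_intent = intent, cpd_date = cpd,
          modalities = unique(paste0("5A:", vapply(agents, `[[`, "", "category"))),
          agents = agents, start_date = .month_date(start_t),
          stop_date = .month_date(stop_t), stop_reason = stop_reason,
          comments = comments, expected = exp_row(guideline)))
      }

      last_reason_pending <- list()  # revisit the final segment's stop reason
      opener_reason <- if (events[["sub"]]) "8C" else
        if (events[["drop"]] || events[["dose"]]) "8F" else "PENDING"
      seg(start_t, stop_t, agents, opener_reason,
          if (k == 1L) "FIRST_SEGMENT" else "G1",
          comments = sprintf("line %d opening regimen", n_line))
      t <- stop_t

      if (events[["sub"]]) {
        # replace the first agent with its same-class partner (G2)
        agents[[1]] <- .synth_agent(classes[1], member = 2L)
        nxt_start <- t + 1L; nxt_stop <- nxt_start + 2L
        reason <- if (events[["drop"]] || events[["dose"]]) "8F" else "PENDING"
        seg(nxt_start, nxt_stop, agents, reason, "G2",
            comments = "same-class substitute after toxicity")
        t <- nxt_stop
      }
      if (events[["drop"]] && length(agents) >= 2L) {
        agents <- agents[-length(agents)]
        nxt_start <- t + 1L; nxt_stop <- nxt_start + 2L
        reason <- if (events[["dose"]]) "8F" else "PENDING"
        seg(nxt_start, nxt_stop, agents, reason, "G4",
            comments = "agent discontinued, remaining agents retained")
        t <- nxt_stop
      }
      if (events[["dose"]]) {
        nxt_start <- t + 1L; nxt_stop <- nxt_start + 2L
        seg(nxt_start, nxt_stop, agents, "PENDING", "G5",
            comments = "dose reduction, identical agent set")
        t <- nxt_stop
      }

      # the line's final segment stops for progression when another line
      # follows, otherwise the planned course simply completed
      protos[[length(protos)]]$stop_reason <<-
        if (k < n_lines) "8A" else "8B"

      if (events[["nonq"]]) {
        add_proto(list(
          primary_id = primary_id, clinical_setting = setting,
          treatment_intent = NA_character_, cpd_date = as.Date(NA),
          modalities = sample(c("5C", "5D"), 1), agents = list(),
          start_date = .month_date(t + 1L), stop_date = .month_date(t + 1L),
          stop_reason = "8B", comments = "local therapy between lines",
          expected = NULL))
        t <- t + 1L
      }
      t <- t + 1L  # cPD for the next line is documented at this month
    }
  }

  gen_primary("P1", scenario$n_curative, scenario$n_palliative, month0 = 0L)
  if (scenario$multi_primary) gen_primary("P2", 0L, 1L, month0 = 7L)

  # chronological serials across the whole history (ties: insertion order)
  starts <- as.Date(vapply(protos, function(p) as.numeric(p$start_date), 0),
                    origin = "1970-01-01")
  ord <- order(starts, seq_along(protos))
  protos <- protos[ord]

  segments <- vector("list", length(protos))
  expected <- list()
  for (i in seq_along(protos)) {
    p <- protos[[i]]
    segments[[i]] <- therapy_segment(
      serial_no = i, primary_id = p$primary_id,
      clinical_setting = p$clinical_setting,
      treatment_intent = p$treatment_intent, cpd_date = p$cpd_date,
      modalities = p$modalities, agents = p$agents,
      start_date = p$start_date, stop_date = p$stop_date,
      stop_reason = p$stop_reason, comments = p$comments
    )
    if (!is.null(p$expected)) {
      e <- p$expected
      expected[[length(expected) + 1L]] <- data.frame(
        serial_no = i, primary_id = e$primary_id,
        line_number = e$line_number, track = e$track,
        clot = e$clot, plot = e$plot, label = e$label,
        guideline = e$guideline, stringsAsFactors = FALSE)
    }
  }

  list(
    history = patient_history(segments,
                              patient_id = sprintf("synthetic-%d", scenario$seed)),
    expected = do.call(rbind, expected)
  )
}
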