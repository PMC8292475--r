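# Shared fixtures, built in code.

# Shorthand agent constructor.
ag <- function(name, class = NA_character_, category = "v", ...) {
  agent_record(name, class = class, category = category, ...)
}

d <- function(x) parse_date(x)

# The ten-segment breast-cancer worked example: a pre-planned curative
# multimodal sequence, a curative retreatment after local recurrence, then
# seven palliative-track lines including a taxane substitution after
# toxicity and a final experimental SACT.
worked_example_history <- function() {
  segs <- list(
    therapy_segment(1, d("2000 Jan 01"),
      modalities = c("5A:i", "5A:ii", "5C", "5D"),
      clinical_setting = "2A", treatment_intent = "3A",
      cpd_date = d("NA"), stop_date = d("2005 Aug 14"), stop_reason = "8B",
      agents = list(
        ag("5-fluorouracil", "fluoropyrimidine", "i"),
        ag("epirubicin", "anthracycline", "i"),
        ag("cyclophosphamide", "alkylating agent", "i"),
        ag("tamoxifen", "selective estrogen receptor modulator", "ii"),
        ag("letrozole", "aromatase inhibitor", "ii")),
      comments = "5FU + epirubicin 75 + cyclophosphamide x6 -> breast conserving surgery -> EBRT -> tamoxifen x 2 yrs -> letrozole x 3 yrs"),
    therapy_segment(2, d("2011 Jan 01"),
      modalities = c("5A:ii", "5C"),
      clinical_setting = "2A", treatment_intent = "3A",
      cpd_date = d("2010 Dec 22"), stop_date = d("2013 Jan 01"), stop_reason = "8B",
      agents = list(ag("letrozole", "aromatase inhibitor", "ii")),
      comments = "Isolated local recurrence, mastectomy, letrozole x 2 yrs"),
    therapy_segment(3, d("2015 Feb 07"),
      modalities = "5A:ii",
      clinical_setting = "2B", treatment_intent = "3B",
      cpd_date = d("2015 Feb 01"), stop_date = d("2016 Sep 19"), stop_reason = "8A",
      agents = list(ag("anastrozole", "aromatase inhibitor", "ii")),
      comments = "Anastrozole"),
    therapy_segment(4, d("2016 Oct 02"),
      modalities = c("5A:ii", "5A:iii"),
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2016 Sep 15"), stop_date = d("2017 Jan 07"), stop_reason = "8A",
      agents = list(ag("everolimus", "mTOR inhibitor", "iii"),
                    ag("exemestane", "aromatase inhibitor", "ii")),
      comments = "Everolimus + Exemestane"),
    therapy_segment(5, d("2017 Feb 01"),
      modalities = "5A:i",
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2017 Jan 07"), stop_date = d("2017 Jul 17"), stop_reason = "8C",
      agents = list(ag("paclitaxel", "taxane", "i")),
      comments = "Paclitaxel (stopped due to neuropathy)"),
    therapy_segment(6, d("2017 Aug 09"),
      modalities = "5A:i",
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2017 Jan 07"), stop_date = d("2017 Dec 23"), stop_reason = "8A",
      agents = list(ag("docetaxel", "taxane", "i")),
      comments = "Docetaxel"),
    therapy_segment(7, d("2018 Jan 08"),
      modalities = "5A:i",
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2017 Dec 17"), stop_date = d("2018 Aug 15"), stop_reason = "8A",
      agents = list(ag("capecitabine", "fluoropyrimidine", "i")),
      comments = "Capecitabine"),
    therapy_segment(8, d("2018 Sep 01"),
      modalities = "5A:i",
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2018 Aug 15"), stop_date = d("2018 Dec 30"), stop_reason = "8A",
      agents = list(ag("eribulin", "halichondrin microtubule inhibitor", "i")),
      comments = "Eribulin"),
    therapy_segment(9, d("2019 Jan 27"),
      modalities = "5A:ii",
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2019 Jan 03"), stop_date = d("2019 Jun 15"), stop_reason = "8A",
      agents = list(ag("fulvestrant", "selective estrogen receptor degrader", "ii")),
      comments = "Fulvestrant"),
    therapy_segment(10, d("2019 Jun 22"),
      modalities = "5B:iii",
      clinical_setting = "2C", treatment_intent = "3B",
      cpd_date = d("2019 Jun 04"), stop_date = d("2020 Apr 30"), stop_reason = "8A",
      agents = list(ag("experimental small molecule", "experimental kinase inhibitor",
                       "iii", experimental = TRUE)),
      comments = "Experimental agent (small molecule)")
  )
  patient_history(segs, patient_id = "breast-example")
}

worked_example_labels <- c("1 (1 + 0)", "2 (2 + 0)", "3 (2 + 1)", "4 (2 + 2)",
                   "5 (2 + 3)", "5 (2 + 3)", "6 (2 + 4)", "7 (2 + 5)",
                   "8 (2 + 6)", "9 (2 + 7)")

fixture_path <- function() {
  system.file("extdata", "breast_example.csv", package = "lotengine")
}

# Minimal open-line state for exercising the rule functions directly.
line_state <- function(agents, opening_start, prev_stop_reason = NA_character_,
                       prev_stop_date = as.Date(NA), track = "PALLIATIVE",
                       line_number = 1L, opening_intent = "3B") {
  list(line_number = line_number, track = track,
       opening_start = as.Date(opening_start), opening_intent = opening_intent,
       current_agents = agents, prev_stop_reason = prev_stop_reason,
       prev_stop_date = as.Date(prev_stop_date), member_serials = 1L)
}

# Bare qualifying segment for rules tests.
sact_segment <- function(serial, start, agents, cpd = NA, stop = NA,
                         reason = NA_character_, setting = "2C",
                         intent = "3B", preplanned = FALSE, primary = "P1",
                         comments = "") {
  therapy_segment(serial, as.Date(start),
                  modalities = unique(paste0("5A:", vapply(agents, `[[`, "", "category"))),
                  clinical_setting = setting, treatment_intent = intent,
                  cpd_date = as.Date(cpd), stop_date = as.Date(stop),
                  stop_reason = reason, agents = agents,
                  preplanned_with_previous = preplanned, primary_id = primary,
                  comments = comments)
}

expected_cols <- c("serial_no", "primary_id", "line_number", "track",
                   "clot", "plot", "label", "guideline")

strip_rownames <- function(df) { rownames(df) <- NULL; df }
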