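test_that("qualification separates SACT from local modalities and non-exposures", {
  # experimental targeted agent (5B) qualifies, flagged experimental
  exp_seg <- worked_example_history()$segments[[10]]
  q <- qualifies_for_lot(exp_seg)
  expect_true(q$qualifies)
  expect_true(q$experimental)

  # surgery alone never earns a line
  surgery <- therapy_segment(1, d("2011 Jan 01"), "5C", clinical_setting = "2A",
                             treatment_intent = "3A")
  q <- qualifies_for_lot(surgery)
  expect_false(q$qualifies)
  expect_false(q$experimental)
  expect_match(q$clause, "local modality")

  # blinded placebo arm is not a SACT
  placebo <- sact_segment(1, "2020-01-01",
                          list(ag("blinded tablet", category = "v", placebo = TRUE)))
  q <- qualifies_for_lot(placebo)
  expect_false(q$qualifies)
  expect_match(q$clause, "placebo")

  # dexamethasone as an antiemetic is supportive care, not anti-cancer therapy
  supp <- sact_segment(1, "2020-01-01",
                       list(ag("dexamethasone", category = "v", supportive_only = TRUE)))
  q <- qualifies_for_lot(supp)
  expect_false(q$qualifies)
  expect_match(q$clause, "supportive")

  # an anaphylactic single exposure below clinical relevance does not count
  tiny <- sact_segment(1, "2020-01-01",
                       list(ag("oxaliplatin", "platinum", "i", clinically_relevant = FALSE)))
  expect_false(qualifies_for_lot(tiny)$qualifies)

  # one real agent among supportive ones is enough, and kills the
  # experimental flag unless every counted agent is experimental
  mixed <- sact_segment(1, "2020-01-01", list(
    ag("carboplatin", "platinum", "i"),
    ag("filgrastim", category = "v", supportive_only = TRUE)))
  q <- qualifies_for_lot(mixed)
  expect_true(q$qualifies)
  expect_false(q$experimental)
})

test_that("all-supportive agent lists never qualify, whatever the flags elsewhere say", {
  for (k in 1:5) {
    agents <- lapply(seq_len(k), function(i)
      ag(paste0("supportive", i), category = "v", supportive_only = TRUE,
         experimental = i %% 2 == 0))
    seg <- sact_segment(1, "2020-01-01", agents)
    expect_false(qualifies_for_lot(seg)$qualifies)
  }
})

test_that("a progression is new only when documented after the line opened", {
  line <- line_state(list(ag("paclitaxel", "taxane", "i")), "2017-02-01")
  before <- sact_segment(2, "2017-08-09", list(ag("docetaxel", "taxane", "i")),
                         cpd = "2017-01-07")
  after <- sact_segment(2, "2018-01-08", list(ag("capecitabine", "fluoropyrimidine", "i")),
                        cpd = "2017-12-17")
  none <- sact_segment(2, "2018-01-08", list(ag("capecitabine", "fluoropyrimidine", "i")))
  expect_false(is_new_progression(line, before))
  expect_true(is_new_progression(line, after))
  expect_false(is_new_progression(line, none))
  # same-day documentation as the opening is not "after"
  same <- sact_segment(2, "2017-06-01", list(ag("x", category = "i")),
                       cpd = "2017-02-01")
  expect_false(is_new_progression(line, same))
})

test_that("the transition cascade fires the documented clause on each scenario", {
  cfg <- lot_config()
  taxA <- ag("paclitaxel", "taxane", "i")
  taxB <- ag("docetaxel", "taxane", "i")
  A <- ag("drug A", "class A", "i"); B <- ag("drug B", "class B", "ii")
  C <- ag("drug C", "class C", "iii")

  # no open line
  first <- classify_transition(NULL, sact_segment(1, "2020-01-01", list(A)), cfg)
  expect_equal(first[c("action", "guideline")],
               list(action = "NEW_LINE", guideline = "FIRST_SEGMENT"))

  # same-class substitution after toxicity, progression predates the line
  line <- line_state(list(taxA), "2017-02-01", prev_stop_reason = "8C",
                     prev_stop_date = as.Date("2017-07-17"))
  tr <- classify_transition(line, sact_segment(6, "2017-08-09", list(taxB),
                                               cpd = "2017-01-07"), cfg)
  expect_equal(tr$action, "CONTINUE_LINE")
  expect_equal(tr$guideline, "G2")

  # a documented progression overrides even a same-class substitution
  tr <- classify_transition(line, sact_segment(6, "2017-08-09", list(taxB),
                                               cpd = "2017-06-01"), cfg)
  expect_equal(tr$guideline, "G1")
  expect_equal(tr$action, "NEW_LINE")

  # substitution after a non-toxicity stop opens a new line (with a warning)
  line_choice <- line_state(list(taxA), "2017-02-01", prev_stop_reason = "8D",
                            prev_stop_date = as.Date("2017-07-17"))
  tr <- classify_transition(line_choice, sact_segment(6, "2017-08-09", list(taxB)), cfg)
  expect_equal(tr$guideline, "G3")
  expect_equal(tr$action, "NEW_LINE")
  expect_match(tr$warning, "same-class/toxicity")

  # cross-class substitution after toxicity also falls through to G3
  line_tox <- line_state(list(taxA), "2017-02-01", prev_stop_reason = "8C")
  tr <- classify_transition(line_tox, sact_segment(6, "2017-08-09", list(C)), cfg)
  expect_equal(tr$guideline, "G3")

  # agent added without progression: new SACT
  line_A <- line_state(list(A), "2020-01-01", prev_stop_reason = "8B")
  tr <- classify_transition(line_A, sact_segment(2, "2020-06-01", list(A, B)), cfg)
  expect_equal(tr[c("action", "guideline")],
               list(action = "NEW_LINE", guideline = "G3"))

  # pre-planned addition retains the line (switch/continuation maintenance)
  tr <- classify_transition(line_A,
                            sact_segment(2, "2020-06-01", list(A, B), preplanned = TRUE),
                            cfg)
  expect_equal(tr[c("action", "guideline")],
               list(action = "CONTINUE_LINE", guideline = "PREPLANNED"))

  # ...but not across a documented progression
  tr <- classify_transition(line_A,
                            sact_segment(2, "2020-06-01", list(A, B),
                                         cpd = "2020-03-01", preplanned = TRUE), cfg)
  expect_equal(tr$guideline, "G1")

  # agents dropped, none added: retain the line, irrespective of cPD
  line_AB <- line_state(list(A, B), "2020-01-01", prev_stop_reason = "8C")
  tr <- classify_transition(line_AB, sact_segment(2, "2020-06-01", list(A)), cfg)
  expect_equal(tr[c("action", "guideline")],
               list(action = "CONTINUE_LINE", guideline = "G4"))

  # identical agent set: dose/schedule/route changes retain the line
  tr <- classify_transition(line_A, sact_segment(2, "2020-06-01", list(A)), cfg)
  expect_equal(tr[c("action", "guideline")],
               list(action = "CONTINUE_LINE", guideline = "G5"))
})

test_that("same-class matching falls back to the SACT subcategory when class is absent", {
  cfg <- lot_config()
  line <- line_state(list(ag("old drug", NA, "ii")), "2020-01-01",
                     prev_stop_reason = "8C")
  tr <- classify_transition(line, sact_segment(2, "2020-06-01",
                                               list(ag("new drug", NA, "ii"))), cfg)
  expect_equal(tr$guideline, "G2")
  expect_match(tr$warning, "subcategory")
  # different subcategory without classes: not same class, new line
  tr <- classify_transition(line, sact_segment(2, "2020-06-01",
                                               list(ag("new drug", NA, "i"))), cfg)
  expect_equal(tr$guideline, "G3")
  # the coarse subcategory alone must NOT equate different named classes
  line2 <- line_state(list(ag("capecitabine", "fluoropyrimidine", "i")), "2020-01-01",
                      prev_stop_reason = "8C")
  tr <- classify_transition(line2, sact_segment(2, "2020-06-01",
                                                list(ag("eribulin", "halichondrin", "i"))), cfg)
  expect_equal(tr$guideline, "G3")
})

test_that("drug-holiday resumption is configurable", {
  A <- ag("tamoxifen", "SERM", "ii")
  line <- line_state(list(A), "2020-01-01", prev_stop_reason = "8D",
                     prev_stop_date = as.Date("2020-06-01"))
  resume <- sact_segment(2, "2021-01-01", list(A))
  keep <- classify_transition(line, resume, lot_config())
  expect_equal(keep[c("action", "guideline")],
               list(action = "CONTINUE_LINE", guideline = "G5"))
  new <- classify_transition(line, resume,
                             lot_config(gap_resumption_continues = FALSE))
  expect_equal(new$action, "NEW_LINE")
})

test_that("exactly one cascade clause fires and progression dominates substitution", {
  cfg <- lot_config()
  A <- ag("drug A", "class A", "i"); A2 <- ag("drug A2", "class A", "i")
  B <- ag("drug B", "class B", "ii"); C <- ag("drug C", "class C", "iii")
  rel <- list(equal = list(A, B), superset = list(A, B, C), subset = list(A),
              swap = list(A2, B), disjoint = list(C))
  cases <- expand.grid(rel = names(rel), cpd = c("none", "before", "after"),
                       reason = c("8A", "8B", "8C", "8F"),
                       preplanned = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    line <- line_state(list(A, B), "2020-02-01", prev_stop_reason = cs$reason,
                       prev_stop_date = as.Date("2020-05-01"))
    seg <- sact_segment(2, "2020-06-01", rel[[cs$rel]],
                        cpd = switch(cs$cpd, none = NA, before = "2020-01-15",
                                     after = "2020-04-01"),
                        preplanned = cs$preplanned)
    tr <- classify_transition(line, seg, cfg)
    expect_true(tr$guideline %in% c("G1", "G2", "G3", "G4", "G5", "PREPLANNED"))
    expect_true(tr$action %in% c("NEW_LINE", "CONTINUE_LINE"))
    # replay is byte-identical (pure function)
    expect_identical(tr, classify_transition(line, seg, cfg))
    if (is_new_progression(line, seg)) expect_equal(tr$guideline, "G1")
  }
})

test_that("intent takes precedence over setting for the track, with a setting default", {
  cfg <- lot_config()
  trk <- function(setting, intent) {
    as.character(assign_track(sact_segment(1, "2020-01-01",
                                           list(ag("x", category = "i")),
                                           setting = setting, intent = intent), cfg))
  }
  expect_equal(trk("2A", "3A"), "CURATIVE")
  expect_equal(trk("2B", "3B"), "PALLIATIVE")
  # curative intent in the metastatic setting (e.g. seminoma) stays curative
  expect_equal(trk("2C", "3A"), "CURATIVE")
  expect_equal(trk("2A", "3B"), "PALLIATIVE")
  # absent intent defaults from the setting and warns
  expect_equal(trk("2A", NA), "CURATIVE")
  expect_equal(trk("2B", NA), "PALLIATIVE")
  expect_equal(trk("2C", NA), "PALLIATIVE")
  t <- assign_track(sact_segment(1, "2020-01-01", list(ag("x", category = "i")),
                                 setting = "2C", intent = NA), cfg)
  expect_match(attr(t, "warning"), "defaulted")
})

test_that("engine configuration serializes and reads back identically", {
  cfg <- lot_config(same_class_source = "subcategory",
                    g2_stop_reasons = c("8C", "8F"),
                    gap_resumption_continues = FALSE)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  expect_identical(read_config(path), cfg)
  write_config(lot_config(), path)
  expect_identical(read_config(path), lot_config())
})
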