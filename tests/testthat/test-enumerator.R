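test_that("format_label renders the cumulative format and enforces N = CLoT + PLoT", {
  expect_identical(format_label(9, 2, 7), "9 (2 + 7)")
  expect_identical(format_label(1, 1, 0), "1 (1 + 0)")
  expect_identical(format_label(5, 2, 3), "5 (2 + 3)")
  expect_error(format_label(3, 1, 1), "identity violated")
  expect_error(format_label(0, 0, 0), "n >= 1")
  expect_error(format_label(2, -1, 3), "non-negative")
})

test_that("the full worked example enumerates to the published column of labels", {
  ann <- assign_lines(worked_example_history())
  expect_equal(ann$assignments$label, worked_example_labels)
  expect_equal(ann$assignments$serial_no, 1:10)
  # the taxane substitution is the one continuation, decided by G2
  expect_equal(ann$assignments$guideline,
               c("FIRST_SEGMENT", rep("G1", 4), "G2", rep("G1", 4)))
  expect_equal(nrow(ann$skipped), 0L)
  expect_true(ann$assignments$experimental[10])
  expect_false(any(ann$assignments$experimental[1:9]))
})

test_that("degenerate histories enumerate cleanly", {
  empty <- assign_lines(patient_history())
  expect_equal(nrow(empty$assignments), 0L)
  expect_equal(nrow(empty$skipped), 0L)
  expect_length(empty$warnings, 0L)

  one <- assign_lines(patient_history(list(
    therapy_segment(1, d("2020 Jan 01"), "5A:i", clinical_setting = "2A",
                    treatment_intent = "3A",
                    agents = list(ag("doxorubicin", "anthracycline", "i"))))))
  expect_equal(one$assignments$label, "1 (1 + 0)")

  # ongoing segment (no stop date) is assigned like any other
  ongoing <- assign_lines(patient_history(list(
    sact_segment(1, "2024-01-01", list(ag("x", "cls", "i")), stop = NA))))
  expect_equal(ongoing$assignments$label, "1 (0 + 1)")
})

test_that("enumeration refuses histories with blocking validation errors", {
  h <- worked_example_history()
  h$segments[[3]]$stop_date <- d("2014 Jan 01")
  err <- tryCatch(assign_lines(h), lot_validation_error = function(e) e)
  expect_s3_class(err, "lot_validation_error")
  expect_s3_class(err$report, "lot_validation")
  expect_true(any(err$report$severity == "ERROR"))
})

test_that("each primary organ keeps independent counters and tracks", {
  segs <- list(
    sact_segment(1, "2018-01-01", list(ag("docetaxel", "taxane", "i")),
                 setting = "2A", intent = "3A", primary = "breast"),
    sact_segment(2, "2019-01-01", list(ag("cisplatin", "platinum", "i")),
                 setting = "2C", intent = "3B", primary = "lung"),
    sact_segment(3, "2020-01-01", list(ag("capecitabine", "fluoropyrimidine", "i")),
                 cpd = "2019-06-01", setting = "2C", intent = "3B",
                 primary = "breast"))
  ann <- assign_lines(patient_history(segs))
  a <- ann$assignments
  expect_equal(a$label[a$serial_no == 1], "1 (1 + 0)")
  expect_equal(a$label[a$serial_no == 2], "1 (0 + 1)")  # lung restarts at 1
  expect_equal(a$label[a$serial_no == 3], "2 (1 + 1)")  # breast continues
  s <- summary(ann)
  expect_setequal(s$per_primary$primary_id, c("breast", "lung"))
  expect_equal(s$per_primary$n_lines[s$per_primary$primary_id == "breast"], 2L)
})

test_that("label invariants hold along the worked example", {
  a <- assign_lines(worked_example_history())$assignments
  expect_true(all(a$line_number == a$clot + a$plot))
  steps <- diff(a$line_number)
  expect_true(all(steps %in% c(0L, 1L)))
  expect_true(all(diff(a$clot) >= 0) && all(diff(a$plot) >= 0))
  # exactly one of the two counters increments when the line number does
  inc <- which(steps == 1L) + 1L
  expect_true(all((a$clot[inc] - a$clot[inc - 1L]) +
                  (a$plot[inc] - a$plot[inc - 1L]) == 1L))
  expect_true(all(grepl("^[0-9]+ \\([0-9]+ \\+ [0-9]+\\)$", a$label)))
})

test_that("summary reports totals, metastatic-opened lines and treatment-free intervals", {
  ann <- assign_lines(worked_example_history())
  s <- summary(ann)
  expect_equal(s$per_primary$n_lines, 9L)
  expect_equal(s$per_primary$clot, 2L)
  expect_equal(s$per_primary$plot, 7L)
  expect_equal(s$per_primary$current_label, "9 (2 + 7)")
  # lines 4-9 opened in the metastatic setting
  expect_equal(s$per_primary$metastatic_lines, 6L)
  # disease-free interval feeding "relapse within X" eligibility queries:
  # line 1 stopped 2005 Aug 14, next cPD documented 2010 Dec 22
  iv <- s$intervals
  expect_equal(iv$line_number, 1:8)
  expect_equal(iv$interval_days[1],
               as.numeric(d("2010 Dec 22") - d("2005 Aug 14")))
  # the docetaxel line: progression documented days before therapy stopped
  expect_equal(iv$interval_days[iv$line_number == 5],
               as.numeric(d("2017 Dec 17") - d("2017 Dec 23")))

  empty <- summary(assign_lines(patient_history()))
  expect_equal(nrow(empty$per_primary), 0L)
  expect_equal(nrow(empty$intervals), 0L)
})

test_that("non-qualifying segments are inert and free text never changes output", {
  h <- worked_example_history()
  # interleave surgery / radiotherapy / other-local segments
  extra <- list(
    therapy_segment(11, d("2014 Jun 01"), "5C", clinical_setting = "2A",
                    treatment_intent = "3A", comments = "reconstruction"),
    therapy_segment(12, d("2017 Jan 20"), "5D", clinical_setting = "2C",
                    treatment_intent = "3B", cpd_date = d("2017 Jan 07"),
                    comments = "palliative RT"),
    therapy_segment(13, d("2019 Jan 10"), "5E", clinical_setting = "2C",
                    treatment_intent = "3B", comments = "cryotherapy"))
  h_aug <- patient_history(c(h$segments, extra), patient_id = h$patient_id)
  ann_aug <- assign_lines(h_aug)
  expect_equal(nrow(ann_aug$skipped), 3L)
  a <- ann_aug$assignments
  expect_equal(a$label[match(1:10, a$serial_no)], worked_example_labels)

  # mutating comments cannot change any assignment
  h_mut <- h
  for (i in seq_along(h_mut$segments)) {
    h_mut$segments[[i]]$comments <- paste("scrambled", i)
  }
  expect_equal(assign_lines(h_mut)$assignments, assign_lines(h)$assignments)
})

test_that("a curative-track line may follow palliative-track lines", {
  segs <- list(
    sact_segment(1, "2020-01-01", list(ag("folfox", "regimen", "i")),
                 setting = "2C", intent = "3B"),
    # oligometastatic disease rendered resectable: curative conversion
    sact_segment(2, "2021-01-01", list(ag("capecitabine", "fluoropyrimidine", "i")),
                 cpd = "2020-10-01", setting = "2C", intent = "3A"))
  a <- assign_lines(patient_history(segs))$assignments
  expect_equal(a$label, c("1 (0 + 1)", "2 (1 + 1)"))
  expect_equal(a$track, c("PALLIATIVE", "CURATIVE"))
})
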