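fixed_time <- as.POSIXct("2026-01-02 03:04:05", tz = "UTC")

test_that("report tallies and highlights mirror the result list", {
  res <- run_process(clean_chart(), "seed_ordering", default_registry())
  report <- summary_report(res, "seed_ordering", "P001", fixed_time)
  expect_identical(unname(report$tallies$severity[["pass"]]), 20L)
  expect_length(report$highlighted, 0)
  text <- render_report(report, "text")
  expect_match(text, "20 checks, 0 warnings, 0 errors", fixed = TRUE)
  expect_match(text, "none")  # empty highlighted section

  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "prescription",
                                field = "prostate_volume",
                                kind = "inconsistent_value",
                                magnitude = 3)))
  res2 <- run_process(load_chart(dir), "seed_ordering",
                      default_registry())
  report2 <- summary_report(res2, "seed_ordering", "P001", fixed_time)
  expect_true(length(report2$highlighted) >= 1)
  # highlighted preserves order and holds only warnings/errors
  sev <- vapply(report2$highlighted, function(r) r$severity, character(1))
  expect_true(all(sev %in% c("warning", "error")))
  text2 <- render_report(report2, "text")
  expect_match(text2, "Highlighted variances:")
  expect_match(text2, "inconsistent prostate_volume")
})

test_that("each check type renders with its own symbol", {
  res <- run_process(clean_chart(), "seed_ordering", default_registry())
  report <- summary_report(res, "seed_ordering", "P001", fixed_time)
  lines <- strsplit(render_report(report, "text"), "\n")[[1]]
  expect_identical(sum(startsWith(lines, "[C]")), 12L)
  expect_identical(sum(startsWith(lines, "[X]")), 3L)
  expect_identical(sum(startsWith(lines, "[R]")), 5L)
})

test_that("an empty result list still renders a valid report", {
  report <- summary_report(list(), "seed_ordering", "P000", fixed_time)
  expect_match(render_report(report, "text"),
               "0 checks, 0 warnings, 0 errors", fixed = TRUE)
  parsed <- parse_report_json(render_report(report, "json"))
  expect_length(parsed$results, 0)
  expect_error(render_report(report, "pdf"), "unknown report format")
})

test_that("JSON reports round-trip every check-result field", {
  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "prescription",
                                field = "prostate_volume",
                                kind = "inconsistent_value",
                                magnitude = 3)))
  res <- run_process(load_chart(dir), "full_chart", default_registry())
  report <- summary_report(res, "full_chart", "P001", fixed_time)
  parsed <- parse_report_json(render_report(report, "json"))
  expect_length(parsed$results, length(res))
  for (i in seq_along(res)) {
    expect_equal(parsed$results[[i]], res[[i]],
                 label = paste("result", i))
  }
  expect_identical(parsed$patient_id, "P001")
  expect_identical(unlist(parsed$tallies$severity),
                   stats::setNames(as.integer(report$tallies$severity),
                                   names(report$tallies$severity)))
})

test_that("rendered bytes are deterministic for fixed input and timestamp", {
  res <- run_process(clean_chart(), "seed_ordering", default_registry())
  report <- summary_report(res, "seed_ordering", "P001", fixed_time)
  expect_identical(render_report(report, "text"),
                   render_report(report, "text"))
  expect_identical(render_report(report, "json"),
                   render_report(report, "json"))
})

test_that("saved reports never overwrite and name the patient and process", {
  res <- run_process(clean_chart(), "seed_ordering", default_registry())
  out <- tempfile("reports")
  dir.create(out)
  p1 <- save_report(summary_report(res, "seed_ordering", "P001",
                                   fixed_time), out)
  p2 <- save_report(summary_report(res, "seed_ordering", "P001",
                                   fixed_time + 1), out)
  expect_true(file.exists(p1))
  expect_true(file.exists(p2))
  expect_false(p1 == p2)
  expect_match(basename(p1), "^P001_seed_ordering_")
  expect_error(save_report(summary_report(res, "seed_ordering", "P001",
                                          fixed_time),
                           file.path(out, "missing-subdir")),
               "does not exist")
})

test_that("dispatch queues to an outbox in integration mode only", {
  res <- run_process(clean_chart(), "seed_ordering", default_registry())
  report <- summary_report(res, "seed_ordering", "P001", fixed_time)
  outbox <- tempfile("outbox")
  rec <- dispatch_report(report, "physicist@example.org", outbox)
  expect_true(rec$queued)
  expect_true(file.exists(file.path(rec$entry, "report.txt")))
  meta <- jsonlite::read_json(file.path(rec$entry, "dispatch.json"))
  expect_identical(unlist(meta$recipients), "physicist@example.org")

  none <- dispatch_report(report, character(0), outbox)
  expect_false(none$queued)
  expect_error(dispatch_report(report, "x@example.org", outbox,
                               mode = "standalone"), "integration-only")
})

test_that("reports carry only pseudonymous identifiers", {
  res <- run_process(clean_chart(), "full_chart", default_registry())
  report <- summary_report(res, "full_chart", "P001", fixed_time)
  text <- render_report(report, "text")
  # the only patient reference is the pseudonymous id
  expect_match(text, "Patient: P001", fixed = TRUE)
  expect_false(grepl("Physician A", text, fixed = TRUE))
})
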