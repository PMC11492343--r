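test_that("completeness emits one result per required auto-checkable field", {
  registry <- default_registry()
  chart <- clean_chart()
  for (kind in audit_core_kinds()) {
    schema <- schema_for(kind, registry)
    res <- run_completeness(chart$documents[[kind]], schema)
    n_required <- sum(vapply(schema$fields, function(f)
      f$required && !f$manual_only, logical(1)))
    expect_length(res, n_required)
    expect_true(all(vapply(res, function(r) r$severity, character(1)) ==
                      "pass"))
  }
})

test_that("missing, unparsable and off-expectation fields are errors", {
  registry <- default_registry()
  dir <- mutable_chart_dir()
  inject_defects(dir, list(
    list(document = "prescription", field = "attestation",
         kind = "delete"),
    list(document = "prescription", field = "prior_dose", kind = "typo")))
  doc <- load_chart(dir, registry)$documents$prescription
  res <- run_completeness(doc, schema_for("prescription", registry))
  by_id <- stats::setNames(res, vapply(res, function(r) r$check_id,
                                       character(1)))
  att <- by_id[["completeness:prescription:attestation"]]
  expect_identical(att$severity, "error")
  expect_match(att$message, "missing details in attestation")
  expect_identical(
    by_id[["completeness:prescription:prior_dose"]]$severity, "error")

  # expected-value mismatch: source activity must be 0.36 mCi
  doc$fields$source_activity$value <- 0.4
  doc$fields$source_activity$raw_text <- "0.4 mCi"
  res <- run_completeness(doc, schema_for("prescription", registry))
  act <- Filter(function(r)
    r$check_id == "completeness:prescription:source_activity", res)[[1]]
  expect_identical(act$severity, "error")
  expect_match(act$message, "0.36")
})

test_that("consistency passes on agreement and escalates on discrepancy", {
  registry <- default_registry()
  rules <- default_consistency_rules()
  chart <- clean_chart()
  res <- run_consistency(chart, rules$prostate_volume, registry)
  expect_length(res, 1)
  expect_identical(res[[1]]$severity, "pass")

  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "prescription",
                                field = "prostate_volume",
                                kind = "inconsistent_value",
                                magnitude = 3)))
  mutated <- load_chart(dir, registry)
  res <- run_consistency(mutated, rules$prostate_volume, registry)
  expect_identical(res[[1]]$severity, "warning")
  expect_match(res[[1]]$message, "inconsistent prostate_volume")
  # the discrepancy triggers a completeness pass over both documents
  triggered <- res[-1]
  n_req <- function(kind) sum(vapply(
    schema_for(kind, registry)$fields, function(f)
      f$required && !f$manual_only, logical(1)))
  expect_length(triggered, n_req("prescription") + n_req("volume_report"))
  expect_true(all(vapply(triggered, function(r)
    identical(r$triggered_by, "consistency:prostate_volume"), logical(1))))
})

test_that("seed-count disagreement across three documents is an error", {
  registry <- default_registry()
  rules <- default_consistency_rules()
  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "end_of_treatment",
                                field = "implanted_seed_count",
                                kind = "inconsistent_value",
                                magnitude = 2)))
  chart <- load_chart(dir, registry)
  res <- run_consistency(chart, rules$implanted_seed_count, registry)
  expect_identical(res[[1]]$severity, "error")
  kinds <- vapply(res[[1]]$involved, function(i) i[1], character(1))
  expect_setequal(kinds, c("quality_checklist", "survey_report",
                           "end_of_treatment"))
})

test_that("consistency degrades to manual when comparison is impossible", {
  registry <- default_registry()
  rules <- default_consistency_rules()
  chart <- clean_chart()
  partial <- patient_chart(chart$patient_id,
                           chart$documents["prescription"], "active")
  res <- run_consistency(partial, rules$prostate_volume, registry)
  expect_identical(res[[1]]$severity, "manual_required")
  expect_match(res[[1]]$message, "absent")

  # a unit mismatch between compared fields is a configuration error
  broken <- chart
  broken$documents$volume_report$fields$prostate_volume$unit <- "mL"
  expect_error(run_consistency(broken, rules$prostate_volume, registry),
               "mismatched units")
  # numeric comparator on non-numeric fields is a configuration error too
  bad_rule <- consistency_rule("names",
                               list(c("prescription", "physician_name"),
                                    c("volume_report", "physician_name")),
                               comparator = "numeric_tolerance")
  expect_error(run_consistency(chart, bad_rule, registry), "non-numeric")
})

test_that("range checks use inclusive bounds and discrete allowed sets", {
  registry <- default_registry()
  doc <- clean_chart()$documents$prescription
  spec <- schema_for("prescription", registry)$fields$prostate_volume

  at <- function(value) {
    doc$fields$prostate_volume$value <- value
    doc$fields$prostate_volume$raw_text <- paste(value, "cm3")
    run_range(doc, spec)
  }
  expect_identical(at(10)$severity, "pass")   # boundary inclusive
  expect_identical(at(80)$severity, "pass")
  expect_identical(at(9.9)$severity, "error")
  expect_identical(at(80.1)$severity, "error")

  dose_spec <- schema_for("prescription", registry)$fields$prescribed_dose
  doc$fields$prescribed_dose$value <- 145
  expect_identical(run_range(doc, dose_spec)$severity, "pass")
  doc$fields$prescribed_dose$value <- 120
  doc$fields$prescribed_dose$raw_text <- "120 Gy"
  expect_identical(run_range(doc, dose_spec)$severity, "error")

  # a missing value defers to the completeness layer
  doc$fields$prostate_volume$status <- "missing"
  doc$fields$prostate_volume$value <- NULL
  res <- run_range(doc, spec)
  expect_identical(res$severity, "pass")
  expect_match(res$message, "not evaluated")
})

test_that("the seed-ordering process runs 20 checks, all passing when clean", {
  res <- run_process(clean_chart(), "seed_ordering", default_registry())
  expect_length(res, 20)
  sev <- vapply(res, function(r) r$severity, character(1))
  expect_identical(sum(sev %in% c("warning", "error")), 0L)
  types <- vapply(res, function(r) r$check_type, character(1))
  expect_identical(as.vector(table(types)[c("completeness", "consistency",
                                            "range")]),
                   c(12L, 3L, 5L))
  # layer order: completeness first, then consistency, then range
  expect_identical(rle(types)$values, c("completeness", "consistency",
                                        "range"))
})

test_that("an injected volume typo flags only the affected checks", {
  registry <- default_registry()
  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "prescription",
                                field = "prostate_volume",
                                kind = "inconsistent_value",
                                magnitude = 3)))
  res <- run_process(load_chart(dir, registry), "seed_ordering", registry)
  flagged <- Filter(function(r) r$severity %in% c("warning", "error"), res)
  expect_true(length(flagged) >= 1)
  for (r in flagged) {
    fields <- vapply(r$involved, function(i) i[2], character(1))
    expect_true("prostate_volume" %in% fields ||
                  "seeds_ordered" %in% fields)
  }
})

test_that("a chart without the volume report degrades to manual results", {
  registry <- default_registry()
  chart <- clean_chart()
  chart$documents$volume_report <- NULL
  res <- run_process(chart, "seed_ordering", registry)
  expect_length(res, 20)
  sev <- vapply(res, function(r) r$severity, character(1))
  ids <- vapply(res, function(r) r$check_id, character(1))
  expect_identical(sum(sev %in% c("warning", "error")), 0L)
  expect_true(all(sev[grepl("volume_report", ids)] == "manual_required"))
  expect_identical(
    sev[ids == "consistency:prostate_volume"], "manual_required")
})

test_that("escalation references always point at a failed consistency check", {
  registry <- default_registry()
  dir <- mutable_chart_dir()
  inject_defects(dir, list(
    list(document = "prescription", field = "prostate_volume",
         kind = "inconsistent_value", magnitude = 4),
    list(document = "end_of_treatment", field = "needle_count",
         kind = "inconsistent_value", magnitude = 2)))
  res <- run_process(load_chart(dir, registry), "full_chart", registry)
  ids <- vapply(res, function(r) r$check_id, character(1))
  sev <- vapply(res, function(r) r$severity, character(1))
  triggered <- Filter(function(r) !is.null(r$triggered_by), res)
  expect_true(length(triggered) > 0)
  for (r in triggered) {
    expect_identical(r$check_type, "completeness")
    source_sev <- sev[ids == r$triggered_by]
    expect_true(all(source_sev != "pass"))
  }
})

test_that("the engine supports config-registered kinds such as plan reports", {
  registry <- default_registry()
  registry$plan_report <- document_schema("plan_report", list(
    field_spec("patient_id", "Patient ID"),
    field_spec("implanted_seed_count", value_type = "integer",
               unit = "seeds")))
  rule <- consistency_rule("seed_count_plan",
                           list(c("quality_checklist",
                                  "implanted_seed_count"),
                                c("plan_report", "implanted_seed_count")),
                           severity_on_mismatch = "error")
  plan_path <- tempfile(fileext = ".docx")
  psichart:::write_docx(plan_path, list(
    list(type = "para", text = "Patient ID: P001"),
    list(type = "para", text = "Implanted seed count: 73")))
  chart <- clean_chart()  # quality checklist records 71
  chart$documents$plan_report <- parse_document(plan_path, "plan_report",
                                                registry$plan_report)
  res <- run_consistency(chart, rule, registry)
  expect_identical(res[[1]]$severity, "error")
})
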