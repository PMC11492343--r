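test_that("numeric values parse with unit synonyms normalized", {
  activity <- field_spec("source_activity", value_type = "number",
                         unit = "mCi")
  out <- parse_value("0.36 mCi", activity)
  expect_identical(out$status, "found")
  expect_equal(out$value, 0.36)
  expect_identical(out$unit, "mCi")

  volume <- field_spec("prostate_volume", value_type = "number",
                       unit = "cm³")
  for (raw in c("35 cc", "35 cm3", "35 cm³", "35")) {
    out <- parse_value(raw, volume)
    expect_equal(out$value, 35)
    expect_identical(out$unit, "cm³")
  }
  # a wrong unit is not silently accepted
  expect_identical(parse_value("35 Gy", volume)$status, "unparsable")
})

test_that("blank, non-numeric and malformed values surface as statuses", {
  spec <- field_spec("needle_count", value_type = "integer")
  expect_identical(parse_value("", spec)$status, "missing")
  expect_identical(parse_value("2x4", spec)$status, "unparsable")
  expect_identical(parse_value("24.5", spec)$status, "unparsable")
  expect_identical(parse_value("24", spec)$value, 24L)
})

test_that("enumerations validate dropdown content and dates accept two forms", {
  modality <- field_spec("imaging_modality", value_type = "enumeration",
                         options = c("CT", "US", "MRI"))
  expect_identical(parse_value("ct", modality)$value, "CT")
  expect_identical(parse_value("PET", modality)$status, "unparsable")

  date <- field_spec("procedure_date", value_type = "date")
  expect_identical(parse_value("2024-03-12", date)$value,
                   as.Date("2024-03-12"))
  expect_identical(parse_value("03/12/2024", date)$value,
                   as.Date("2024-03-12"))
  expect_identical(parse_value("12 March 2024", date)$status, "unparsable")

  box <- field_spec("consent_confirmed", value_type = "checkbox")
  expect_true(parse_value("Yes", box)$value)
  expect_false(parse_value("No", box)$value)
  expect_identical(parse_value("maybe", box)$status, "unparsable")
})

test_that("a complete synthetic document extracts every field", {
  chart <- clean_chart()
  for (kind in audit_core_kinds()) {
    doc <- chart$documents[[kind]]
    statuses <- vapply(doc$fields, function(f) f$status, character(1))
    expect_true(all(statuses == "found"),
                label = paste("all", kind, "fields found"))
  }
  expect_identical(chart$documents$prescription$fields$seeds_ordered$value,
                   75L)
})

test_that("DOCX and PDF renderings extract identically", {
  docx <- clean_chart("docx")
  pdf <- clean_chart("pdf")
  for (kind in audit_core_kinds()) {
    fd <- docx$documents[[kind]]$fields
    fp <- pdf$documents[[kind]]$fields
    expect_identical(names(fd), names(fp))
    for (nm in names(fd)) {
      expect_identical(fd[[nm]]$status, fp[[nm]]$status,
                       label = paste(kind, nm, "status"))
      expect_identical(fd[[nm]]$value, fp[[nm]]$value,
                       label = paste(kind, nm, "value"))
    }
  }
})

test_that("a document missing a label yields a missing field, not an error", {
  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "prescription",
                                field = "attestation", kind = "delete")))
  for (prefer in c("docx", "pdf")) {
    chart <- load_chart(dir, prefer = prefer)
    expect_identical(chart$documents$prescription$fields$attestation$status,
                     "missing")
  }
})

test_that("picture-backed fields are skipped, not misread", {
  dir <- mutable_chart_dir()
  inject_defects(dir, list(list(document = "prescription",
                                field = "attestation",
                                kind = "image_substitute")))
  for (prefer in c("docx", "pdf")) {
    chart <- load_chart(dir, prefer = prefer)
    f <- chart$documents$prescription$fields$attestation
    expect_identical(f$status, "image_skipped", label = prefer)
    expect_null(f$value)
  }
})

test_that("a fully rasterized PDF marks every field image_skipped", {
  path <- tempfile(fileext = ".pdf")
  # a page that paints only an image: no text layer at all
  psichart:::write_pdf(path, list(list(type = "para", text = "",
                                       image = TRUE)))
  schema <- schema_for("prescription", default_registry())
  doc <- parse_document(path, "prescription", schema)
  statuses <- vapply(doc$fields, function(f) f$status, character(1))
  expect_true(all(statuses == "image_skipped"))
})

test_that("file-level problems raise while content anomalies do not", {
  schema <- schema_for("prescription", default_registry())
  expect_error(parse_document(tempfile(fileext = ".docx"), "prescription",
                              schema), "not found")
  bad <- tempfile(fileext = ".docx")
  writeLines("this is not a zip archive", bad)
  expect_error(parse_document(bad, "prescription", schema), "cannot read")
  expect_error(parse_document(tempfile(fileext = ".csv"), "prescription",
                              schema), "unsupported")
  vol_schema <- schema_for("volume_report", default_registry())
  src <- file.path(clean_chart_dir(), "prescription.docx")
  expect_error(parse_document(src, "prescription", vol_schema), "mismatch")
})
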