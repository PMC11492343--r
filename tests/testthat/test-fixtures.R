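test_that("chart parameters enforce the dose/treatment pairing and domain", {
  expect_error(chart_params("P1", dose = 120), "dose")
  expect_error(chart_params("P1", dose = 145, treatment_type = "Boost"),
               "pairs with")
  expect_error(chart_params("P1", prostate_volume = 5),
               "outside nomogram domain")
  boost <- chart_params("P1", prostate_volume = 40, dose = 110)
  expect_identical(boost$treatment_type, "Boost")
})

test_that("the generated seed order is the nomogram value rounded up to 5", {
  chart <- clean_chart()  # volume 30, 145 Gy: nomogram 71
  expect_identical(chart$documents$prescription$fields$seeds_ordered$value,
                   75L)
  dir <- tempfile()
  generate_chart(chart_params("P2", prostate_volume = 60, dose = 110),
                 dir)  # nomogram 100, already a multiple of 5
  chart2 <- load_chart(dir)
  expect_identical(chart2$documents$prescription$fields$seeds_ordered$value,
                   100L)
})

test_that("generation is byte-deterministic for fixed parameters", {
  params <- chart_params("P7", prostate_volume = 42.5, dose = 145,
                         rng_seed = 9L)
  d1 <- tempfile()
  d2 <- tempfile()
  generate_chart(params, d1, formats = c("docx", "pdf"))
  generate_chart(params, d2, formats = c("docx", "pdf"))
  for (f in list.files(d1)) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2, label = f)
  }
})

test_that("every fixture field extracts before defect injection (closure)", {
  registry <- default_registry()
  for (seed in c(11L, 12L)) {
    dir <- tempfile()
    generate_chart(random_chart_params(sprintf("P%d", seed), seed), dir,
                   formats = if (seed %% 2 == 0) "pdf" else "docx")
    chart <- load_chart(dir, registry)
    for (kind in audit_core_kinds()) {
      statuses <- vapply(chart$documents[[kind]]$fields,
                         function(f) f$status, character(1))
      expect_true(all(statuses == "found"),
                  label = paste("seed", seed, kind))
    }
  }
})

test_that("defect injection records ground truth and hits its targets", {
  registry <- default_registry()
  dir <- mutable_chart_dir()
  log <- inject_defects(dir, list(
    list(document = "prescription", field = "prostate_volume",
         kind = "inconsistent_value", magnitude = 3),
    list(document = "prescription", field = "attestation",
         kind = "delete"),
    list(document = "survey_report", field = "surface_anterior",
         kind = "typo"),
    list(document = "survey_report", field = "pecu_reading",
         kind = "out_of_range", magnitude = 4)))
  expect_length(log, 4)
  expect_identical(log[[1]]$expected_flags[[1]],
                   "consistency:prostate_volume")
  expect_identical(log[[2]]$expected_flags[[1]],
                   "completeness:prescription:attestation")
  expect_identical(log[[3]]$expected_flags[[1]],
                   "completeness:survey_report:surface_anterior")
  expect_identical(log[[4]]$expected_flags[[1]],
                   "range:survey_report:pecu_reading")
  expect_true(all(vapply(log, function(m) m$detectable, logical(1))))

  res <- run_process(load_chart(dir, registry), "full_chart", registry)
  ids <- vapply(res, function(r) r$check_id, character(1))
  sev <- vapply(res, function(r) r$severity, character(1))
  for (m in log) {
    flagged <- sev[ids %in% unlist(m$expected_flags)]
    expect_true(all(flagged != "pass"),
                label = paste(m$kind, m$field))
  }
  # ground truth is also persisted beside the chart
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("free-text typos are logged as undetectable by rule checks", {
  dir <- mutable_chart_dir()
  log <- inject_defects(dir, list(
    list(document = "prescription", field = "prostate_stage",
         kind = "typo")))
  expect_false(log[[1]]$detectable)
})

test_that("injection refuses targets that do not exist", {
  dir <- mutable_chart_dir()
  expect_error(inject_defects(dir, list(
    list(document = "prescription", field = "no_such_field",
         kind = "delete"))), "no field")
  expect_error(inject_defects(dir, list(
    list(document = "prescription", field = "attestation",
         kind = "out_of_range"))), "no allowable range")
  expect_error(inject_defects(tempfile(), list()), "manifest")
})

test_that("the validation suite is reproducible for a fixed seed", {
  d1 <- tempfile()
  d2 <- tempfile()
  s1 <- build_validation_suite(1, 2, 77L, d1)
  s2 <- build_validation_suite(1, 2, 77L, d2)
  expect_identical(lapply(s1$charts, function(ch) ch$defects),
                   lapply(s2$charts, function(ch) ch$defects))
  for (ch in seq_along(s1$charts)) {
    files <- list.files(s1$charts[[ch]]$dir)
    for (f in setdiff(files, c("manifest.json", "ground_truth.json"))) {
      p1 <- file.path(s1$charts[[ch]]$dir, f)
      p2 <- file.path(s2$charts[[ch]]$dir, f)
      expect_identical(readBin(p1, "raw", file.size(p1)),
                       readBin(p2, "raw", file.size(p2)), label = f)
    }
  }
  expect_true(file.exists(s1$patient_list))
})
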