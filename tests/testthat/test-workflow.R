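write_patient_list <- function(lines, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("patient selection filters by care-path status in file order", {
  path <- write_patient_list(c(
    "patient_id\tcare_path_status\tchart_dir",
    "P001\tactive\t/charts/P001",
    "P002\tcompleted\t/charts/P002",
    "P003\tactive\t/charts/P003",
    "P004\tcompleted\t/charts/P004",
    "P005\tactive\t/charts/P005"))
  sel <- select_patients(path, "active")
  expect_identical(sel$patient_id, c("P001", "P003", "P005"))
  expect_identical(select_patients(path, "on_hold")$patient_id,
                   character(0))
  # comma-delimited lists work too
  csv <- write_patient_list(c("patient_id,care_path_status,chart_dir",
                              "P009,active,/charts/P009"))
  expect_identical(select_patients(csv, "active")$patient_id, "P009")
})

test_that("malformed patient lists fail with a located parse error", {
  empty <- write_patient_list("patient_id\tcare_path_status\tchart_dir")
  expect_identical(nrow(select_patients(empty, "active")), 0L)
  ragged <- write_patient_list(c(
    "patient_id\tcare_path_status\tchart_dir",
    "P001\tactive\t/charts/P001",
    "P002\tactive"))
  expect_error(select_patients(ragged, "active"), "line 3")
  nostatus <- write_patient_list(c("patient_id\tchart_dir",
                                   "P001\t/charts/P001"))
  expect_error(select_patients(nostatus, "active"), "care_path_status")
  expect_error(select_patients(tempfile(), "active"), "not found")
})

test_that("the check subcommand exits 0/1/2 by worst severity", {
  out <- tempfile()
  expect_identical(run_cli(c("check", "--chart", clean_chart_dir(),
                             "--process", "seed_ordering",
                             "--out", out)), 0L)
  expect_length(list.files(out, pattern = "seed_ordering.*txt$"), 1)
  expect_true(file.exists(file.path(out, "run.log")))

  warn_dir <- mutable_chart_dir()
  inject_defects(warn_dir, list(list(document = "prescription",
                                     field = "prostate_volume",
                                     kind = "inconsistent_value",
                                     magnitude = 3)))
  expect_identical(run_cli(c("check", "--chart", warn_dir, "--out", out)),
                   1L)

  err_dir <- mutable_chart_dir()
  inject_defects(err_dir, list(list(document = "prescription",
                                    field = "attestation",
                                    kind = "delete")))
  expect_identical(run_cli(c("check", "--chart", err_dir, "--process",
                             "full_chart", "--out", out)), 2L)
})

test_that("usage problems exit 3 with diagnostics on stderr", {
  expect_identical(suppressMessages(run_cli(character(0))), 3L)
  expect_identical(suppressMessages(run_cli("frobnicate")), 3L)
  expect_identical(suppressMessages(run_cli(c("check", "--out",
                                              tempfile()))), 3L)
  expect_identical(suppressMessages(run_cli(c("batch", "--out",
                                              tempfile()))), 3L)
})

test_that("batch mode equals independent standalone runs per patient", {
  suite_dir <- tempfile()
  suite <- build_validation_suite(2, 1, 5L, suite_dir)
  out_batch <- tempfile()
  out_single <- tempfile()
  code_batch <- suppressMessages(run_cli(c(
    "batch", "--patients", suite$patient_list, "--status", "active",
    "--process", "seed_ordering", "--out", out_batch)))
  codes_single <- vapply(suite$charts, function(ch)
    run_cli(c("check", "--chart", ch$dir, "--process", "seed_ordering",
              "--out", out_single)), integer(1))
  expect_identical(code_batch, max(codes_single))
  # per-patient report bodies match between the two modes
  strip_time <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines[!grepl("Time:", lines)]
  }
  for (ch in suite$charts) {
    rb <- list.files(out_batch, pattern = paste0("^", ch$patient_id, "_"),
                     full.names = TRUE)
    rs <- list.files(out_single, pattern = paste0("^", ch$patient_id, "_"),
                     full.names = TRUE)
    expect_identical(strip_time(rb[1]), strip_time(rs[1]),
                     label = ch$patient_id)
  }
  # structured run log: one line per patient
  log <- readLines(file.path(out_batch, "run.log"))
  expect_length(log, length(suite$charts))
  expect_true(all(grepl("seed_ordering\tpass=", log)))
})

test_that("the generate subcommand builds a loadable suite", {
  out <- tempfile()
  code <- suppressMessages(run_cli(c("generate", "--n-clean", "1",
                                     "--n-defective", "1", "--seed", "3",
                                     "--out", out)))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "suite_manifest.json")))
  chart <- load_chart(file.path(out, "P001"))
  expect_identical(chart$patient_id, "P001")
  expect_length(chart$documents, 5)
})

test_that("audit subcommand appends the manual to-do to the report", {
  out <- tempfile()
  expect_identical(run_cli(c("audit", "--chart", clean_chart_dir(),
                             "--out", out)), 0L)
  report <- list.files(out, pattern = "monthly_audit.*txt$",
                       full.names = TRUE)
  lines <- readLines(report[1], warn = FALSE)
  expect_true(any(grepl("Manual inspection to-do \\(8\\):", lines)))
  expect_true(any(grepl("Seed vendor confirmation", lines)))
})
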