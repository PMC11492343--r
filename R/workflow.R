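# Execution modes and the command-line interface.
#
# Standalone mode checks one explicitly named chart directory; integration
# mode batches over a patient-list file (the filesystem stand-in for the
# EMR middleware): a delimited table with header columns patient_id,
# care_path_status, chart_dir. Exit codes: 0 no warnings/errors, 1
# warnings only, 2 errors present, 3 usage/configuration failure.

#' Select patients from a care-path list
#'
#' @param patient_list Path to a tab- or comma-delimited file with header
#'   columns `patient_id`, `care_path_status`, `chart_dir`.
#' @param status_filter Care-path status to keep (statuses are opaque
#'   strings; comparison is exact).
#' @return Data frame of the matching rows, in file order.
#' @export
select_patients <- function(patient_list, status_filter = "active") {
  if (!file.exists(patient_list))
    stop("patient list not found: ", patient_list)
  first <- readLines(patient_list, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  nf <- utils::count.fields(patient_list, sep = sep, quote = "\"")
  expected <- nf[1]
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1]
    stop("patient list parse error at line ", bad, " of ", patient_list,
         ": expected ", expected, " fields, found ", nf[bad])
  }
  df <- utils::read.table(patient_list, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  needed <- c("patient_id", "care_path_status", "chart_dir")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("patient list parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", patient_list)
  df[df$care_path_status == status_filter, needed, drop = FALSE]
}

#' Load a chart directory into a patient chart
#'
#' Looks for `<kind>.docx` / `<kind>.pdf` files for every audit-core kind
#' and parses those present. When a kind exists in both formats the
#' preferred one is used. The patient id and care-path status come from
#' the chart's `manifest.json` when present, else from the directory name.
#'
#' @param chart_dir Chart directory.
#' @param registry Schema registry.
#' @param prefer Preferred format when both exist.
#' @return A [patient_chart()].
#' @export
load_chart <- function(chart_dir, registry = load_schemas(),
                       prefer = "docx") {
  if (!dir.exists(chart_dir))
    stop("chart directory not found: ", chart_dir)
  patient_id <- basename(normalizePath(chart_dir))
  status <- ""
  manifest_path <- file.path(chart_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    if (!is.null(manifest$patient_id)) patient_id <- manifest$patient_id
    if (!is.null(manifest$care_path_status))
      status <- manifest$care_path_status
  }
  documents <- list()
  for (kind in audit_core_kinds()) {
    exts <- c(prefer, setdiff(c("docx", "pdf"), prefer))
    for (ext in exts) {
      path <- file.path(chart_dir, paste0(kind, ".", ext))
      if (file.exists(path)) {
        documents[[kind]] <- parse_document(path, kind,
                                            schema_for(kind, registry))
        break
      }
    }
  }
  patient_chart(patient_id, documents, status)
}

.exit_code <- function(tallies) {
  if (tallies[["error"]] > 0) 2L
  else if (tallies[["warning"]] > 0) 1L
  else 0L
}

.log_run <- function(out_dir, patient_id, process, tallies) {
  line <- sprintf("%s\t%s\t%s\tpass=%d warning=%d error=%d manual=%d",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), patient_id,
                  process, tallies[["pass"]], tallies[["warning"]],
                  tallies[["error"]], tallies[["manual_required"]])
  cat(line, "\n", sep = "", file = file.path(out_dir, "run.log"),
      append = TRUE)
}

.cli_usage <- function() {
  paste(
    "usage: psichart <subcommand> [options]",
    "",
    "subcommands:",
    "  check    --chart DIR [--process seed_ordering|full_chart]",
    "           [--config FILE] [--nomogram FILE] [--out DIR]",
    "           [--format docx|pdf] [--report text|json]",
    "  audit    --chart DIR [--config FILE] [--out DIR]",
    "  batch    --patients FILE [--status active] [--process NAME]",
    "           [--audit] [--out DIR]",
    "  generate --out DIR [--n-clean K] [--n-defective M] [--seed S]",
    "",
    "exit codes: 0 clean, 1 warnings, 2 errors, 3 usage/config failure",
    sep = "\n")
}

.parse_cli_opts <- function(args) {
  opts <- list()
  flags <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags <- c(flags, key)
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  list(opts = opts, flags = flags)
}

.cli_check_one <- function(chart_dir, process, registry, nomogram, out_dir,
                           prefer, report_format, audit_mode) {
  chart <- load_chart(chart_dir, registry, prefer = prefer)
  if (audit_mode) {
    audit <- run_monthly_audit(chart, registry = registry,
                               nomogram = nomogram)
    results <- audit$results
    process_name <- "monthly_audit"
    report <- summary_report(results, process_name, chart$patient_id)
    extra <- c("", sprintf("Manual inspection to-do (%d):",
                           length(audit$manual_todo)),
               vapply(audit$manual_todo, function(m)
                 sprintf("  - %s / %s: %s", m$category, m$item, m$reason),
                 character(1)), "")
  } else {
    results <- run_process(chart, process, registry, nomogram)
    process_name <- process
    report <- summary_report(results, process_name, chart$patient_id)
    extra <- NULL
  }
  path <- save_report(report, out_dir, report_format)
  if (!is.null(extra) && report_format == "text")
    cat(paste(extra, collapse = "\n"), file = path, append = TRUE)
  .log_run(out_dir, chart$patient_id, process_name,
           report$tallies$severity)
  .exit_code(report$tallies$severity)
}

#' Command-line entry point
#'
#' Subcommands: `check` (one chart, one process), `audit` (monthly audit
#' of one chart), `batch` (integration mode: every matching patient in a
#' care-path list, equivalent to independent per-patient runs), and
#' `generate` (synthetic validation fixtures). Diagnostics go to standard
#' error; reports and a structured run log are written to the output
#' directory.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   program name).
#' @return The exit code, invisibly: 0 = no warnings or errors, 1 =
#'   warnings only, 2 = errors present, 3 = usage or configuration
#'   failure.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0) {
      message(.cli_usage())
      return(invisible(3L))
    }
    sub <- args[1]
    parsed <- .parse_cli_opts(args[-1])
    opts <- parsed$opts
    flags <- parsed$flags
    out_dir <- opts$out %||% "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (sub %in% c("check", "audit")) {
      if (is.null(opts$chart))
        stop("standalone mode requires --chart DIR")
      registry <- load_schemas(opts$config)
      nomogram <- load_nomogram(opts$nomogram)
      .cli_check_one(opts$chart, opts$process %||% "seed_ordering",
                     registry, nomogram, out_dir,
                     opts$format %||% "docx", opts$report %||% "text",
                     audit_mode = identical(sub, "audit"))
    } else if (sub == "batch") {
      if (is.null(opts$patients))
        stop("integration mode requires --patients FILE")
      registry <- load_schemas(opts$config)
      nomogram <- load_nomogram(opts$nomogram)
      patients <- select_patients(opts$patients, opts$status %||% "active")
      codes <- 0L
      for (i in seq_len(nrow(patients))) {
        codes <- max(codes, .cli_check_one(
          patients$chart_dir[i], opts$process %||% "seed_ordering",
          registry, nomogram, out_dir, opts$format %||% "docx",
          opts$report %||% "text", audit_mode = "audit" %in% flags))
      }
      codes
    } else if (sub == "generate") {
      suite <- build_validation_suite(
        n_clean = as.integer(opts[["n-clean"]] %||% "1"),
        n_defective = as.integer(opts[["n-defective"]] %||% "0"),
        rng_seed = as.integer(opts$seed %||% "1"),
        out_dir = out_dir)
      message("generated ", length(suite$charts), " chart(s) under ",
              out_dir)
      0L
    } else {
      message(.cli_usage())
      stop("unknown subcommand: ", sub)
    }
  }, error = function(e) {
    message("psichart: ", conditionMessage(e))
    3L
  })
  invisible(code)
}
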