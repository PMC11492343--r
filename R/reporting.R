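# Summary reports highlighting practice variances.
#
# Three fixed ASCII markers distinguish the check types ([C] completeness,
# [X] consistency, [R] range) and severities are rendered as words, keeping
# reports terminal- and diff-friendly. Only pseudonymous patient ids ever
# appear; no PHI field is rendered.

.check_symbols <- c(completeness = "[C]", consistency = "[X]", range = "[R]")
.severity_words <- c(pass = "PASS", warning = "WARN", error = "ERROR",
                     manual_required = "MANUAL")

#' Assemble a summary report
#'
#' @param results Ordered list of [check_result()] (empty allowed).
#' @param process Process name the results came from.
#' @param patient_id Pseudonymous patient identifier.
#' @param timestamp Report time; injectable for deterministic output.
#' @return An object of class `summary_report` with severity/type tallies
#'   and the order-preserving `highlighted` subset (warnings and errors).
#' @export
summary_report <- function(results, process, patient_id,
                           timestamp = Sys.time()) {
  sev <- vapply(results, function(r) r$severity, character(1))
  type <- vapply(results, function(r) r$check_type, character(1))
  structure(list(
    process = process, patient_id = patient_id,
    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    results = results,
    tallies = list(severity = severity_tally(results),
                   type = c(completeness = sum(type == "completeness"),
                            consistency = sum(type == "consistency"),
                            range = sum(type == "range"))),
    highlighted = results[sev %in% c("warning", "error")]),
    class = "summary_report")
}

.render_line <- function(r) {
  trig <- if (!is.null(r$triggered_by))
    paste0("  <- triggered by ", r$triggered_by) else ""
  sprintf("%s %-6s %s  %s%s", .check_symbols[[r$check_type]],
          .severity_words[[r$severity]], r$check_id, r$message, trig)
}

#' Render a report as text or JSON
#'
#' The text format prefixes each line with the check-type symbol and a
#' severity word and repeats all warnings/errors in a highlighted section;
#' the JSON format is one record per check result plus a tally header.
#' Output bytes are deterministic for a fixed result list and timestamp.
#'
#' @param report A [summary_report()].
#' @param format `"text"` or `"json"`.
#' @return A single character scalar (the report artifact).
#' @export
render_report <- function(report, format = c("text", "json")) {
  if (length(format) > 1) format <- format[1]
  if (!format %in% c("text", "json"))
    stop("unknown report format: ", format)
  if (format == "json") {
    payload <- list(
      process = report$process, patient_id = report$patient_id,
      timestamp = report$timestamp,
      tallies = list(severity = as.list(report$tallies$severity),
                     type = as.list(report$tallies$type)),
      results = lapply(report$results, function(r) {
        list(check_id = r$check_id, check_type = r$check_type,
             severity = r$severity, message = r$message,
             involved = lapply(r$involved, function(i)
               list(kind = i[1], field = i[2])),
             triggered_by = r$triggered_by)
      }))
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         null = "null", pretty = TRUE)))
  }
  t <- report$tallies$severity
  header <- c(
    "=== PSI chart check report ===",
    sprintf("Patient: %s    Process: %s    Time: %s", report$patient_id,
            report$process, report$timestamp),
    sprintf("%d checks, %d warnings, %d errors", length(report$results),
            t[["warning"]], t[["error"]]),
    sprintf("(%d pass, %d manual inspection required)", t[["pass"]],
            t[["manual_required"]]),
    strrep("-", 70))
  body <- vapply(report$results, .render_line, character(1))
  high <- c(strrep("-", 70), "Highlighted variances:")
  if (length(report$highlighted)) {
    high <- c(high, vapply(report$highlighted, .render_line, character(1)))
  } else {
    high <- c(high, "  none")
  }
  paste(c(header, body, high, ""), collapse = "\n")
}

#' Parse a JSON report back into its check results
#'
#' Inverse of the JSON rendering in [render_report()]; used for
#' machine-readable downstream processing.
#'
#' @param json JSON report text.
#' @return A list with `process`, `patient_id`, `timestamp`, `tallies` and
#'   `results` (a list of [check_result()]).
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  x$results <- lapply(x$results, function(r) {
    check_result(r$check_id, r$check_type, r$severity, r$message,
                 involved = lapply(r$involved, function(i)
                   c(i$kind, i$field)),
                 triggered_by = r$triggered_by)
  })
  x
}

#' Save a rendered report to a directory
#'
#' The file is named `<patient_id>_<process>_<timestamp>` so repeated runs
#' never overwrite each other.
#'
#' @param report A [summary_report()].
#' @param out_dir Existing writable directory.
#' @param format `"text"` or `"json"`.
#' @return The written file path.
#' @export
save_report <- function(report, out_dir, format = "text") {
  if (!dir.exists(out_dir))
    stop("output directory does not exist: ", out_dir)
  stamp <- gsub("[:\\-]", "", report$timestamp)
  path <- file.path(out_dir, sprintf("%s_%s_%s.%s", report$patient_id,
                                     report$process, stamp,
                                     if (format == "json") "json" else "txt"))
  writeLines(render_report(report, format), path, useBytes = TRUE)
  path
}

#' Queue a report for email dispatch (integration mode)
#'
#' Transport is deployment-specific: the report and its recipient metadata
#' are written to an outbox directory and no network activity occurs.
#' Dispatch is only meaningful in integration mode; calling it in
#' standalone mode is a contract error.
#'
#' @param report A [summary_report()].
#' @param recipients Character vector of recipient addresses (possibly
#'   empty, in which case nothing is queued).
#' @param outbox_dir Outbox directory (created if needed).
#' @param mode `"integration"` or `"standalone"`.
#' @return A dispatch record: `queued`, `entry` (path or `NA`),
#'   `recipients`.
#' @export
dispatch_report <- function(report, recipients, outbox_dir,
                            mode = "integration") {
  if (!identical(mode, "integration"))
    stop("dispatch_report is integration-only; standalone runs save ",
         "reports to the output directory instead")
  if (length(recipients) == 0) {
    return(list(queued = FALSE, entry = NA_character_,
                recipients = character(0)))
  }
  if (!dir.exists(outbox_dir))
    dir.create(outbox_dir, recursive = TRUE)
  stamp <- gsub("[:\\-]", "", report$timestamp)
  entry <- file.path(outbox_dir, sprintf("%s_%s_%s", report$patient_id,
                                         report$process, stamp))
  dir.create(entry, showWarnings = FALSE)
  writeLines(render_report(report, "text"),
             file.path(entry, "report.txt"), useBytes = TRUE)
  jsonlite::write_json(list(recipients = recipients,
                            patient_id = report$patient_id,
                            process = report$process,
                            timestamp = report$timestamp),
                       file.path(entry, "dispatch.json"),
                       auto_unbox = TRUE)
  list(queued = TRUE, entry = entry, recipients = recipients)
}
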