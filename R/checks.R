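# The three-layer rule engine: data completeness, cross-document
# consistency, allowable value range. Consistency discrepancies escalate to
# a triggered completeness pass over every involved document.

#' Construct one check outcome
#'
#' @param check_id Identifier of the check that produced this result.
#' @param check_type `"completeness"`, `"consistency"` or `"range"`.
#' @param severity `"pass"`, `"warning"`, `"error"` or `"manual_required"`.
#' @param message Human-readable outcome.
#' @param involved List of `c(kind, field)` pairs the check looked at.
#' @param triggered_by For completeness results spawned by a consistency
#'   discrepancy: the consistency check's id. `NULL` otherwise.
#' @return An object of class `check_result`.
#' @export
check_result <- function(check_id, check_type, severity, message,
                         involved = list(), triggered_by = NULL) {
  stopifnot(check_type %in% c("completeness", "consistency", "range"),
            severity %in% c("pass", "warning", "error", "manual_required"))
  structure(list(check_id = check_id, check_type = check_type,
                 severity = severity, message = message,
                 involved = involved, triggered_by = triggered_by),
            class = "check_result")
}

#' @export
print.check_result <- function(x, ...) {
  cat(sprintf("[%s] %s %s: %s\n", x$check_type, toupper(x$severity),
              x$check_id, x$message))
  invisible(x)
}

#' Define a cross-document consistency rule
#'
#' @param rule_id Identifier.
#' @param fields List of `c(kind, field)` pairs (at least two) whose values
#'   must agree.
#' @param comparator `"exact"` (equality after unit/whitespace/case
#'   normalization) or `"numeric_tolerance"` (numeric values within
#'   `tolerance` of each other; all referenced fields must share a unit).
#' @param tolerance Numeric tolerance for `"numeric_tolerance"`; default 0.
#' @param severity_on_mismatch `"warning"` or `"error"`.
#' @return An object of class `consistency_rule`.
#' @export
consistency_rule <- function(rule_id, fields, comparator = "exact",
                             tolerance = 0,
                             severity_on_mismatch = "warning") {
  stopifnot(length(fields) >= 2,
            comparator %in% c("exact", "numeric_tolerance"),
            severity_on_mismatch %in% c("warning", "error"))
  fields <- lapply(fields, function(f) {
    stopifnot(length(f) == 2)
    c(kind = unname(f[1]), field = unname(f[2]))
  })
  structure(list(rule_id = rule_id, fields = fields,
                 comparator = comparator, tolerance = tolerance,
                 severity_on_mismatch = severity_on_mismatch),
            class = "consistency_rule")
}

#' Default cross-document consistency rules
#'
#' The data points recorded in more than one PSI document and compared
#' across them. A mismatch in implanted seed counts across the quality
#' checklist, survey report and end-of-treatment note is treated as an
#' error (a potential issue for post-implant planning); other mismatches
#' default to warnings.
#'
#' @return Named list of [consistency_rule()] objects.
#' @export
default_consistency_rules <- function() {
  pairs <- function(...) {
    args <- list(...)
    lapply(args, function(a) c(a[[1]], a[[2]]))
  }
  rules <- list(
    consistency_rule("patient_id",
      pairs(c("prescription", "patient_id"),
            c("volume_report", "patient_id"),
            c("quality_checklist", "patient_id"),
            c("survey_report", "patient_id"),
            c("end_of_treatment", "patient_id"))),
    consistency_rule("prostate_volume",
      pairs(c("prescription", "prostate_volume"),
            c("volume_report", "prostate_volume"))),
    consistency_rule("imaging_modality",
      pairs(c("prescription", "imaging_modality"),
            c("volume_report", "imaging_modality"))),
    consistency_rule("implanted_seed_count",
      pairs(c("quality_checklist", "implanted_seed_count"),
            c("survey_report", "implanted_seed_count"),
            c("end_of_treatment", "implanted_seed_count")),
      severity_on_mismatch = "error"),
    consistency_rule("needle_count",
      pairs(c("quality_checklist", "needle_count"),
            c("end_of_treatment", "needle_count"))),
    consistency_rule("prescribed_dose",
      pairs(c("prescription", "prescribed_dose"),
            c("end_of_treatment", "prescribed_dose"))),
    consistency_rule("treatment_type",
      pairs(c("prescription", "treatment_type"),
            c("end_of_treatment", "treatment_type"))),
    consistency_rule("isotope",
      pairs(c("prescription", "isotope"),
            c("end_of_treatment", "isotope"))),
    consistency_rule("source_activity",
      pairs(c("prescription", "source_activity"),
            c("end_of_treatment", "source_activity")),
      comparator = "numeric_tolerance", tolerance = 0),
    consistency_rule("ebrt_dose",
      pairs(c("prescription", "ebrt_dose"),
            c("end_of_treatment", "ebrt_dose")),
      comparator = "numeric_tolerance", tolerance = 0),
    consistency_rule("procedure_date",
      pairs(c("prescription", "procedure_date"),
            c("quality_checklist", "procedure_date"),
            c("end_of_treatment", "procedure_date"))))
  names(rules) <- vapply(rules, function(r) r$rule_id, character(1))
  rules
}

# ---------------------------------------------------------------------------
# Layer 1: completeness

# one completeness verdict for a single extracted field under its spec
.completeness_one <- function(field, spec, kind, triggered_by = NULL) {
  id <- paste0("completeness:", kind, ":", spec$name)
  involved <- list(c(kind, spec$name))
  if (field$status == "image_skipped") {
    return(check_result(id, "completeness", "manual_required",
                        paste0("'", spec$name, "' in ", kind,
                               " is an embedded image: manual inspection ",
                               "required"),
                        involved, triggered_by))
  }
  if (field$status == "missing") {
    return(check_result(id, "completeness", "error",
                        paste0("missing details in ", spec$name, " (",
                               kind, ")"),
                        involved, triggered_by))
  }
  if (field$status == "unparsable") {
    return(check_result(id, "completeness", "error",
                        paste0("'", spec$name, "' in ", kind,
                               " could not be parsed as ", spec$value_type,
                               ": \"", field$raw_text, "\""),
                        involved, triggered_by))
  }
  if (!is.null(spec$expected_value)) {
    same <- if (is.numeric(spec$expected_value)) {
      is.numeric(field$value) &&
        isTRUE(all.equal(field$value, spec$expected_value))
    } else {
      identical(tolower(trimws(as.character(field$value))),
                tolower(trimws(as.character(spec$expected_value))))
    }
    if (!same) {
      return(check_result(id, "completeness", "error",
                          sprintf("'%s' in %s is \"%s\", expected \"%s\"",
                                  spec$name, kind, field$raw_text,
                                  format(spec$expected_value)),
                          involved, triggered_by))
    }
  }
  check_result(id, "completeness", "pass",
               paste0("'", spec$name, "' present and as expected"),
               involved, triggered_by)
}

#' Data completeness check over one document
#'
#' Verifies that every required, auto-checkable field is filled in, parses
#' under its value type, and equals its expected constant where one is
#' configured (e.g. source activity 0.36 mCi). Picture-backed fields are
#' reported as requiring manual inspection. Returns exactly one result per
#' required non-manual field.
#'
#' @param doc An `extracted_document` from [parse_document()].
#' @param schema Its governing [document_schema()].
#' @param triggered_by Internal: consistency check id when this pass was
#'   escalated from a discrepancy.
#' @return List of [check_result()].
#' @export
run_completeness <- function(doc, schema, triggered_by = NULL) {
  stopifnot(identical(doc$kind, schema$kind))
  specs <- .required_fields(schema)
  lapply(specs, function(spec) {
    .completeness_one(doc$fields[[spec$name]], spec, doc$kind, triggered_by)
  })
}

# ---------------------------------------------------------------------------
# Layer 2: consistency

# comparable scalar for consistency comparison, or NULL
.comparable_value <- function(field) {
  v <- field$value
  if (is.null(v)) return(NULL)
  if (inherits(v, "Date")) return(as.numeric(v))
  if (is.character(v)) return(tolower(trimws(v)))
  v
}

#' Cross-document consistency check
#'
#' Compares the data points named by a rule across the chart's documents.
#' All values equal under the rule's comparator is a pass. On a mismatch a
#' result at the rule's severity is emitted and the escalation rule fires:
#' a completeness pass over every involved document is appended, each
#' result carrying `triggered_by = ` the consistency check's id, so the
#' report explains the discrepancy. Documents absent from the chart, or
#' values that are missing or picture-backed, make the comparison
#' impossible and yield a `manual_required` result.
#'
#' @param chart A [patient_chart()] with parsed documents.
#' @param rule A [consistency_rule()].
#' @param registry Schema registry, needed for escalation.
#' @return List of [check_result()] (one, plus escalations on mismatch).
#' @export
run_consistency <- function(chart, rule, registry = load_schemas()) {
  id <- paste0("consistency:", rule$rule_id)
  involved <- lapply(rule$fields, function(f) unname(f))
  kinds <- vapply(rule$fields, function(f) f[["kind"]], character(1))
  fieldnames <- vapply(rule$fields, function(f) f[["field"]], character(1))

  absent <- setdiff(unique(kinds), names(chart$documents))
  if (length(absent)) {
    return(list(check_result(id, "consistency", "manual_required",
                             paste0("cannot compare '", rule$rule_id,
                                    "': document(s) absent: ",
                                    paste(absent, collapse = ", ")),
                             involved)))
  }
  fields <- mapply(function(k, fn) {
    f <- chart$documents[[k]]$fields[[fn]]
    if (is.null(f))
      stop("consistency rule '", rule$rule_id, "' references unknown ",
           "field '", fn, "' in ", k)
    f
  }, kinds, fieldnames, SIMPLIFY = FALSE)

  statuses <- vapply(fields, function(f) f$status, character(1))
  if (any(statuses == "image_skipped")) {
    return(list(check_result(id, "consistency", "manual_required",
                             paste0("cannot compare '", rule$rule_id,
                                    "': picture-backed field(s) require ",
                                    "manual inspection"), involved)))
  }
  if (any(statuses != "found")) {
    return(list(check_result(id, "consistency", "manual_required",
                             paste0("cannot compare '", rule$rule_id,
                                    "': value(s) missing or unparsable ",
                                    "(see completeness results)"),
                             involved)))
  }

  values <- lapply(fields, .comparable_value)
  numeric_vals <- vapply(values, is.numeric, logical(1))
  if (rule$comparator == "numeric_tolerance" && !all(numeric_vals))
    stop("consistency rule '", rule$rule_id,
         "' uses numeric_tolerance on non-numeric fields")
  if (all(numeric_vals)) {
    units <- unique(vapply(fields, function(f) normalize_unit(f$unit),
                           character(1)))
    units <- units[nzchar(units)]
    if (length(units) > 1)
      stop("consistency rule '", rule$rule_id, "' compares fields with ",
           "mismatched units: ", paste(units, collapse = " vs "))
  }

  agree <- if (rule$comparator == "numeric_tolerance") {
    v <- unlist(values)
    max(v) - min(v) <= rule$tolerance
  } else {
    length(unique(vapply(values, function(v) paste(format(v), collapse = ","),
                         character(1)))) == 1
  }
  if (agree) {
    return(list(check_result(id, "consistency", "pass",
                             paste0("'", rule$rule_id,
                                    "' consistent across ",
                                    paste(unique(kinds), collapse = ", ")),
                             involved)))
  }

  shown <- paste(sprintf("%s=%s", kinds,
                         vapply(fields, function(f) f$raw_text,
                                character(1))), collapse = ", ")
  out <- list(check_result(id, "consistency", rule$severity_on_mismatch,
                           paste0("inconsistent ", rule$rule_id, ": ",
                                  shown), involved))
  # discrepancy triggers a completeness check of each involved document
  for (k in unique(kinds)) {
    out <- c(out, run_completeness(chart$documents[[k]],
                                   schema_for(k, registry),
                                   triggered_by = id))
  }
  out
}

# ---------------------------------------------------------------------------
# Layer 3: allowable value range

#' Allowable value range check for one field
#'
#' Passes when the numeric value lies inside the field's inclusive
#' `allowed_range` or equals one of its `allowed_values`; a violation is an
#' error (or a warning for soft limits). Missing or unparsable values are
#' not judged here — the completeness layer already reports them — and a
#' picture-backed value requires manual inspection.
#'
#' @param doc An `extracted_document`.
#' @param spec A [field_spec()] with `allowed_range` or `allowed_values`.
#' @return A single [check_result()].
#' @export
run_range <- function(doc, spec) {
  id <- paste0("range:", doc$kind, ":", spec$name)
  involved <- list(c(doc$kind, spec$name))
  if (is.null(spec$allowed_range) && is.null(spec$allowed_values))
    stop("field '", spec$name, "' has no allowable range configured")
  field <- doc$fields[[spec$name]]
  if (is.null(field))
    stop("document has no field '", spec$name, "'")
  if (field$status == "image_skipped") {
    return(check_result(id, "range", "manual_required",
                        paste0("'", spec$name, "' in ", doc$kind,
                               " is an embedded image: manual inspection ",
                               "required"), involved))
  }
  if (field$status != "found") {
    return(check_result(id, "range", "pass",
                        paste0("'", spec$name,
                               "' not evaluated (missing/unparsable; see ",
                               "completeness results)"), involved))
  }
  value <- field$value
  if (!is.numeric(value))
    return(check_result(id, "range", "pass",
                        paste0("'", spec$name,
                               "' is not numeric; range not applicable"),
                        involved))
  ok <- if (!is.null(spec$allowed_values)) {
    any(vapply(spec$allowed_values, function(a)
      isTRUE(all.equal(as.numeric(value), a)), logical(1)))
  } else {
    value >= spec$allowed_range[1] && value <= spec$allowed_range[2]
  }
  if (ok) {
    return(check_result(id, "range", "pass",
                        sprintf("'%s' = %s %s within allowable values",
                                spec$name, format(value), field$unit),
                        involved))
  }
  limit_txt <- if (!is.null(spec$allowed_values)) {
    paste0("{", paste(spec$allowed_values, collapse = ", "), "}")
  } else {
    sprintf("[%g, %g]", spec$allowed_range[1], spec$allowed_range[2])
  }
  check_result(id, "range",
               if (spec$soft_limit) "warning" else "error",
               sprintf("'%s' = %s %s outside allowable %s %s",
                       spec$name, format(value), field$unit, limit_txt,
                       field$unit), involved)
}

# ---------------------------------------------------------------------------
# Process definitions

#' Define an ordered chart-check process
#'
#' @param name Process name (`"seed_ordering"`, `"monthly_audit"`,
#'   `"full_chart"`, or a custom name).
#' @param checks Ordered list of check specifications; see
#'   [default_process()].
#' @return An object of class `process_definition`.
#' @export
process_definition <- function(name, checks) {
  structure(list(name = name, checks = checks),
            class = "process_definition")
}

.chk <- function(type, ...) c(list(type = type), list(...))

#' Bundled process definitions
#'
#' `"seed_ordering"` is the pre-implant report run when the physicist
#' orders seeds: 20 automatic checks over the prescription and volume study
#' report (12 completeness, 3 consistency, 4 range, plus the nomogram
#' verification of the manually entered seed number). `"full_chart"` sweeps
#' every required field, every consistency rule and every range-limited
#' field of all five audit-core documents.
#'
#' @param name Process name.
#' @param registry Schema registry (used to expand full-chart sweeps).
#' @param rules Consistency rules, by default
#'   [default_consistency_rules()].
#' @return A [process_definition()].
#' @export
default_process <- function(name, registry = load_schemas(),
                            rules = default_consistency_rules()) {
  if (name == "seed_ordering") {
    comp <- function(kind, field) .chk("completeness", kind = kind,
                                       field = field)
    rng <- function(kind, field) .chk("range", kind = kind, field = field)
    checks <- list(
      comp("prescription", "prescribed_dose"),
      comp("prescription", "treatment_type"),
      comp("prescription", "isotope"),
      comp("prescription", "source_activity"),
      comp("prescription", "prostate_volume"),
      comp("prescription", "seeds_ordered"),
      comp("prescription", "attestation"),
      comp("prescription", "prior_treatment_history"),
      comp("prescription", "prior_dose"),
      comp("volume_report", "prostate_volume"),
      comp("volume_report", "imaging_modality"),
      comp("volume_report", "pubic_arch_interference"),
      .chk("consistency", rule = rules$prostate_volume),
      .chk("consistency", rule = rules$imaging_modality),
      .chk("consistency", rule = consistency_rule("patient_id_seed_order",
        list(c("prescription", "patient_id"),
             c("volume_report", "patient_id")))),
      rng("prescription", "prescribed_dose"),
      rng("prescription", "prostate_volume"),
      rng("volume_report", "prostate_volume"),
      rng("prescription", "seeds_ordered"),
      .chk("nomogram"))
    process_definition("seed_ordering", checks)
  } else if (name == "full_chart") {
    checks <- lapply(audit_core_kinds(), function(k)
      .chk("document_completeness", kind = k))
    checks <- c(checks, lapply(unname(rules), function(r)
      .chk("consistency", rule = r)))
    for (k in audit_core_kinds()) {
      schema <- schema_for(k, registry)
      for (f in schema$fields) {
        if (!is.null(f$allowed_range) || !is.null(f$allowed_values))
          checks[[length(checks) + 1]] <- .chk("range", kind = k,
                                               field = f$name)
      }
    }
    checks[[length(checks) + 1]] <- .chk("nomogram")
    process_definition("full_chart", checks)
  } else {
    stop("no default process named '", name, "'")
  }
}

# the nomogram verification as a range-layer check over the prescription
.run_nomogram_check <- function(chart, nomogram) {
  id <- "range:nomogram:seeds_ordered"
  involved <- list(c("prescription", "seeds_ordered"),
                   c("prescription", "prostate_volume"),
                   c("prescription", "prescribed_dose"))
  doc <- chart$documents[["prescription"]]
  if (is.null(doc)) {
    return(check_result(id, "range", "manual_required",
                        "cannot verify seed order: prescription absent",
                        involved))
  }
  fields <- lapply(c("seeds_ordered", "prostate_volume", "prescribed_dose"),
                   function(nm) doc$fields[[nm]])
  statuses <- vapply(fields, function(f) f$status, character(1))
  if (any(statuses == "image_skipped")) {
    return(check_result(id, "range", "manual_required",
                        "cannot verify seed order: picture-backed input",
                        involved))
  }
  if (any(statuses != "found")) {
    return(check_result(id, "range", "pass",
                        paste0("seed order not verified against nomogram ",
                               "(inputs missing/unparsable; see ",
                               "completeness results)"), involved))
  }
  verdict <- tryCatch(
    classify_order(fields[[1]]$value, fields[[2]]$value, fields[[3]]$value,
                   nomogram),
    psichart_nomogram_domain_error = function(e) e,
    error = function(e) e)
  if (inherits(verdict, "condition")) {
    return(check_result(id, "range", "error",
                        paste0("seed order check: ",
                               conditionMessage(verdict)), involved))
  }
  check_result(id, "range", verdict$severity, verdict$message, involved)
}

#' Run a chart-check process
#'
#' Executes the process's checks in order. Within the defined order the
#' completeness layer comes first, then consistency (whose discrepancies
#' append triggered completeness results), then allowable-range checks and
#' the nomogram verification, so the report reads top-down like the manual
#' checklist. Checks that reference a document absent from the chart
#' produce `manual_required` results; the function itself never fails on
#' chart content.
#'
#' @param chart A [patient_chart()] with parsed documents.
#' @param process A [process_definition()] or a default process name.
#' @param registry Schema registry.
#' @param nomogram A [nomogram_table()].
#' @return Ordered list of [check_result()].
#' @export
run_process <- function(chart, process = "seed_ordering",
                        registry = load_schemas(),
                        nomogram = default_nomogram()) {
  if (is.character(process))
    process <- default_process(process, registry)
  results <- list()
  for (spec in process$checks) {
    if (spec$type == "completeness") {
      doc <- chart$documents[[spec$kind]]
      if (is.null(doc)) {
        results[[length(results) + 1]] <- check_result(
          paste0("completeness:", spec$kind, ":", spec$field),
          "completeness", "manual_required",
          paste0("document absent: ", spec$kind),
          list(c(spec$kind, spec$field)))
      } else {
        schema <- schema_for(spec$kind, registry)
        results[[length(results) + 1]] <- .completeness_one(
          doc$fields[[spec$field]], schema$fields[[spec$field]], spec$kind)
      }
    } else if (spec$type == "document_completeness") {
      doc <- chart$documents[[spec$kind]]
      if (is.null(doc)) {
        results[[length(results) + 1]] <- check_result(
          paste0("completeness:", spec$kind, ":document"),
          "completeness", "manual_required",
          paste0("document absent: ", spec$kind),
          list(c(spec$kind, "*")))
      } else {
        results <- c(results,
                     run_completeness(doc, schema_for(spec$kind, registry)))
      }
    } else if (spec$type == "consistency") {
      results <- c(results, run_consistency(chart, spec$rule, registry))
    } else if (spec$type == "range") {
      doc <- chart$documents[[spec$kind]]
      if (is.null(doc)) {
        results[[length(results) + 1]] <- check_result(
          paste0("range:", spec$kind, ":", spec$field), "range",
          "manual_required", paste0("document absent: ", spec$kind),
          list(c(spec$kind, spec$field)))
      } else {
        schema <- schema_for(spec$kind, registry)
        results[[length(results) + 1]] <- run_range(
          doc, schema$fields[[spec$field]])
      }
    } else if (spec$type == "nomogram") {
      results[[length(results) + 1]] <- .run_nomogram_check(chart, nomogram)
    } else {
      stop("unknown check type in process '", process$name, "': ",
           spec$type)
    }
  }
  unname(results)
}

# worst severity over a result list, for exit codes and tallies
severity_tally <- function(results) {
  sev <- vapply(results, function(r) r$severity, character(1))
  c(pass = sum(sev == "pass"), warning = sum(sev == "warning"),
    error = sum(sev == "error"),
    manual_required = sum(sev == "manual_required"))
}
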