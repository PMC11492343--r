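# Domain types and the schema registry for PSI chart documents.

#' Chart document kinds
#'
#' The document kinds the tool knows about. The first five are the
#' "audit-core" kinds: the prescription, volume study report, quality
#' checklist, radiation survey report and end-of-treatment note that make up
#' a complete prostate seed implant (PSI) chart and carry bundled default
#' schemas. `plan_report` and `seed_order` are recognised kinds that can be
#' given schemas through configuration.
#'
#' @return Character vector of kind names.
#' @export
document_kinds <- function() {
  c("prescription", "volume_report", "quality_checklist", "survey_report",
    "end_of_treatment", "plan_report", "seed_order")
}

#' @rdname document_kinds
#' @export
audit_core_kinds <- function() {
  document_kinds()[1:5]
}

.assert_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 || !kind %in% document_kinds())
    stop("unknown document kind: ", paste(kind, collapse = ", "))
  kind
}

.field_value_types <- c("number", "integer", "text", "date", "enumeration",
                        "checkbox")

#' Define one checkable field of a chart document
#'
#' A field specification names a data point, the label strings under which it
#' appears in the source document, its value type, and the expectations the
#' rule engine enforces: a required flag, an exact expected value, an
#' inclusive numeric range, or a discrete set of permitted values.
#'
#' @param name Field identifier (unique within a schema).
#' @param labels Label strings accepted in the source text; defaults to the
#'   identifier with underscores as spaces, matched case-insensitively.
#' @param value_type One of `"number"`, `"integer"`, `"text"`, `"date"`,
#'   `"enumeration"`, `"checkbox"`.
#' @param unit Expected unit string (e.g. `"Gy"`, `"mCi"`, `"mR/h"`), or `""`.
#' @param required Must the field be filled in? Completeness checking only
#'   covers required fields.
#' @param expected_value Optional constant the value must equal (e.g. source
#'   activity 0.36 mCi). Mutually exclusive with `allowed_range` and
#'   `allowed_values`.
#' @param allowed_range Optional inclusive numeric `c(low, high)` limit.
#' @param allowed_values Optional discrete set of permitted numeric values
#'   (e.g. a prescribed dose of 110 or 145 Gy).
#' @param options Permitted options for `enumeration` fields (dropdown
#'   content).
#' @param manual_only Field lives in an embedded image or a non-digital
#'   record and cannot be auto-checked; it is reported for manual inspection
#'   and excluded from automated checking.
#' @param soft_limit If `TRUE`, a range violation is reported as a warning
#'   rather than an error.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(name, labels = NULL, value_type = "text", unit = "",
                       required = TRUE, expected_value = NULL,
                       allowed_range = NULL, allowed_values = NULL,
                       options = NULL, manual_only = FALSE,
                       soft_limit = FALSE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!value_type %in% .field_value_types)
    stop("invalid value_type for field '", name, "': ", value_type)
  if (is.null(labels)) {
    labels <- gsub("_", " ", name)
    substr(labels, 1, 1) <- toupper(substr(labels, 1, 1))
  }
  n_constraints <- (!is.null(expected_value)) + (!is.null(allowed_range)) +
    (!is.null(allowed_values))
  if (n_constraints > 1)
    stop("field '", name, "': expected_value, allowed_range and ",
         "allowed_values are mutually exclusive")
  if (!is.null(allowed_range)) {
    if (!is.numeric(allowed_range) || length(allowed_range) != 2 ||
        allowed_range[1] > allowed_range[2])
      stop("field '", name, "': allowed_range must be numeric c(low, high)")
  }
  if (value_type == "enumeration" && is.null(options))
    stop("field '", name, "': enumeration fields need options")
  structure(list(name = name, labels = labels, value_type = value_type,
                 unit = unit, required = isTRUE(required),
                 expected_value = expected_value,
                 allowed_range = allowed_range,
                 allowed_values = allowed_values, options = options,
                 manual_only = isTRUE(manual_only),
                 soft_limit = isTRUE(soft_limit)),
            class = "field_spec")
}

#' Assemble a document schema
#'
#' @param kind A document kind (see [document_kinds()]).
#' @param fields Ordered list of [field_spec()] objects; names must be unique.
#' @param version Schema version string; schemas encode institutional
#'   practice and are expected to evolve.
#' @return An object of class `document_schema`.
#' @export
document_schema <- function(kind, fields, version = "1.0") {
  .assert_kind(kind)
  stopifnot(is.list(fields), length(fields) > 0)
  nm <- vapply(fields, function(f) f$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate field name in ", kind, " schema: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(fields) <- nm
  structure(list(kind = kind, fields = fields, version = version),
            class = "document_schema")
}

#' @export
print.document_schema <- function(x, ...) {
  cat(sprintf("<document_schema> %s (v%s): %d fields, %d required\n",
              x$kind, x$version, length(x$fields),
              sum(vapply(x$fields, function(f) f$required, logical(1)))))
  invisible(x)
}

#' A patient's chart: document set plus Care Path status
#'
#' @param patient_id Pseudonymous patient identifier (never PHI).
#' @param documents Named list mapping document kind to an extracted
#'   document (see [parse_document()]); kinds may be absent.
#' @param care_path_status Workflow status string used for batch selection.
#' @return An object of class `patient_chart`.
#' @export
patient_chart <- function(patient_id, documents = list(),
                          care_path_status = "") {
  stopifnot(is.character(patient_id), length(patient_id) == 1)
  if (length(documents)) {
    kinds <- names(documents)
    if (is.null(kinds) || anyDuplicated(kinds))
      stop("chart may hold at most one document per kind")
    for (k in kinds) .assert_kind(k)
  }
  structure(list(patient_id = patient_id, documents = documents,
                 care_path_status = care_path_status),
            class = "patient_chart")
}

# ---------------------------------------------------------------------------
# Default schemas. Field counts per document are fixed institutional
# checklist sizes: prescription 20, volume report 16, quality checklist 34,
# survey report 27, end of treatment 36 (133 data points in total). Fields
# not tied to a named crucial check are institution-placeholder items and are
# expected to be overridden via a schema config file.

.schema_prescription <- function() {
  document_schema("prescription", list(
    field_spec("patient_id", "Patient ID"),
    field_spec("procedure_date", value_type = "date"),
    field_spec("treatment_site", expected_value = "Prostate"),
    field_spec("prescribed_dose", value_type = "number", unit = "Gy",
               allowed_values = c(110, 145)),
    field_spec("treatment_type", value_type = "enumeration",
               options = c("Definitive", "Boost")),
    field_spec("ebrt_dose", labels = "EBRT dose", value_type = "number",
               unit = "Gy", allowed_values = c(0, 45)),
    field_spec("isotope", expected_value = "I-125"),
    field_spec("source_activity", value_type = "number", unit = "mCi",
               expected_value = 0.36),
    field_spec("prostate_volume", value_type = "number", unit = "cm³",
               allowed_range = c(10, 80)),
    field_spec("imaging_modality", value_type = "enumeration",
               options = c("CT", "US", "MRI")),
    field_spec("seeds_ordered", value_type = "integer", unit = "seeds",
               allowed_range = c(20, 160)),
    field_spec("seed_model"),
    field_spec("prostate_stage"),
    field_spec("prior_treatment_history"),
    field_spec("prior_dose", value_type = "number", unit = "Gy"),
    field_spec("attestation"),
    field_spec("physician_name"),
    field_spec("physician_signature_date", value_type = "date"),
    field_spec("allergy_review", value_type = "checkbox"),
    field_spec("consent_confirmed", value_type = "checkbox")
  ))
}

.schema_volume_report <- function() {
  document_schema("volume_report", list(
    field_spec("patient_id", "Patient ID"),
    field_spec("study_date", value_type = "date"),
    field_spec("imaging_modality", value_type = "enumeration",
               options = c("CT", "US", "MRI")),
    field_spec("prostate_volume", value_type = "number", unit = "cm³",
               allowed_range = c(10, 80)),
    field_spec("pubic_arch_interference", value_type = "enumeration",
               options = c("None", "Minor", "Significant")),
    field_spec("prostate_length", value_type = "number", unit = "cm",
               allowed_range = c(2, 7)),
    field_spec("prostate_width", value_type = "number", unit = "cm",
               allowed_range = c(2, 7)),
    field_spec("prostate_height", value_type = "number", unit = "cm",
               allowed_range = c(2, 7)),
    field_spec("slice_thickness", value_type = "number", unit = "mm",
               allowed_range = c(1, 5)),
    field_spec("urethra_visualized", value_type = "checkbox"),
    field_spec("bladder_filling_adequate", value_type = "checkbox"),
    field_spec("template_grid_position"),
    field_spec("anesthesia_clearance", value_type = "checkbox"),
    field_spec("physician_name"),
    field_spec("physician_signature_date", value_type = "date"),
    field_spec("comments", required = FALSE)
  ))
}

.schema_quality_checklist <- function() {
  document_schema("quality_checklist", list(
    field_spec("patient_id", "Patient ID"),
    field_spec("procedure_date", value_type = "date"),
    field_spec("timeout_patient_identity", labels = "Time-out: patient identity",
               value_type = "checkbox"),
    field_spec("timeout_site_verified", labels = "Time-out: site verified",
               value_type = "checkbox"),
    field_spec("timeout_consent_signed", labels = "Time-out: consent signed",
               value_type = "checkbox"),
    field_spec("timeout_allergy_reviewed", labels = "Time-out: allergy reviewed",
               value_type = "checkbox"),
    field_spec("timeout_antibiotics_given", labels = "Time-out: antibiotics given",
               value_type = "checkbox"),
    field_spec("timeout_anesthesia_confirmed",
               labels = "Time-out: anesthesia confirmed",
               value_type = "checkbox"),
    field_spec("needle_count", value_type = "integer",
               allowed_range = c(10, 40)),
    field_spec("implanted_seed_count", value_type = "integer",
               unit = "seeds", allowed_range = c(20, 160)),
    field_spec("seeds_received", value_type = "integer", unit = "seeds",
               allowed_range = c(20, 200)),
    field_spec("seeds_returned", value_type = "integer", unit = "seeds",
               allowed_range = c(0, 80)),
    field_spec("seed_delivery_method", value_type = "enumeration",
               options = c("Loose", "Stranded")),
    field_spec("ultrasound_guidance", value_type = "checkbox"),
    field_spec("cystoscopy_performed", value_type = "checkbox"),
    field_spec("cystoscopy_findings", required = FALSE),
    field_spec("fluoroscopy_used", value_type = "checkbox"),
    field_spec("or_room", labels = "OR room"),
    field_spec("source_activity", value_type = "number", unit = "mCi",
               expected_value = 0.36),
    field_spec("isotope", expected_value = "I-125"),
    field_spec("seed_lot_number"),
    field_spec("calibration_date", value_type = "date"),
    field_spec("post_plan_signature_date", value_type = "date"),
    field_spec("realtime_plan_completed", value_type = "checkbox"),
    field_spec("post_implant_ct_ordered",
               labels = "Post-implant CT ordered", value_type = "checkbox"),
    field_spec("room_survey_completed", value_type = "checkbox"),
    field_spec("waste_survey_completed", value_type = "checkbox"),
    field_spec("seed_count_reconciled", value_type = "checkbox"),
    field_spec("physicist_name"),
    field_spec("physicist_signature_date", value_type = "date"),
    field_spec("second_check_name"),
    field_spec("second_check_signature_date", value_type = "date"),
    field_spec("physician_name"),
    field_spec("comments", required = FALSE)
  ))
}

.schema_survey_report <- function() {
  surface <- function(loc, label) {
    field_spec(paste0("surface_", loc), labels = paste("Surface:", label),
               value_type = "number", unit = "mR/h", allowed_range = c(0, 10))
  }
  one_meter <- function(loc, label) {
    field_spec(paste0("one_meter_", loc), labels = paste("At 1 m:", label),
               value_type = "number", unit = "mR/h", allowed_range = c(0, 1))
  }
  document_schema("survey_report", list(
    field_spec("patient_id", "Patient ID"),
    field_spec("survey_date", value_type = "date"),
    field_spec("survey_meter_model"),
    field_spec("survey_meter_serial"),
    field_spec("survey_meter_cal_due",
               labels = "Survey meter calibration due", value_type = "date"),
    field_spec("background_reading", value_type = "number", unit = "mR/h",
               allowed_range = c(0, 0.1)),
    surface("anterior", "anterior"),
    surface("posterior", "posterior"),
    surface("left_lateral", "left lateral"),
    surface("right_lateral", "right lateral"),
    surface("perineum", "perineum"),
    one_meter("anterior", "anterior"),
    one_meter("posterior", "posterior"),
    one_meter("left_lateral", "left lateral"),
    one_meter("right_lateral", "right lateral"),
    one_meter("perineum", "perineum"),
    field_spec("pecu_reading", labels = "PECU reading",
               value_type = "number", unit = "mR/h", allowed_range = c(0, 2)),
    field_spec("implanted_seed_count", value_type = "integer",
               unit = "seeds", allowed_range = c(20, 160)),
    field_spec("seeds_accounted_for", value_type = "checkbox"),
    field_spec("patient_released", value_type = "checkbox"),
    field_spec("release_instructions_given", value_type = "checkbox"),
    field_spec("wristband_applied", value_type = "checkbox"),
    field_spec("room_cleared", value_type = "checkbox"),
    field_spec("regulatory_limit_met", value_type = "checkbox"),
    field_spec("physicist_name"),
    field_spec("physicist_signature_date", value_type = "date"),
    field_spec("comments", required = FALSE)
  ))
}

.schema_end_of_treatment <- function() {
  document_schema("end_of_treatment", list(
    field_spec("patient_id", "Patient ID"),
    field_spec("procedure_date", value_type = "date"),
    field_spec("treatment_site", expected_value = "Prostate"),
    field_spec("prescribed_dose", value_type = "number", unit = "Gy",
               allowed_values = c(110, 145)),
    field_spec("treatment_type", value_type = "enumeration",
               options = c("Definitive", "Boost")),
    field_spec("ebrt_dose", labels = "EBRT dose", value_type = "number",
               unit = "Gy", allowed_values = c(0, 45)),
    field_spec("isotope", expected_value = "I-125"),
    field_spec("source_activity", value_type = "number", unit = "mCi",
               expected_value = 0.36),
    field_spec("prostate_volume", value_type = "number", unit = "cm³",
               allowed_range = c(10, 80)),
    field_spec("implanted_seed_count", value_type = "integer",
               unit = "seeds", allowed_range = c(20, 160)),
    field_spec("needle_count", value_type = "integer",
               allowed_range = c(10, 40)),
    field_spec("seed_delivery_method", value_type = "enumeration",
               options = c("Loose", "Stranded")),
    field_spec("anesthesia_type", value_type = "enumeration",
               options = c("General", "Spinal", "Local")),
    field_spec("estimated_blood_loss", value_type = "number", unit = "mL",
               allowed_range = c(0, 500)),
    field_spec("procedure_duration", value_type = "number", unit = "min",
               allowed_range = c(15, 240)),
    field_spec("complications", required = FALSE),
    field_spec("cystoscopy_performed", value_type = "checkbox"),
    field_spec("post_implant_imaging", labels = "Post-implant imaging",
               value_type = "enumeration", options = c("CT", "MRI")),
    field_spec("post_plan_scheduled", value_type = "checkbox"),
    field_spec("foley_removed", value_type = "checkbox"),
    field_spec("discharge_condition"),
    field_spec("followup_scheduled", labels = "Follow-up scheduled",
               value_type = "checkbox"),
    field_spec("pathology_reviewed", value_type = "checkbox"),
    field_spec("operative_findings"),
    field_spec("specimen_collected", value_type = "checkbox"),
    field_spec("radiation_safety_instructions", value_type = "checkbox"),
    field_spec("medications_prescribed", required = FALSE),
    field_spec("attestation"),
    field_spec("physician_name"),
    field_spec("physician_signature_date", value_type = "date"),
    field_spec("assistant_name", required = FALSE),
    field_spec("dictated_date", value_type = "date"),
    field_spec("plan_report_uploaded", value_type = "checkbox"),
    field_spec("survey_completed", value_type = "checkbox"),
    field_spec("quality_checklist_completed", value_type = "checkbox"),
    field_spec("comments", required = FALSE)
  ))
}

#' Bundled default document schemas
#'
#' Builds the default schema registry for the five audit-core document
#' kinds. Per-document field counts are fixed checklist sizes (prescription
#' 20, volume report 16, quality checklist 34, survey report 27, end of
#' treatment 36; 133 data points in total).
#'
#' @return Named list mapping document kind to [document_schema()].
#' @export
default_schemas <- function() {
  list(prescription = .schema_prescription(),
       volume_report = .schema_volume_report(),
       quality_checklist = .schema_quality_checklist(),
       survey_report = .schema_survey_report(),
       end_of_treatment = .schema_end_of_treatment())
}

# ---------------------------------------------------------------------------
# Config (YAML) serialization

.field_to_config <- function(f) {
  out <- list(name = f$name, labels = as.list(f$labels),
              value_type = f$value_type)
  if (nzchar(f$unit)) out$unit <- f$unit
  out$required <- f$required
  if (!is.null(f$expected_value)) out$expected_value <- f$expected_value
  if (!is.null(f$allowed_range)) out$allowed_range <- as.list(f$allowed_range)
  if (!is.null(f$allowed_values))
    out$allowed_values <- as.list(f$allowed_values)
  if (!is.null(f$options)) out$options <- as.list(f$options)
  if (f$manual_only) out$manual_only <- TRUE
  if (f$soft_limit) out$soft_limit <- TRUE
  out
}

.field_from_config <- function(x, kind) {
  if (is.null(x$name))
    stop("schema config error in '", kind, "': field entry lacks a name")
  known <- c("name", "labels", "value_type", "unit", "required",
             "expected_value", "allowed_range", "allowed_values", "options",
             "manual_only", "soft_limit")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("schema config error in '", kind, "', field '", x$name,
         "': unknown key ", paste(bad, collapse = ", "))
  field_spec(name = x$name,
             labels = if (is.null(x$labels)) NULL else unlist(x$labels),
             value_type = if (is.null(x$value_type)) "text" else x$value_type,
             unit = if (is.null(x$unit)) "" else x$unit,
             required = if (is.null(x$required)) TRUE else x$required,
             expected_value = x$expected_value,
             allowed_range = if (is.null(x$allowed_range)) NULL else
               as.numeric(unlist(x$allowed_range)),
             allowed_values = if (is.null(x$allowed_values)) NULL else
               as.numeric(unlist(x$allowed_values)),
             options = if (is.null(x$options)) NULL else unlist(x$options),
             manual_only = isTRUE(x$manual_only),
             soft_limit = isTRUE(x$soft_limit))
}

#' Write a schema registry to a YAML config file
#'
#' @param registry Named list of [document_schema()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_schemas()] for the inverse.
#' @export
save_schemas <- function(registry, path) {
  out <- list(schemas = lapply(registry, function(s) {
    list(kind = s$kind, version = s$version,
         fields = lapply(unname(s$fields), .field_to_config))
  }))
  names(out$schemas) <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Load the schema registry
#'
#' With `config_path = NULL` the bundled defaults are returned. A config
#' file replaces the schema of every kind it defines; kinds it does not
#' mention keep their defaults.
#'
#' @param config_path Path to a YAML schema config, or `NULL` for defaults.
#' @return Named list mapping document kind to [document_schema()].
#' @export
load_schemas <- function(config_path = NULL) {
  registry <- default_schemas()
  if (is.null(config_path)) return(registry)
  if (!file.exists(config_path))
    stop("schema config not found: ", config_path)
  cfg <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
    stop("schema config error: cannot parse ", config_path, ": ",
         conditionMessage(e))
  })
  if (is.null(cfg$schemas))
    stop("schema config error: top-level 'schemas' key missing in ",
         config_path)
  for (entry in cfg$schemas) {
    if (is.null(entry$kind))
      stop("schema config error: schema entry lacks a kind")
    fields <- lapply(entry$fields, .field_from_config, kind = entry$kind)
    registry[[entry$kind]] <- document_schema(
      kind = entry$kind, fields = fields,
      version = if (is.null(entry$version)) "1.0" else
        as.character(entry$version))
  }
  registry
}

#' Look up the schema governing a document kind
#'
#' @param kind A document kind.
#' @param registry Schema registry from [load_schemas()].
#' @return A [document_schema()].
#' @export
schema_for <- function(kind, registry = load_schemas()) {
  .assert_kind(kind)
  s <- registry[[kind]]
  if (is.null(s))
    stop("no schema registered for document kind '", kind, "'")
  s
}

# required, auto-checkable fields of a schema (completeness scope)
.required_fields <- function(schema) {
  Filter(function(f) f$required && !f$manual_only, schema$fields)
}
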