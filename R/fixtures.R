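# Synthetic PSI charts: internally consistent document sets generated from
# one parameter block, rendered to DOCX and text-layer PDF from a shared
# intermediate representation, plus controlled defect injection with a
# ground-truth log. This reproduces the validation protocol the rule engine
# is qualified against: clean charts must raise no flag (false positives),
# injected defects must all be flagged (false negatives).

#' Parameters of one synthetic chart
#'
#' @param patient_id Pseudonymous id.
#' @param prostate_volume Prostate volume in cm\\u00b3; must lie in the
#'   nomogram domain.
#' @param dose Prescription dose, 145 Gy (definitive) or 110 Gy (boost
#'   after 45 Gy whole-pelvis EBRT).
#' @param treatment_type `"Definitive"` or `"Boost"`; derived from `dose`
#'   when `NULL` and must pair with it otherwise.
#' @param implanted_seed_count Seeds implanted; defaults to the rounded
#'   nomogram value.
#' @param needle_count Needles used; defaults to roughly one needle per
#'   four seeds.
#' @param survey_readings Named numeric vector overriding individual survey
#'   fields (mR/h): `surface_*`, `one_meter_*`, `pecu_reading`,
#'   `background_reading`.
#' @param procedure_date Implant date.
#' @param rng_seed Integer recorded in the manifest; generation itself is
#'   fully deterministic given the parameters.
#' @param nomogram Nomogram used to derive the seed order.
#' @return An object of class `chart_params`.
#' @export
chart_params <- function(patient_id, prostate_volume = 30, dose = 145,
                         treatment_type = NULL, implanted_seed_count = NULL,
                         needle_count = NULL, survey_readings = NULL,
                         procedure_date = as.Date("2024-03-12"),
                         rng_seed = 1L, nomogram = default_nomogram()) {
  if (!dose %in% c(110, 145))
    stop("invalid params: dose must be 110 or 145 Gy")
  expected_type <- if (dose == 145) "Definitive" else "Boost"
  if (is.null(treatment_type)) treatment_type <- expected_type
  if (!identical(treatment_type, expected_type))
    stop("invalid params: ", dose, " Gy pairs with ", expected_type,
         " treatment")
  lo <- min(nomogram$volumes)
  hi <- max(nomogram$volumes)
  if (prostate_volume < lo || prostate_volume > hi)
    stop("invalid params: prostate volume ", prostate_volume,
         " cm³ outside nomogram domain [", lo, ", ", hi, "]")
  required <- seeds_required(prostate_volume, dose, nomogram)
  if (is.null(implanted_seed_count))
    implanted_seed_count <- as.integer(round(required))
  if (is.null(needle_count))
    needle_count <- max(10L, as.integer(round(implanted_seed_count / 4)))
  defaults <- c(surface_anterior = 3.2, surface_posterior = 2.8,
                surface_left_lateral = 2.4, surface_right_lateral = 2.6,
                surface_perineum = 4.1, one_meter_anterior = 0.18,
                one_meter_posterior = 0.15, one_meter_left_lateral = 0.12,
                one_meter_right_lateral = 0.13, one_meter_perineum = 0.22,
                pecu_reading = 0.8, background_reading = 0.03)
  if (!is.null(survey_readings)) defaults[names(survey_readings)] <-
    survey_readings
  structure(list(patient_id = patient_id,
                 prostate_volume = prostate_volume, dose = dose,
                 treatment_type = treatment_type,
                 implanted_seed_count = as.integer(implanted_seed_count),
                 needle_count = as.integer(needle_count),
                 survey_readings = defaults,
                 procedure_date = as.Date(procedure_date),
                 rng_seed = as.integer(rng_seed)),
            class = "chart_params")
}

#' Draw realistic chart parameters from a seeded generator
#'
#' Prostate volume is uniform on 15 to 75 cm\\u00b3, the dose level is an
#' even draw between 110 and 145 Gy, and survey readings are drawn below
#' their institutional limits so a clean chart raises no flag.
#'
#' @param patient_id Pseudonymous id.
#' @param rng_seed Integer seed.
#' @return A [chart_params()].
#' @export
random_chart_params <- function(patient_id, rng_seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(rng_seed)
  volume <- round(stats::runif(1, 15, 75), 1)
  dose <- sample(c(110, 145), 1)
  readings <- c(
    surface_anterior = round(stats::runif(1, 1, 6), 2),
    surface_posterior = round(stats::runif(1, 1, 6), 2),
    surface_left_lateral = round(stats::runif(1, 1, 6), 2),
    surface_right_lateral = round(stats::runif(1, 1, 6), 2),
    surface_perineum = round(stats::runif(1, 1, 6), 2),
    one_meter_anterior = round(stats::runif(1, 0.05, 0.4), 2),
    one_meter_posterior = round(stats::runif(1, 0.05, 0.4), 2),
    one_meter_left_lateral = round(stats::runif(1, 0.05, 0.4), 2),
    one_meter_right_lateral = round(stats::runif(1, 0.05, 0.4), 2),
    one_meter_perineum = round(stats::runif(1, 0.05, 0.4), 2),
    pecu_reading = round(stats::runif(1, 0.2, 1.2), 2),
    background_reading = round(stats::runif(1, 0.01, 0.06), 2))
  day <- as.Date("2024-01-08") + sample(0:300, 1)
  chart_params(patient_id, prostate_volume = volume, dose = dose,
               survey_readings = readings, procedure_date = day,
               rng_seed = rng_seed)
}

# ---------------------------------------------------------------------------
# Shared intermediate representation: per document, an ordered named
# character vector field name -> value string (formatted as it appears in
# the rendered document).

.fmt_date <- function(d) format(d, "%Y-%m-%d")

.chart_values <- function(params, nomogram = default_nomogram()) {
  p <- params
  seeds_order <- round_order_quantity(
    seeds_required(p$prostate_volume, p$dose, nomogram))
  boost <- p$dose == 110
  vol_txt <- paste0(format(p$prostate_volume), " cm3")
  study_date <- p$procedure_date - 14
  sr <- p$survey_readings
  mrh <- function(x) paste0(format(x), " mR/h")
  dims <- round(c(length = 3.2 + p$prostate_volume / 40,
                  width = 3.6 + p$prostate_volume / 45,
                  height = 2.6 + p$prostate_volume / 50), 1)
  list(
    prescription = c(
      patient_id = p$patient_id,
      procedure_date = .fmt_date(p$procedure_date),
      treatment_site = "Prostate",
      prescribed_dose = paste(p$dose, "Gy"),
      treatment_type = p$treatment_type,
      ebrt_dose = if (boost) "45 Gy" else "0 Gy",
      isotope = "I-125",
      source_activity = "0.36 mCi",
      prostate_volume = vol_txt,
      imaging_modality = "CT",
      seeds_ordered = as.character(seeds_order),
      seed_model = "STM-1251",
      prostate_stage = "T1c",
      prior_treatment_history = if (boost)
        "EBRT 45 Gy to whole pelvis" else "None",
      prior_dose = if (boost) "45 Gy" else "0 Gy",
      attestation = "Reviewed and attested by the prescribing physician",
      physician_name = "Physician A",
      physician_signature_date = .fmt_date(p$procedure_date),
      allergy_review = "Yes",
      consent_confirmed = "Yes"),
    volume_report = c(
      patient_id = p$patient_id,
      study_date = .fmt_date(study_date),
      imaging_modality = "CT",
      prostate_volume = vol_txt,
      pubic_arch_interference = "None",
      prostate_length = paste(format(dims[["length"]]), "cm"),
      prostate_width = paste(format(dims[["width"]]), "cm"),
      prostate_height = paste(format(dims[["height"]]), "cm"),
      slice_thickness = "3 mm",
      urethra_visualized = "Yes",
      bladder_filling_adequate = "Yes",
      template_grid_position = "D2.5",
      anesthesia_clearance = "Yes",
      physician_name = "Physician A",
      physician_signature_date = .fmt_date(study_date),
      comments = "None"),
    quality_checklist = c(
      patient_id = p$patient_id,
      procedure_date = .fmt_date(p$procedure_date),
      timeout_patient_identity = "Yes",
      timeout_site_verified = "Yes",
      timeout_consent_signed = "Yes",
      timeout_allergy_reviewed = "Yes",
      timeout_antibiotics_given = "Yes",
      timeout_anesthesia_confirmed = "Yes",
      needle_count = as.character(p$needle_count),
      implanted_seed_count = as.character(p$implanted_seed_count),
      seeds_received = as.character(seeds_order),
      seeds_returned = as.character(seeds_order - p$implanted_seed_count),
      seed_delivery_method = "Loose",
      ultrasound_guidance = "Yes",
      cystoscopy_performed = "Yes",
      cystoscopy_findings = "No seeds visualized in bladder",
      fluoroscopy_used = "No",
      or_room = "OR 3",
      source_activity = "0.36 mCi",
      isotope = "I-125",
      seed_lot_number = sprintf("LOT-%05d", 10000 + p$rng_seed %% 80000),
      calibration_date = .fmt_date(p$procedure_date - 1),
      post_plan_signature_date = .fmt_date(p$procedure_date + 28),
      realtime_plan_completed = "Yes",
      post_implant_ct_ordered = "Yes",
      room_survey_completed = "Yes",
      waste_survey_completed = "Yes",
      seed_count_reconciled = "Yes",
      physicist_name = "Physicist B",
      physicist_signature_date = .fmt_date(p$procedure_date),
      second_check_name = "Physicist C",
      second_check_signature_date = .fmt_date(p$procedure_date),
      physician_name = "Physician A",
      comments = "None"),
    survey_report = c(
      patient_id = p$patient_id,
      survey_date = .fmt_date(p$procedure_date),
      survey_meter_model = "Ludlum 14C",
      survey_meter_serial = "SN-20451",
      survey_meter_cal_due = .fmt_date(p$procedure_date + 180),
      background_reading = mrh(sr[["background_reading"]]),
      surface_anterior = mrh(sr[["surface_anterior"]]),
      surface_posterior = mrh(sr[["surface_posterior"]]),
      surface_left_lateral = mrh(sr[["surface_left_lateral"]]),
      surface_right_lateral = mrh(sr[["surface_right_lateral"]]),
      surface_perineum = mrh(sr[["surface_perineum"]]),
      one_meter_anterior = mrh(sr[["one_meter_anterior"]]),
      one_meter_posterior = mrh(sr[["one_meter_posterior"]]),
      one_meter_left_lateral = mrh(sr[["one_meter_left_lateral"]]),
      one_meter_right_lateral = mrh(sr[["one_meter_right_lateral"]]),
      one_meter_perineum = mrh(sr[["one_meter_perineum"]]),
      pecu_reading = mrh(sr[["pecu_reading"]]),
      implanted_seed_count = as.character(p$implanted_seed_count),
      seeds_accounted_for = "Yes",
      patient_released = "Yes",
      release_instructions_given = "Yes",
      wristband_applied = "Yes",
      room_cleared = "Yes",
      regulatory_limit_met = "Yes",
      physicist_name = "Physicist B",
      physicist_signature_date = .fmt_date(p$procedure_date),
      comments = "None"),
    end_of_treatment = c(
      patient_id = p$patient_id,
      procedure_date = .fmt_date(p$procedure_date),
      treatment_site = "Prostate",
      prescribed_dose = paste(p$dose, "Gy"),
      treatment_type = p$treatment_type,
      ebrt_dose = if (boost) "45 Gy" else "0 Gy",
      isotope = "I-125",
      source_activity = "0.36 mCi",
      prostate_volume = vol_txt,
      implanted_seed_count = as.character(p$implanted_seed_count),
      needle_count = as.character(p$needle_count),
      seed_delivery_method = "Loose",
      anesthesia_type = "Spinal",
      estimated_blood_loss = "25 mL",
      procedure_duration = "90 min",
      complications = "None",
      cystoscopy_performed = "Yes",
      post_implant_imaging = "CT",
      post_plan_scheduled = "Yes",
      foley_removed = "Yes",
      discharge_condition = "Stable",
      followup_scheduled = "Yes",
      pathology_reviewed = "Yes",
      operative_findings =
        "Uncomplicated loose seed implant under ultrasound guidance",
      specimen_collected = "No",
      radiation_safety_instructions = "Yes",
      medications_prescribed = "Tamsulosin 0.4 mg daily",
      attestation = "Operative note reviewed and attested",
      physician_name = "Physician A",
      physician_signature_date = .fmt_date(p$procedure_date),
      assistant_name = "Resident D",
      dictated_date = .fmt_date(p$procedure_date),
      plan_report_uploaded = "Yes",
      survey_completed = "Yes",
      quality_checklist_completed = "Yes",
      comments = "None"))
}

.doc_titles <- c(prescription = "PSI Prescription",
                 volume_report = "PSI Volume Study Report",
                 quality_checklist = "PSI Quality Checklist",
                 survey_report = "PSI Radiation Survey Report",
                 end_of_treatment = "PSI End of Treatment Note")

# values: named character vector; image_fields: names rendered as pictures.
# The first two fields form a small header table so both table-grid and
# label:value paragraph layouts are exercised.
.doc_blocks <- function(kind, values, schema, image_fields = character(0)) {
  blocks <- list(list(type = "heading", text = .doc_titles[[kind]]))
  nms <- names(values)
  header <- setdiff(nms[seq_len(min(2, length(nms)))], image_fields)
  if (length(header)) {
    blocks[[length(blocks) + 1]] <- list(type = "table", rows = lapply(
      header, function(nm)
        c(schema$fields[[nm]]$labels[1], unname(values[[nm]]))))
  }
  for (nm in setdiff(nms, header)) {
    label <- schema$fields[[nm]]$labels[1]
    if (nm %in% image_fields) {
      blocks[[length(blocks) + 1]] <- list(type = "para",
                                           text = paste0(label, ": "),
                                           image = TRUE)
    } else {
      blocks[[length(blocks) + 1]] <- list(
        type = "para", text = paste0(label, ": ", unname(values[[nm]])))
    }
  }
  blocks
}

.render_chart_files <- function(values_by_kind, image_fields_by_kind,
                                out_dir, formats, registry) {
  files <- character(0)
  for (kind in names(values_by_kind)) {
    schema <- schema_for(kind, registry)
    blocks <- .doc_blocks(kind, values_by_kind[[kind]], schema,
                          image_fields_by_kind[[kind]] %||% character(0))
    for (fmt in formats) {
      path <- file.path(out_dir, paste0(kind, ".", fmt))
      if (fmt == "docx") write_docx(path, blocks) else write_pdf(path, blocks)
      files <- c(files, path)
    }
  }
  files
}

#' Generate one synthetic chart
#'
#' Writes the five audit-core documents, populated mutually consistently
#' from the parameter block (the seed order is the nomogram value rounded
#' up to the 5-seed ordering increment), plus a `manifest.json` recording
#' the parameters. Output bytes are deterministic for fixed parameters.
#'
#' @param params A [chart_params()].
#' @param out_dir Chart directory (created if needed).
#' @param formats Document formats to emit: subset of `c("docx", "pdf")`.
#' @param registry Schema registry.
#' @param nomogram A [nomogram_table()].
#' @return Invisibly, a list with `dir`, `files` and `manifest`.
#' @export
generate_chart <- function(params, out_dir, formats = "docx",
                           registry = load_schemas(),
                           nomogram = default_nomogram()) {
  stopifnot(inherits(params, "chart_params"),
            all(formats %in% c("docx", "pdf")))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  values <- .chart_values(params, nomogram)
  files <- .render_chart_files(values, list(), out_dir, formats, registry)
  manifest <- list(
    patient_id = params$patient_id, care_path_status = "active",
    formats = as.list(formats),
    params = list(prostate_volume = params$prostate_volume,
                  dose = params$dose,
                  treatment_type = params$treatment_type,
                  implanted_seed_count = params$implanted_seed_count,
                  needle_count = params$needle_count,
                  survey_readings = as.list(params$survey_readings),
                  procedure_date = .fmt_date(params$procedure_date),
                  rng_seed = params$rng_seed),
    mutations = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, files = files, manifest = manifest_path))
}

.params_from_manifest <- function(manifest) {
  p <- manifest$params
  chart_params(manifest$patient_id,
               prostate_volume = p$prostate_volume, dose = p$dose,
               treatment_type = p$treatment_type,
               implanted_seed_count = p$implanted_seed_count,
               needle_count = p$needle_count,
               survey_readings = unlist(p$survey_readings),
               procedure_date = as.Date(p$procedure_date),
               rng_seed = p$rng_seed)
}

# which consistency rule (default set) covers a (kind, field) pair, if any
.covering_rule <- function(kind, field,
                           rules = default_consistency_rules()) {
  for (r in rules) {
    for (f in r$fields) {
      if (identical(f[["kind"]], kind) && identical(f[["field"]], field))
        return(r$rule_id)
    }
  }
  NULL
}

# expected check ids that must flag one mutation
.expected_flags <- function(mutation, schema, registry) {
  kind <- mutation$document
  field <- mutation$field
  comp_id <- paste0("completeness:", kind, ":", field)
  spec <- schema$fields[[field]]
  switch(mutation$kind,
    delete = list(ids = comp_id, detectable = spec$required),
    typo = list(ids = comp_id,
                detectable = spec$value_type %in%
                  c("number", "integer", "date")),
    inconsistent_value = {
      rid <- .covering_rule(kind, field)
      list(ids = if (is.null(rid)) character(0) else
        paste0("consistency:", rid), detectable = !is.null(rid))
    },
    out_of_range = list(ids = paste0("range:", kind, ":", field),
                        detectable = !is.null(spec$allowed_range) ||
                          !is.null(spec$allowed_values)),
    image_substitute = list(ids = comp_id, detectable = TRUE,
                            manual = TRUE),
    stop("unknown mutation kind: ", mutation$kind))
}

.apply_mutation <- function(values, images, mutation, schema) {
  kind <- mutation$document
  field <- mutation$field
  if (is.null(values[[kind]]) || !field %in% names(values[[kind]]))
    stop("defect spec error: no field '", field, "' in ", kind)
  mag <- mutation$magnitude %||% 3
  v <- values[[kind]]
  spec <- schema$fields[[field]]
  if (mutation$kind == "delete") {
    values[[kind]] <- v[names(v) != field]
  } else if (mutation$kind == "typo") {
    raw <- v[[field]]
    v[[field]] <- paste0(substr(raw, 1, 1), "x",
                         substr(raw, 2, nchar(raw)))
    values[[kind]] <- v
  } else if (mutation$kind == "inconsistent_value") {
    if (spec$value_type %in% c("number", "integer")) {
      m <- regmatches(v[[field]],
                      regexec("^([-0-9.]+)\\s*(.*)$", v[[field]]))[[1]]
      num <- as.numeric(m[2]) + mag
      v[[field]] <- trimws(paste(format(num), m[3]))
    } else if (spec$value_type == "enumeration") {
      others <- setdiff(spec$options, v[[field]])
      v[[field]] <- others[1]
    } else {
      v[[field]] <- paste(v[[field]], "(amended)")
    }
    values[[kind]] <- v
  } else if (mutation$kind == "out_of_range") {
    if (is.null(spec$allowed_range) && is.null(spec$allowed_values))
      stop("defect spec error: '", field, "' in ", kind,
           " has no allowable range to violate")
    high <- if (!is.null(spec$allowed_range)) spec$allowed_range[2] else
      max(spec$allowed_values)
    num <- high + max(mag, 1)
    unit <- sub("^[-0-9. ]+", "", v[[field]])
    v[[field]] <- trimws(paste(format(num), unit))
    values[[kind]] <- v
  } else if (mutation$kind == "image_substitute") {
    images[[kind]] <- unique(c(images[[kind]], field))
  } else {
    stop("unknown mutation kind: ", mutation$kind)
  }
  list(values = values, images = images)
}

#' Inject controlled defects into a generated chart
#'
#' Re-renders the chart's documents with the requested mutations applied to
#' the shared intermediate representation and writes a ground-truth log
#' pairing each mutation with the check id(s) that must flag it:
#' deletions and numeric typos with the field's completeness check,
#' cross-document value edits with the covering consistency rule, limit
#' violations with the field's range check, and picture substitutions with
#' a manual-inspection requirement. A typo in a free-text field stays a
#' valid string and is logged as undetectable by rule-based checking.
#'
#' @param chart_dir Directory previously written by [generate_chart()].
#' @param defects List of mutations, each a list with `document`, `field`,
#'   `kind` (one of `"delete"`, `"typo"`, `"inconsistent_value"`,
#'   `"out_of_range"`, `"image_substitute"`) and optional `magnitude`.
#' @param registry Schema registry.
#' @param nomogram A [nomogram_table()].
#' @return Invisibly, the ground-truth log (also written to
#'   `ground_truth.json` in the chart directory).
#' @export
inject_defects <- function(chart_dir, defects, registry = load_schemas(),
                           nomogram = default_nomogram()) {
  manifest_path <- file.path(chart_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json in ", chart_dir, "; generate the chart first")
  manifest <- jsonlite::read_json(manifest_path)
  params <- .params_from_manifest(manifest)
  values <- .chart_values(params, nomogram)
  images <- list()
  log <- list()
  for (mut in defects) {
    schema <- schema_for(mut$document, registry)
    applied <- .apply_mutation(values, images, mut, schema)
    values <- applied$values
    images <- applied$images
    exp <- .expected_flags(mut, schema, registry)
    log[[length(log) + 1]] <- list(
      document = mut$document, field = mut$field, kind = mut$kind,
      magnitude = mut$magnitude %||% 3,
      expected_flags = as.list(exp$ids),
      expect_manual = isTRUE(exp$manual),
      detectable = exp$detectable)
  }
  formats <- unlist(manifest$formats)
  .render_chart_files(values, images, chart_dir, formats, registry)
  manifest$mutations <- log
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  gt_path <- file.path(chart_dir, "ground_truth.json")
  jsonlite::write_json(log, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(log)
}

# defect targets eligible per mutation kind under the default schemas
.defect_targets <- function(kind_of_mutation, registry) {
  out <- list()
  for (k in audit_core_kinds()) {
    schema <- schema_for(k, registry)
    for (f in schema$fields) {
      eligible <- switch(kind_of_mutation,
        delete = f$required,
        typo = f$value_type %in% c("number", "integer"),
        inconsistent_value = !is.null(.covering_rule(k, f$name)) &&
          f$value_type %in% c("number", "integer", "enumeration"),
        out_of_range = !is.null(f$allowed_range),
        image_substitute = f$required)
      if (eligible)
        out[[length(out) + 1]] <- c(document = k, field = f$name)
    }
  }
  out
}

#' Build a validation suite of clean and defect-injected charts
#'
#' Generates `n_clean` defect-free charts and `n_defective` charts with one
#' to three randomized mutations each (kinds drawn from delete, numeric
#' typo, inconsistent value, out-of-range and image substitution), writes a
#' suite manifest, and returns an expected-outcome table pairing every
#' chart with the checks that must (and, for clean charts, must not) flag.
#' Charts alternate between DOCX and PDF rendering so both readers are
#' exercised. The same seed reproduces the identical suite.
#'
#' @param n_clean Number of clean charts.
#' @param n_defective Number of defect-injected charts.
#' @param rng_seed Integer seed for all randomization.
#' @param out_dir Suite directory (created if needed).
#' @param registry Schema registry.
#' @param nomogram A [nomogram_table()].
#' @return A list with `charts` (per chart: `patient_id`, `dir`, `clean`,
#'   `defects`) and `patient_list` (path to a batch-mode patient file).
#' @export
build_validation_suite <- function(n_clean, n_defective, rng_seed, out_dir,
                                   registry = load_schemas(),
                                   nomogram = default_nomogram()) {
  stopifnot(n_clean >= 0, n_defective >= 0)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  mutation_kinds <- c("delete", "typo", "inconsistent_value",
                      "out_of_range", "image_substitute")
  targets <- lapply(mutation_kinds, .defect_targets, registry = registry)
  names(targets) <- mutation_kinds

  charts <- list()
  n_total <- n_clean + n_defective
  for (i in seq_len(n_total)) {
    pid <- sprintf("P%03d", i)
    dir_i <- file.path(out_dir, pid)
    seed_i <- (rng_seed %% 1000000L) * 1000L + i
    params <- random_chart_params(pid, seed_i)
    fmt <- if (i %% 2 == 0) "pdf" else "docx"
    generate_chart(params, dir_i, formats = fmt, registry = registry,
                   nomogram = nomogram)
    clean <- i <= n_clean
    defects <- list()
    if (!clean) {
      set.seed(seed_i + 1L)
      n_def <- sample(1:3, 1)
      kinds <- sample(mutation_kinds, n_def, replace = TRUE)
      used <- character(0)
      used_rules <- character(0)  # two value edits on one rule could cancel
      for (mk in kinds) {
        pool <- targets[[mk]]
        keys <- vapply(pool, function(t) paste(t, collapse = ":"),
                       character(1))
        keep <- !keys %in% used
        if (mk %in% c("inconsistent_value", "out_of_range")) {
          rids <- vapply(pool, function(t) {
            r <- .covering_rule(t[["document"]], t[["field"]])
            if (is.null(r)) "" else r
          }, character(1))
          keep <- keep & !(nzchar(rids) & rids %in% used_rules)
        }
        pool <- pool[keep]
        if (!length(pool)) next
        pick <- pool[[sample(length(pool), 1)]]
        used <- c(used, paste(pick, collapse = ":"))
        if (mk %in% c("inconsistent_value", "out_of_range")) {
          rid <- .covering_rule(pick[["document"]], pick[["field"]])
          if (!is.null(rid)) used_rules <- c(used_rules, rid)
        }
        defects[[length(defects) + 1]] <- list(
          document = unname(pick[["document"]]),
          field = unname(pick[["field"]]), kind = mk,
          magnitude = sample(2:8, 1))
      }
      inject_defects(dir_i, defects, registry, nomogram)
    }
    charts[[length(charts) + 1]] <- list(patient_id = pid, dir = dir_i,
                                         clean = clean, defects = defects)
  }
  patient_list <- file.path(out_dir, "patients.tsv")
  lines <- c("patient_id\tcare_path_status\tchart_dir",
             vapply(charts, function(ch) paste(ch$patient_id, "active",
                                               ch$dir, sep = "\t"),
                    character(1)))
  writeLines(lines, patient_list)
  suite <- list(rng_seed = rng_seed, n_clean = n_clean,
                n_defective = n_defective,
                charts = lapply(charts, function(ch)
                  list(patient_id = ch$patient_id, dir = ch$dir,
                       clean = ch$clean, defects = ch$defects)))
  jsonlite::write_json(suite, file.path(out_dir, "suite_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(charts = charts, patient_list = patient_list)
}
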