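# Parsing chart documents into typed field values with provenance.
#
# Anomalies never raise: everything a check might care about is encoded in
# the per-field status (found / missing / unparsable / image_skipped). Only
# file-level corruption is an error.

.unit_synonyms <- c(
  "cc" = "cm³", "cm3" = "cm³", "cm^3" = "cm³",
  "cm³" = "cm³",
  "mci" = "mCi", "gy" = "Gy", "ml" = "mL", "mm" = "mm", "cm" = "cm",
  "mr/h" = "mR/h", "mr/hr" = "mR/h", "mrem/h" = "mR/h",
  "min" = "min", "minutes" = "min", "seeds" = "seeds", "seed" = "seeds")

normalize_unit <- function(unit) {
  if (is.null(unit) || !nzchar(unit)) return("")
  key <- tolower(trimws(unit))
  if (key %in% names(.unit_synonyms)) unname(.unit_synonyms[[key]]) else unit
}

# case-fold and strip punctuation/whitespace for label alias matching
.normalize_label <- function(x) {
  tolower(gsub("[^a-z0-9]", "", tolower(x)))
}

.parse_date <- function(raw) {
  for (fmt in c("%Y-%m-%d", "%m/%d/%Y")) {
    d <- as.Date(raw, format = fmt)
    if (!is.na(d)) {
      # reject two-digit years slipping through %Y
      if (fmt == "%m/%d/%Y" && !grepl("/[0-9]{4}$", raw)) next
      return(d)
    }
  }
  NULL
}

.checkbox_true <- c("yes", "true", "x", "[x]", "checked", "done")
.checkbox_false <- c("no", "false", "", "[ ]", "[]", "unchecked")

#' Parse raw label text into a typed value
#'
#' Applies the field's value type to the text found after a matched label:
#' numbers are read with a unit token normalized over common synonyms
#' (cc/cm3 to cm\\u00b3, mR/hr to mR/h, ...), enumerations must match one of
#' the configured dropdown options, dates are accepted in ISO and US forms,
#' checkboxes map yes/no-style markers to logical.
#'
#' @param raw Text following a matched label.
#' @param spec The governing [field_spec()].
#' @return A list with `value`, `unit` and `status` (one of `"found"`,
#'   `"missing"`, `"unparsable"`).
#' @export
parse_value <- function(raw, spec) {
  raw <- trimws(raw)
  fail <- function(status) list(value = NULL, unit = "", status = status)
  if (!nzchar(raw)) return(fail("missing"))
  vt <- spec$value_type
  if (vt %in% c("number", "integer")) {
    m <- regmatches(raw, regexec(
      "^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$", raw))[[1]]
    if (length(m) == 0) return(fail("unparsable"))
    value <- as.numeric(m[2])
    unit <- normalize_unit(m[3])
    if (nzchar(m[3])) {
      # trailing text must be the expected unit; anything else (a stray
      # letter, a wrong unit) is how numeric typos surface
      if (!nzchar(spec$unit) || !identical(unit, spec$unit))
        return(fail("unparsable"))
    } else {
      unit <- spec$unit
    }
    if (vt == "integer") {
      if (value != round(value)) return(fail("unparsable"))
      value <- as.integer(value)
    }
    list(value = value, unit = unit, status = "found")
  } else if (vt == "date") {
    d <- .parse_date(raw)
    if (is.null(d)) fail("unparsable")
    else list(value = d, unit = "", status = "found")
  } else if (vt == "enumeration") {
    hit <- match(tolower(raw), tolower(spec$options))
    if (is.na(hit)) fail("unparsable")
    else list(value = spec$options[hit], unit = "", status = "found")
  } else if (vt == "checkbox") {
    key <- tolower(raw)
    if (key %in% .checkbox_true)
      list(value = TRUE, unit = "", status = "found")
    else if (key %in% .checkbox_false)
      list(value = FALSE, unit = "", status = "found")
    else fail("unparsable")
  } else {
    list(value = raw, unit = "", status = "found")
  }
}

.extracted_field <- function(name, raw_text = "", value = NULL, unit = "",
                             status = "missing", provenance = NULL) {
  structure(list(name = name, raw_text = raw_text, value = value,
                 unit = unit, status = status, provenance = provenance),
            class = "extracted_field")
}

# Find the block carrying a field's label. Every "key: value" split of a
# block's text is tried so that labels containing colons (e.g.
# "Time-out: consent signed") still match; exact label match is preferred,
# then the punctuation/case-insensitive alias.
.match_label <- function(blocks, labels) {
  norm_labels <- .normalize_label(labels)
  for (exact in c(TRUE, FALSE)) {
    for (i in seq_len(nrow(blocks))) {
      text <- blocks$text[i]
      if (!grepl(":", text, fixed = TRUE)) next
      colons <- gregexpr(":", text, fixed = TRUE)[[1]]
      for (pos in colons) {
        key <- substr(text, 1, pos - 1)
        ok <- if (exact) trimws(key) %in% labels
              else .normalize_label(key) %in% norm_labels
        if (ok) {
          return(list(index = i, raw = trimws(substr(text, pos + 1,
                                                     nchar(text)))))
        }
      }
    }
  }
  NULL
}

#' Parse a chart document into typed fields
#'
#' Reads a DOCX or text-layer PDF document and extracts one field per
#' schema entry. Label matching is case-insensitive over paragraphs, table
#' rows and (for PDF) text lines. Fields whose content region is a picture
#' or screenshot are returned with status `"image_skipped"` and surface
#' downstream as requiring manual inspection; a fully rasterized document
#' (images but no text layer) marks every field `"image_skipped"`.
#'
#' @param path Path to a `.docx` or `.pdf` file.
#' @param kind The document kind the file claims to be.
#' @param schema Governing [document_schema()]; must match `kind`.
#' @return An object of class `extracted_document`: `kind`, `fields` (named
#'   list of extracted fields), `source_format`, `source_path`.
#' @export
parse_document <- function(path, kind, schema) {
  .assert_kind(kind)
  if (!identical(schema$kind, kind))
    stop("schema/kind mismatch: schema is for '", schema$kind,
         "', document claimed as '", kind, "'")
  ext <- tolower(tools::file_ext(path))
  blocks <- switch(ext,
    docx = read_docx(path),
    pdf = read_pdf(path),
    stop("unsupported document format '", ext, "' for ", path))
  source_format <- ext

  rasterized <- nrow(blocks) > 0 && all(!nzchar(blocks$text)) &&
    any(blocks$has_image)
  fields <- vector("list", length(schema$fields))
  names(fields) <- names(schema$fields)
  for (nm in names(schema$fields)) {
    spec <- schema$fields[[nm]]
    if (rasterized) {
      fields[[nm]] <- .extracted_field(nm, status = "image_skipped",
                                       provenance = list(source = path,
                                                         index = NA_integer_))
      next
    }
    hit <- .match_label(blocks, spec$labels)
    if (is.null(hit)) {
      fields[[nm]] <- .extracted_field(nm, provenance = list(source = path,
                                                             index = NA_integer_))
      next
    }
    prov <- list(source = path, index = blocks$index[hit$index])
    raw <- hit$raw
    if (!nzchar(raw)) {
      # empty value region: picture-backed if this or the following block
      # carries an image, otherwise simply missing
      next_img <- hit$index < nrow(blocks) &&
        blocks$has_image[hit$index + 1] && !nzchar(blocks$text[hit$index + 1])
      if (blocks$has_image[hit$index] || next_img) {
        fields[[nm]] <- .extracted_field(nm, status = "image_skipped",
                                         provenance = prov)
      } else {
        fields[[nm]] <- .extracted_field(nm, provenance = prov)
      }
      next
    }
    parsed <- parse_value(raw, spec)
    fields[[nm]] <- .extracted_field(nm, raw_text = raw,
                                     value = parsed$value,
                                     unit = parsed$unit,
                                     status = parsed$status,
                                     provenance = prov)
  }
  structure(list(kind = kind, fields = fields, source_format = source_format,
                 source_path = path),
            class = "extracted_document")
}

#' @export
print.extracted_document <- function(x, ...) {
  st <- vapply(x$fields, function(f) f$status, character(1))
  cat(sprintf("<extracted_document> %s (%s): %d fields (%s)\n",
              x$kind, x$source_format, length(x$fields),
              paste(sprintf("%d %s", as.integer(table(st)),
                            names(table(st))), collapse = ", ")))
  invisible(x)
}
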