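# DOCX reading and writing for the chart-document dialect.
#
# Documents are modelled as an ordered list of blocks:
#   list(type = "heading", text = ...)
#   list(type = "para",    text = "Label: value", image = FALSE)
#   list(type = "table",   rows = list(c("Label", "value"), ...))
# A block with image = TRUE carries its content as an embedded picture
# (no machine-readable text), which downstream extraction must skip.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

.docx_run <- function(text) {
  sprintf('<w:r><w:t xml:space="preserve">%s</w:t></w:r>', .xml_escape(text))
}

# minimal inline-drawing run; extraction only tests for the w:drawing element
.docx_image_run <- function() {
  '<w:r><w:drawing><wp:inline><wp:extent cx="914400" cy="457200"/></wp:inline></w:drawing></w:r>'
}

.docx_block_xml <- function(block) {
  if (block$type == "heading") {
    sprintf('<w:p><w:pPr><w:pStyle w:val="Heading1"/></w:pPr>%s</w:p>',
            .docx_run(block$text))
  } else if (block$type == "para") {
    runs <- .docx_run(block$text)
    if (isTRUE(block$image)) runs <- paste0(runs, .docx_image_run())
    sprintf("<w:p>%s</w:p>", runs)
  } else if (block$type == "table") {
    rows <- vapply(block$rows, function(r) {
      cells <- vapply(r, function(cell) {
        sprintf("<w:tc><w:p>%s</w:p></w:tc>", .docx_run(cell))
      }, character(1))
      sprintf("<w:tr>%s</w:tr>", paste(cells, collapse = ""))
    }, character(1))
    sprintf("<w:tbl>%s</w:tbl>", paste(rows, collapse = ""))
  } else {
    stop("unknown block type: ", block$type)
  }
}

write_docx <- function(path, blocks) {
  body <- paste(vapply(blocks, .docx_block_xml, character(1)), collapse = "")
  document <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<w:document',
    ' xmlns:w="http://schemas.openxmlformats.org/wordprocessingml/2006/main"',
    ' xmlns:wp="http://schemas.openxmlformats.org/drawingml/2006/wordprocessingDrawing">',
    "<w:body>", body, "</w:body></w:document>")
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels"',
    ' ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/word/document.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.wordprocessingml.document.main+xml"/>',
    "</Types>")
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type=',
    '"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument"',
    ' Target="word/document.xml"/>',
    "</Relationships>")
  write_zip_archive(path, list(
    "[Content_Types].xml" = content_types,
    "_rels/.rels" = rels,
    "word/document.xml" = document))
  invisible(path)
}

# Returns a data.frame(index, text, has_image) of text blocks in document
# order. Table rows are flattened to "cell1: cell2: ..." so that a two-column
# label/value grid reads the same as a "Label: value" paragraph.
read_docx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  exdir <- tempfile("docx")
  on.exit(unlink(exdir, recursive = TRUE))
  ok <- tryCatch({
    utils::unzip(path, files = "word/document.xml", exdir = exdir)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  part <- file.path(exdir, "word", "document.xml")
  if (!ok || !file.exists(part)) stop("cannot read DOCX archive: ", path)
  doc <- xml2::read_xml(part)
  ns <- xml2::xml_ns(doc)
  body <- xml2::xml_find_first(doc, ".//w:body", ns)
  texts <- character(0)
  images <- logical(0)
  for (child in xml2::xml_children(body)) {
    nm <- xml2::xml_name(child)
    if (nm == "p") {
      texts <- c(texts, paste(xml2::xml_text(
        xml2::xml_find_all(child, ".//w:t", ns)), collapse = ""))
      images <- c(images, length(xml2::xml_find_all(
        child, ".//w:drawing | .//w:pict", ns)) > 0)
    } else if (nm == "tbl") {
      for (row in xml2::xml_find_all(child, "./w:tr", ns)) {
        cells <- vapply(xml2::xml_find_all(row, "./w:tc", ns), function(tc) {
          paste(xml2::xml_text(xml2::xml_find_all(tc, ".//w:t", ns)),
                collapse = "")
        }, character(1))
        texts <- c(texts, paste(cells, collapse = ": "))
        images <- c(images, length(xml2::xml_find_all(
          row, ".//w:drawing | .//w:pict", ns)) > 0)
      }
    }
  }
  data.frame(index = seq_along(texts), text = texts, has_image = images,
             stringsAsFactors = FALSE)
}
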