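# Text-layer PDF reading and writing for the chart-document dialect.
#
# Writing emits an uncompressed single-font PDF: one BT..ET text object per
# line plus an image XObject paint (/Im1 Do) where a field's content is a
# picture. Reading extracts the text layer only — literal strings shown with
# Tj, in stream order — mirroring the tool's stated no-OCR scope: content
# painted as an image is detected but never interpreted.

.pdf_escape <- function(x) {
  x <- iconv(x, from = "UTF-8", to = "latin1", sub = "?")
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("(", "\\(", x, fixed = TRUE)
  x <- gsub(")", "\\)", x, fixed = TRUE)
  x
}

.pdf_unescape <- function(x) {
  gsub("\\\\([()\\\\])", "\\1", x)
}

# flatten blocks (see docx.R for the block model) to lines
.pdf_lines <- function(blocks) {
  out <- list()
  for (block in blocks) {
    if (block$type == "heading") {
      out[[length(out) + 1]] <- list(text = block$text, image = FALSE)
    } else if (block$type == "para") {
      out[[length(out) + 1]] <- list(text = block$text,
                                     image = isTRUE(block$image))
    } else if (block$type == "table") {
      for (r in block$rows) {
        out[[length(out) + 1]] <- list(text = paste(r, collapse = ": "),
                                       image = FALSE)
      }
    } else {
      stop("unknown block type: ", block$type)
    }
  }
  out
}

write_pdf <- function(path, blocks) {
  lines <- .pdf_lines(blocks)
  # paginate: letter page, 10pt Helvetica, 14pt leading
  pages <- list()
  current <- character(0)
  y <- 760
  for (ln in lines) {
    need <- 14 + if (ln$image) 40 else 0
    if (y - need < 50) {
      pages[[length(pages) + 1]] <- current
      current <- character(0)
      y <- 760
    }
    current <- c(current, sprintf("BT /F1 10 Tf 72 %d Td (%s) Tj ET",
                                  y, .pdf_escape(ln$text)))
    y <- y - 14
    if (ln$image) {
      current <- c(current, sprintf("q 100 0 0 30 72 %d cm /Im1 Do Q", y - 30))
      y <- y - 40
    }
  }
  pages[[length(pages) + 1]] <- current

  n_pages <- length(pages)
  # objects: 1 catalog, 2 pages, 3 font, 4 image, then (page, contents) pairs
  page_obj <- function(i) 4 + 2 * i - 1
  content_obj <- function(i) 4 + 2 * i
  kids <- paste(sprintf("%d 0 R", vapply(seq_len(n_pages), page_obj, 1)),
                collapse = " ")
  objs <- character(4 + 2 * n_pages)
  objs[1] <- "<< /Type /Catalog /Pages 2 0 R >>"
  objs[2] <- sprintf("<< /Type /Pages /Kids [%s] /Count %d >>", kids, n_pages)
  objs[3] <- "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>"
  objs[4] <- paste0("<< /Type /XObject /Subtype /Image /Width 2 /Height 2",
                    " /ColorSpace /DeviceGray /BitsPerComponent 8",
                    " /Length 4 >>\nstream\npppp\nendstream")
  for (i in seq_len(n_pages)) {
    stream <- paste(pages[[i]], collapse = "\n")
    objs[page_obj(i)] <- paste0(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792]",
      " /Resources << /Font << /F1 3 0 R >> /XObject << /Im1 4 0 R >> >>",
      sprintf(" /Contents %d 0 R >>", content_obj(i)))
    objs[content_obj(i)] <- sprintf("<< /Length %d >>\nstream\n%s\nendstream",
                                    nchar(stream, type = "bytes"), stream)
  }

  header <- "%PDF-1.4\n"
  body <- character(length(objs))
  offsets <- numeric(length(objs))
  pos <- nchar(header, type = "bytes")
  for (i in seq_along(objs)) {
    body[i] <- sprintf("%d 0 obj\n%s\nendobj\n", i, objs[i])
    offsets[i] <- pos
    pos <- pos + nchar(body[i], type = "bytes")
  }
  xref <- paste0("xref\n0 ", length(objs) + 1, "\n0000000000 65535 f \n",
                 paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"),
                 "\n")
  trailer <- sprintf(
    "trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
    length(objs) + 1, pos)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, paste(body, collapse = ""), xref, trailer)),
           con)
  invisible(path)
}

# Returns data.frame(index, text, has_image, page). A painted image becomes
# its own block with empty text and has_image = TRUE.
read_pdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "latin1"
  if (!startsWith(txt, "%PDF")) stop("not a PDF file: ", path)
  # locate stream objects together with their dictionaries
  m <- gregexpr("(?s)<<((?:(?!>>).)*)>>\\s*stream\r?\n(.*?)endstream", txt,
                perl = TRUE)[[1]]
  texts <- character(0)
  images <- logical(0)
  pages <- integer(0)
  if (m[1] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    page_no <- 0
    for (i in seq_along(starts)) {
      chunk <- substr(txt, starts[i], starts[i] + lens[i] - 1)
      dict <- sub("(?s)^(<<(?:(?!>>).)*>>).*$", "\\1", chunk, perl = TRUE)
      if (grepl("/Subtype\\s*/Image", dict)) next
      page_no <- page_no + 1
      stream <- sub("(?s)^.*?stream\r?\n(.*?)endstream$", "\\1", chunk,
                    perl = TRUE)
      toks <- gregexpr("\\((?:[^\\\\()]|\\\\.)*\\)\\s*Tj|/Im[0-9]+\\s+Do",
                       stream, perl = TRUE)[[1]]
      if (toks[1] == -1) next
      tlens <- attr(toks, "match.length")
      for (j in seq_along(toks)) {
        tok <- substr(stream, toks[j], toks[j] + tlens[j] - 1)
        if (grepl("Do$", tok)) {
          texts <- c(texts, "")
          images <- c(images, TRUE)
        } else {
          s <- sub("\\)\\s*Tj$", "", sub("^\\(", "", tok))
          texts <- c(texts, enc2utf8(.pdf_unescape(s)))
          images <- c(images, FALSE)
        }
        pages <- c(pages, page_no)
      }
    }
  }
  data.frame(index = seq_along(texts), text = texts, has_image = images,
             page = pages, stringsAsFactors = FALSE)
}
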