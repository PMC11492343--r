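# Minimal ZIP container writer (stored entries only).
#
# DOCX files are ZIP archives of XML parts. Archives are written with
# compression method 0 (stored) and a fixed DOS timestamp so that a chart
# generated twice from the same parameters is byte-identical. Reading goes
# through utils::unzip(), which needs no external binary.

.crc32_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      odd <- c %% 2
      c <- c %/% 2
      if (odd) {
        lo <- bitwXor(as.integer(c %% 65536), 0x8320L)
        hi <- bitwXor(as.integer(c %/% 65536), 0xEDB8L)
        c <- hi * 65536 + lo
      }
    }
    tab[n + 1] <- c
  }
  tab
})

# 32-bit XOR on doubles holding unsigned values
.xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

.crc32 <- function(bytes) {
  crc <- 4294967295
  tab <- .crc32_table
  for (b in as.integer(bytes)) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- .xor32(tab[idx + 1], crc %/% 256)
  }
  4294967295 - crc
}

# little-endian byte encoding of a non-negative value
.le_bytes <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# entries: named list, entry name -> raw vector
write_zip_archive <- function(path, entries) {
  stopifnot(length(entries) > 0, !is.null(names(entries)))
  dos_date <- 44 * 512 + 1 * 32 + 1  # 2024-01-01, fixed for reproducible bytes
  dos_time <- 0
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    if (is.character(data)) data <- charToRaw(enc2utf8(data))
    entries[[i]] <- data
    crcs[i] <- .crc32(data)
    offsets[i] <- pos
    hdr <- c(.le_bytes(0x04034b50, 4), .le_bytes(20, 2), .le_bytes(0, 2),
             .le_bytes(0, 2), .le_bytes(dos_time, 2), .le_bytes(dos_date, 2),
             .le_bytes(crcs[i], 4), .le_bytes(length(data), 4),
             .le_bytes(length(data), 4), .le_bytes(length(nm), 2),
             .le_bytes(0, 2), nm)
    writeBin(hdr, con)
    writeBin(data, con)
    pos <- pos + length(hdr) + length(data)
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    cd <- c(.le_bytes(0x02014b50, 4), .le_bytes(20, 2), .le_bytes(20, 2),
            .le_bytes(0, 2), .le_bytes(0, 2), .le_bytes(dos_time, 2),
            .le_bytes(dos_date, 2), .le_bytes(crcs[i], 4),
            .le_bytes(length(data), 4), .le_bytes(length(data), 4),
            .le_bytes(length(nm), 2), .le_bytes(0, 2), .le_bytes(0, 2),
            .le_bytes(0, 2), .le_bytes(0, 2), .le_bytes(0, 4),
            .le_bytes(offsets[i], 4), nm)
    writeBin(cd, con)
    cd_len <- cd_len + length(cd)
  }
  eocd <- c(.le_bytes(0x06054b50, 4), .le_bytes(0, 2), .le_bytes(0, 2),
            .le_bytes(length(entries), 2), .le_bytes(length(entries), 2),
            .le_bytes(cd_len, 4), .le_bytes(cd_start, 4), .le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
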