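# Minimal ZIP archiver (stored entries, no compression) so tests can build
# ImageJ ROI-set archives without an external zip binary.
.crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

write_test_zip <- function(zipfile, files) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2,
                             endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4,
                             endian = "little")
  entries <- list()
  offset <- 0L
  for (f in files) {
    data <- readBin(f, "raw", file.size(f))
    name <- charToRaw(basename(f))
    crc <- crc32(data)
    entries[[length(entries) + 1L]] <- list(name = name, crc = crc,
                                            size = length(data),
                                            offset = offset)
    w4(0x04034b50); w2(20); w2(0); w2(0); w2(0); w2(0)
    w4(crc); w4(length(data)); w4(length(data))
    w2(length(name)); w2(0)
    writeBin(name, con); writeBin(data, con)
    offset <- offset + 30L + length(name) + length(data)
  }
  cd_start <- offset
  for (e in entries) {
    w4(0x02014b50); w2(20); w2(20); w2(0); w2(0); w2(0); w2(0)
    w4(e$crc); w4(e$size); w4(e$size)
    w2(length(e$name)); w2(0); w2(0); w2(0); w2(0); w4(0)
    w4(e$offset)
    writeBin(e$name, con)
  }
  cd_size <- sum(vapply(entries, function(e) 46L + length(e$name),
                        integer(1)))
  w4(0x06054b50); w2(0); w2(0)
  w2(length(entries)); w2(length(entries))
  w4(cd_size); w4(cd_start)
  w2(0)
  invisible(zipfile)
}
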