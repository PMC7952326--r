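## Minimal deterministic ZIP writer (store method, no compression).
## The exchange container is a plain ZIP archive so that it is a single
## file, diff-able after extraction, and readable by any ZIP tool;
## utils::unzip() (internal method) reads it back and verifies the CRCs.
## Timestamps are fixed so identical studies produce bit-identical
## containers.

int_le <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

DOS_DATE <- bitwOr(bitwOr(bitwShiftL(2021L - 1980L, 9L), bitwShiftL(1L, 5L)), 1L)

## files: named list of raw vectors (name = archive path)
write_zip <- function(files, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  crcs <- numeric(length(files))
  offset <- 0
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    data <- files[[i]]
    fn <- charToRaw(nm)
    crcs[i] <- crc32_raw(data)
    offsets[i] <- offset
    hdr <- c(int_le(0x04034b50, 4), int_le(20, 2), int_le(0, 2), int_le(0, 2),
             int_le(0, 2), int_le(DOS_DATE, 2), int_le(crcs[i], 4),
             int_le(length(data), 4), int_le(length(data), 4),
             int_le(length(fn), 2), int_le(0, 2), fn)
    writeBin(hdr, con)
    writeBin(data, con)
    offset <- offset + length(hdr) + length(data)
  }
  cd_start <- offset
  cd_size <- 0
  for (i in seq_along(files)) {
    fn <- charToRaw(names(files)[i])
    ent <- c(int_le(0x02014b50, 4), int_le(20, 2), int_le(20, 2), int_le(0, 2),
             int_le(0, 2), int_le(0, 2), int_le(DOS_DATE, 2), int_le(crcs[i], 4),
             int_le(length(files[[i]]), 4), int_le(length(files[[i]]), 4),
             int_le(length(fn), 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
             int_le(0, 2), int_le(0, 4), int_le(offsets[i], 4), fn)
    writeBin(ent, con)
    cd_size <- cd_size + length(ent)
  }
  eocd <- c(int_le(0x06054b50, 4), int_le(0, 2), int_le(0, 2),
            int_le(length(files), 2), int_le(length(files), 2),
            int_le(cd_size, 4), int_le(cd_start, 4), int_le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

file_as_raw <- function(path) {
  readBin(path, "raw", n = file.size(path))
}
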