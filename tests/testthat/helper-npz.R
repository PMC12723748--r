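# write a NumPy .npz archive from R, so the npz reader can be exercised
# without binary fixtures: an uncompressed ("stored") zip of .npy members.

crc32raw <- function(bytes) {
  crc <- -1L
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (b in as.integer(bytes)) {
    crc <- bitwXor(crc, b)
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L)
        bitwXor(bitwShiftR(crc, 1L), poly) else bitwShiftR(crc, 1L)
    }
  }
  crc <- bitwXor(crc, -1L)
  x <- if (crc < 0) crc + 2^32 else as.numeric(crc)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

u16raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

npyBytes <- function(m) {
  m <- as.matrix(m)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
                    utf8ToInt("P"), utf8ToInt("Y"), 1, 0)), con)
  writeBin(u16raw(nchar(header)), con)
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  rawConnectionValue(con)
}

writeNpz <- function(arrays, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  entries <- list()
  pos <- 0L
  for (nm in names(arrays)) {
    fname <- paste0(nm, ".npy")
    data <- npyBytes(arrays[[nm]])
    crc <- crc32raw(data)
    local <- c(u32raw(0x04034b50), u16raw(20), u16raw(0), u16raw(0),
               u16raw(0), u16raw(0), crc, u32raw(length(data)),
               u32raw(length(data)), u16raw(nchar(fname)), u16raw(0),
               charToRaw(fname))
    writeBin(local, con)
    writeBin(data, con)
    entries[[nm]] <- list(fname = fname, crc = crc, size = length(data),
                          offset = pos)
    pos <- pos + length(local) + length(data)
  }
  cdStart <- pos
  for (e in entries) {
    cd <- c(u32raw(0x02014b50), u16raw(20), u16raw(20), u16raw(0), u16raw(0),
            u16raw(0), u16raw(0), e$crc, u32raw(e$size), u32raw(e$size),
            u16raw(nchar(e$fname)), u16raw(0), u16raw(0), u16raw(0),
            u16raw(0), u32raw(0), u32raw(e$offset), charToRaw(e$fname))
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  writeBin(c(u32raw(0x06054b50), u16raw(0), u16raw(0),
             u16raw(length(entries)), u16raw(length(entries)),
             u32raw(pos - cdStart), u32raw(cdStart), u16raw(0)), con)
  invisible(path)
}
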