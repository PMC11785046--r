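# Minimal ZIP container writer (method 0, "stored"). Reading goes through R's
# internal unzip; writing is done here because archive round-trips must be
# byte-deterministic, so entries carry a fixed DOS timestamp and appear in
# manifest order.

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  if (length(bytes) > 0) {
    b <- as.integer(bytes)
    for (i in seq_along(b)) {
      crc <- bitwXor(bitwShiftR(crc, 8L),
                     crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
    }
  }
  bitwXor(crc, -1L)
}

u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))

u32 <- function(x) {
  # x may be a signed 32-bit int (CRC) or a non-negative double (sizes)
  if (is.integer(x) && x < 0) x <- x + 4294967296
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# Fixed timestamp 2020-01-01 00:00:00 in DOS date/time encoding.
zip_dos_time <- u16(0L)
zip_dos_date <- u16(bitwOr(bitwOr(bitwShiftL(40L, 9L), bitwShiftL(1L, 5L)), 1L))

# files: named list of raw vectors (names are archive-internal paths).
# Returns the ZIP container as a raw vector.
zip_build <- function(files) {
  stopifnot(is.list(files), !is.null(names(files)))
  locals <- list()
  centrals <- list()
  offset <- 0
  for (i in seq_along(files)) {
    name <- names(files)[i]
    data <- files[[i]]
    stopifnot(is.raw(data))
    nameb <- charToRaw(name)
    crc <- crc32(data)
    local <- c(u32(0x04034b50), u16(20L), u16(0L), u16(0L),
               zip_dos_time, zip_dos_date, u32(crc),
               u32(length(data)), u32(length(data)),
               u16(length(nameb)), u16(0L), nameb, data)
    central <- c(u32(0x02014b50), u16(20L), u16(20L), u16(0L), u16(0L),
                 zip_dos_time, zip_dos_date, u32(crc),
                 u32(length(data)), u32(length(data)),
                 u16(length(nameb)), u16(0L), u16(0L), u16(0L), u16(0L),
                 u32(0L), u32(offset), nameb)
    locals[[i]] <- local
    centrals[[i]] <- central
    offset <- offset + length(local)
  }
  cd <- do.call(c, centrals) %||% raw(0)
  n <- length(files)
  eocd <- c(u32(0x06054b50), u16(0L), u16(0L), u16(n), u16(n),
            u32(length(cd)), u32(offset), u16(0L))
  c(do.call(c, locals) %||% raw(0), cd, eocd)
}

# Extract a ZIP given as raw bytes into a named list of raw vectors.
# Directories are skipped. Errors with "corrupt-archive" if unreadable.
zip_extract <- function(archive_bytes) {
  stopifnot(is.raw(archive_bytes))
  tmp <- tempfile(fileext = ".zip")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(archive_bytes, tmp)
  listing <- tryCatch(
    withCallingHandlers(
      utils::unzip(tmp, list = TRUE),
      warning = function(w) vk_stop("corrupt-archive", conditionMessage(w))
    ),
    error = function(e) {
      if (inherits(e, "verikit_error")) stop(e)
      vk_stop("corrupt-archive", conditionMessage(e))
    }
  )
  names_in <- listing$Name[!endsWith(listing$Name, "/")]
  exdir <- tempfile("zipx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(tmp, exdir = exdir)
  out <- lapply(names_in, function(nm) {
    p <- file.path(exdir, nm)
    readBin(p, "raw", n = file.info(p)$size)
  })
  names(out) <- names_in
  out
}
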