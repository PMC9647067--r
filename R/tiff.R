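# Minimal baseline TIFF reader/writer (uncompressed, single-sample grayscale,
# 8/16/32-bit unsigned, multi-page). The runtime has no TIFF package, so the
# container is handled here; scope is the plane-sequential confocal export
# regime this package consumes, not general TIFF.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

# ---- writer ----------------------------------------------------------------

u16le <- function(v) writeBin(as.integer(ifelse(v > 32767L, v - 65536L, v)),
                              raw(), size = 2L, endian = "little")
u32le <- function(v) {
  v <- as.numeric(v)
  writeBin(as.integer(ifelse(v > 2147483647, v - 4294967296, v)),
           raw(), size = 4L, endian = "little")
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16le(tag), u16le(type), u32le(count), value_raw4)
}

pad4 <- function(r) c(r, raw(4L - length(r)))

# pages: list of integer matrices [y, x]; bits in {8, 16, 32}.
write_tiff <- function(pages, path, bits = 16L, description = NULL) {
  stopifnot(length(pages) >= 1L)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L)) stop("unsupported bits per sample")
  bytes <- bits %/% 8L
  dims <- lapply(pages, dim)
  sizes <- vapply(dims, function(d) prod(d) * bytes, 0)

  desc <- NULL
  if (!is.null(description)) {
    desc <- c(charToRaw(description), as.raw(0L))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  }

  data_off <- 8
  strip_off <- data_off + cumsum(c(0, sizes[-length(sizes)]))
  desc_off <- data_off + sum(sizes)
  ifd0_off <- desc_off + length(desc)
  n_entries <- 10L + as.integer(!is.null(desc))  # description on page 1 only
  ifd_sizes <- c(2L + 12L * n_entries + 4L,
                 rep(2L + 12L * 10L + 4L, length(pages) - 1L))
  ifd_off <- ifd0_off + cumsum(c(0L, ifd_sizes[-length(ifd_sizes)]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L), u32le(ifd0_off)), con)

  for (p in seq_along(pages)) {
    m <- pages[[p]]
    v <- as.vector(t(m))                       # row-major, x fastest
    if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else if (bits == 16L) {
      writeBin(as.integer(ifelse(v > 32767, v - 65536, v)), con,
               size = 2L, endian = "little")
    } else {
      writeBin(as.integer(ifelse(v > 2147483647, v - 4294967296, v)), con,
               size = 4L, endian = "little")
    }
  }
  if (!is.null(desc)) writeBin(desc, con)

  for (p in seq_along(pages)) {
    d <- dims[[p]]
    ent <- list(
      tiff_entry(256L, 4L, 1L, u32le(d[2])),             # ImageWidth = nx
      tiff_entry(257L, 4L, 1L, u32le(d[1])),             # ImageLength = ny
      tiff_entry(258L, 3L, 1L, pad4(u16le(bits))),
      tiff_entry(259L, 3L, 1L, pad4(u16le(1L))),         # no compression
      tiff_entry(262L, 3L, 1L, pad4(u16le(1L))))         # BlackIsZero
    if (p == 1L && !is.null(desc))
      ent <- c(ent, list(tiff_entry(270L, 2L, length(desc), u32le(desc_off))))
    ent <- c(ent, list(
      tiff_entry(273L, 4L, 1L, u32le(strip_off[p])),
      tiff_entry(277L, 3L, 1L, pad4(u16le(1L))),
      tiff_entry(278L, 4L, 1L, u32le(d[1])),
      tiff_entry(279L, 4L, 1L, u32le(sizes[p])),
      tiff_entry(339L, 3L, 1L, pad4(u16le(1L)))))        # unsigned int
    nxt <- if (p < length(pages)) ifd_off[p + 1L] else 0
    writeBin(c(u16le(length(ent)), do.call(c, ent), u32le(nxt)), con)
  }
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

rd_int <- function(raw, off, size, endian, signed = FALSE, n = 1L) {
  # readBin only honors `signed` for 1- and 2-byte integers
  readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
          endian = endian, signed = if (size <= 2L) signed else TRUE)
}

read_ifd_entries <- function(raw, off, endian) {
  n <- rd_int(raw, off, 2L, endian)
  entries <- list()
  for (i in seq_len(n)) {
    e <- off + 2L + (i - 1L) * 12L
    tag <- rd_int(raw, e, 2L, endian)
    type <- rd_int(raw, e + 2L, 2L, endian)
    count <- rd_int(raw, e + 4L, 4L, endian)
    type_size <- c(1L, 1L, 2L, 4L)[type]
    if (is.na(type_size)) next                     # skip exotic types
    total <- type_size * count
    voff <- if (total <= 4L) e + 8L else rd_int(raw, e + 8L, 4L, endian)
    vals <- if (type == 2L) {
      b <- raw[(voff + 1L):(voff + count)]
      z <- which(b == as.raw(0L))
      if (length(z)) b <- b[seq_len(z[1] - 1L)]
      rawToChar(b)
    } else {
      rd_int(raw, voff, type_size, endian, signed = FALSE, n = count)
    }
    entries[[as.character(tag)]] <- vals
  }
  nxt <- rd_int(raw, off + 2L + n * 12L, 4L, endian)
  list(entries = entries, next_ifd = nxt)
}

# Returns list(pages = list of [y, x] integer matrices, description, bits)
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  bom <- rawToChar(raw[1:2])
  endian <- switch(bom, II = "little", MM = "big",
                   stop(sprintf("'%s' is not a TIFF file", path)))
  if (rd_int(raw, 2L, 2L, endian) != 42L)
    stop(sprintf("'%s' is not a TIFF file", path))
  off <- rd_int(raw, 4L, 4L, endian)
  pages <- list()
  description <- NULL
  bits_all <- integer()
  while (off != 0L) {
    ifd <- read_ifd_entries(raw, off, endian)
    e <- ifd$entries
    g <- function(tag, default = NULL) e[[as.character(TIFF_TAGS[[tag]])]] %||% default
    nx <- g("ImageWidth"); ny <- g("ImageLength")
    if (is.null(nx) || is.null(ny)) stop("TIFF page lacks dimensions")
    comp <- g("Compression", 1L)
    if (comp != 1L) stop("compressed TIFF is not supported")
    bits <- g("BitsPerSample", 1L)[1]
    if (!bits %in% c(8L, 16L, 32L))
      stop(sprintf("unsupported sample size: %d bits", bits))
    spp <- g("SamplesPerPixel", 1L)
    if (spp != 1L) stop("only single-sample (grayscale) TIFF is supported")
    fmt <- g("SampleFormat", 1L)[1]
    if (fmt != 1L) stop("unsupported sample type (only unsigned integers)")
    offs <- g("StripOffsets"); cnts <- g("StripByteCounts")
    if (is.null(offs)) stop("TIFF page lacks strip offsets")
    if (is.null(cnts)) cnts <- rep(prod(nx, ny) * bits %/% 8L, length(offs))
    bytes <- bits %/% 8L
    vals <- unlist(lapply(seq_along(offs), function(i) {
      n <- cnts[i] %/% bytes
      if (bytes == 4L) {
        v <- rd_int(raw, offs[i], 4L, endian, signed = TRUE, n = n)
        if (any(v < 0)) stop("32-bit sample overflows R integer range")
        v
      } else {
        rd_int(raw, offs[i], bytes, endian, signed = FALSE, n = n)
      }
    }))
    if (length(vals) != nx * ny)
      stop(sprintf("TIFF strip data (%d px) does not match %d x %d page",
                   length(vals), nx, ny))
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ny, ncol = nx,
                                          byrow = TRUE)
    if (is.null(description)) description <- g("ImageDescription")
    bits_all <- c(bits_all, bits)
    off <- ifd$next_ifd
  }
  list(pages = pages, description = description, bits = bits_all)
}

# ---- metadata block --------------------------------------------------------

stack_description <- function(stack) {
  paste0("qdmi\n",
         "channels=", paste(stack$channel_names, collapse = ","), "\n",
         "voxel_size_nm=", paste(stack$voxel_size_nm, collapse = ","), "\n",
         "bit_depth=", stack$bit_depth, "\n")
}

parse_description <- function(desc) {
  if (is.null(desc) || !startsWith(desc, "qdmi")) return(NULL)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- lines[grepl("=", lines, fixed = TRUE)]
  parts <- strsplit(kv, "=", fixed = TRUE)
  out <- setNames(lapply(parts, `[[`, 2L), vapply(parts, `[[`, "", 1L))
  meta <- list()
  if (!is.null(out$channels))
    meta$channels <- strsplit(out$channels, ",", fixed = TRUE)[[1]]
  if (!is.null(out$voxel_size_nm))
    meta$voxel_size_nm <- as.numeric(strsplit(out$voxel_size_nm, ",")[[1]])
  if (!is.null(out$bit_depth)) meta$bit_depth <- as.integer(out$bit_depth)
  meta
}
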