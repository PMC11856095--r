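## Minimal baseline TIFF codec (pure R).
##
## Scope: what this package needs for CT slices and masks — uncompressed
## (Compression = 1) grayscale 8/16-bit and 8-bit RGB(A) on read (RGB is
## averaged to grayscale by the caller); writes single-strip little-endian
## 8- or 16-bit grayscale. Planar configuration must be chunky. No external
## TIFF library exists in this R installation, hence the hand-rolled codec;
## it is cross-checked against an independent reader in the test suite.

## size-4 reads stay signed (readBin cannot do unsigned 32-bit); offsets in
## files under 2 GB fit in a signed int.
read_uint <- function(con, n, size, endian) {
  v <- readBin(con, "integer", n = n, size = size, signed = size >= 4L,
               endian = endian)
  if (length(v) < n) stop_format("truncated TIFF file")
  v
}

## TIFF field types we understand: 1=BYTE 3=SHORT 4=LONG
tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

read_tiff_entry <- function(raw_entry, endian) {
  int_at <- function(off, size, n) {
    con <- rawConnection(raw_entry[(off + 1):(off + size * n)])
    on.exit(close(con))
    readBin(con, "integer", n = n, size = size, signed = size >= 4L,
            endian = endian)
  }
  tag <- int_at(0, 2, 1)
  type <- int_at(2, 2, 1)
  count <- int_at(4, 4, 1)
  size <- tiff_type_size[as.character(type)]
  list(tag = tag, type = type, count = count, size = size,
       value_raw = raw_entry[9:12])
}

tiff_entry_values <- function(entry, path, endian) {
  if (is.na(entry$size)) return(NULL)  # unsupported field type: ignore
  nbytes <- entry$size * entry$count
  if (nbytes <= 4) {
    con <- rawConnection(entry$value_raw[1:max(1L, nbytes)])
    on.exit(close(con))
    readBin(con, "integer", n = entry$count, size = entry$size,
            signed = entry$size >= 4L, endian = endian)
  } else {
    con0 <- rawConnection(entry$value_raw)
    offset <- readBin(con0, "integer", n = 1, size = 4, signed = TRUE, endian = endian)
    close(con0)
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, offset)
    read_uint(con, entry$count, entry$size, endian)
  }
}

#' Read a TIFF image as a matrix of stored integer intensities
#'
#' Supports baseline uncompressed TIFF: 8- or 16-bit grayscale (one sample
#' per pixel) and 8-bit RGB/RGBA. Multi-sample images are returned as an
#' H x W x S array; grayscale as an H x W matrix.
#'
#' @param path path to a `.tif`/`.tiff` file.
#' @return integer matrix (grayscale) or 3-d array (multi-sample), with the
#'   stored integer values (0..255 or 0..65535) and attribute `bits`.
#' @keywords internal
#' @noRd
read_tiff_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4) stop_format("not a TIFF file (truncated header): ", path)
  endian <- if (identical(magic[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else stop_format("not a TIFF file (bad byte-order mark): ", path)
  ifd_offset <- read_uint(con, 1, 4, endian)
  seek(con, ifd_offset)
  n_entries <- read_uint(con, 1, 2, endian)
  entries_raw <- readBin(con, "raw", n = 12L * n_entries)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- read_tiff_entry(entries_raw[(12L * (i - 1L) + 1L):(12L * i)], endian)
    tags[[as.character(e$tag)]] <- e
  }
  get_tag <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(default)
    tiff_entry_values(e, path, endian)
  }

  width <- get_tag(256)
  height <- get_tag(257)
  if (is.null(width) || is.null(height)) stop_format("TIFF missing dimensions: ", path)
  bits <- get_tag(258, 8L)
  compression <- get_tag(259, 1L)
  if (compression != 1L) {
    stop_format("unsupported TIFF compression (", compression, "); only uncompressed baseline TIFF is readable: ", path)
  }
  spp <- get_tag(277, 1L)
  if (length(unique(bits)) != 1L) stop_format("heterogeneous BitsPerSample unsupported: ", path)
  bits <- bits[1]
  if (!bits %in% c(8L, 16L)) stop_format("unsupported TIFF bit depth ", bits, ": ", path)
  if (spp > 1L && bits != 8L) stop_format("multi-sample TIFF must be 8-bit: ", path)
  planar <- get_tag(284, 1L)
  if (planar != 1L) stop_format("unsupported TIFF planar configuration: ", path)

  strip_offsets <- get_tag(273)
  strip_counts <- get_tag(279)
  rows_per_strip <- get_tag(278, height)
  if (is.null(strip_offsets)) stop_format("TIFF missing strip offsets: ", path)
  if (is.null(strip_counts)) {
    strip_counts <- rep(rows_per_strip * width * spp * (bits / 8L), length(strip_offsets))
  }

  sample_size <- bits / 8L
  values <- integer(0)
  for (i in seq_along(strip_offsets)) {
    seek(con, strip_offsets[i])
    n_samples <- strip_counts[i] / sample_size
    values <- c(values, read_uint(con, n_samples, sample_size, endian))
  }
  n_expected <- height * width * spp
  if (length(values) < n_expected) stop_format("TIFF pixel data truncated: ", path)
  values <- values[seq_len(n_expected)]

  ## TIFF stores row-major (rows of pixels, samples interleaved).
  if (spp == 1L) {
    out <- matrix(values, nrow = height, ncol = width, byrow = TRUE)
  } else {
    arr <- aperm(array(values, dim = c(spp, width, height)), c(3, 2, 1))
    out <- arr
  }
  attr(out, "bits") <- bits
  out
}

#' Write an integer matrix as single-strip uncompressed grayscale TIFF
#'
#' @param pixels integer matrix of stored intensities.
#' @param path output path.
#' @param bits 8 or 16.
#' @keywords internal
#' @noRd
write_tiff_raw <- function(pixels, path, bits = 8L) {
  if (!bits %in% c(8L, 16L)) stop_validation("bits must be 8 or 16")
  h <- nrow(pixels)
  w <- ncol(pixels)
  maxv <- 2^bits - 1
  v <- as.integer(round(pixels))
  if (any(v < 0 | v > maxv)) stop_validation("pixel values out of range for ", bits, "-bit TIFF")
  sample_size <- bits / 8L
  data_bytes <- h * w * sample_size

  con <- tryCatch(file(path, "wb"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) stop_io("cannot open for writing: ", path)
  on.exit(close(con))

  header_len <- 8L
  data_offset <- header_len
  ifd_offset <- data_offset + data_bytes
  ## pad IFD to even offset (TIFF requires word alignment)
  pad <- ifd_offset %% 2L
  ifd_offset <- ifd_offset + pad

  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)                      # "II", 42
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")

  ## pixel data, row-major
  row_major <- as.integer(t(matrix(v, nrow = h, ncol = w)))
  writeBin(row_major, con, size = sample_size, endian = "little")
  if (pad) writeBin(as.raw(0), con)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  n_entries <- 8L
  writeBin(n_entries, con, size = 2, endian = "little")
  entry(256, 4, 1, w)              # ImageWidth
  entry(257, 4, 1, h)              # ImageLength
  entry(258, 3, 1, bits)           # BitsPerSample
  entry(259, 3, 1, 1)              # Compression: none
  entry(262, 3, 1, 1)              # Photometric: BlackIsZero
  entry(273, 4, 1, data_offset)    # StripOffsets
  entry(278, 4, 1, h)              # RowsPerStrip
  entry(279, 4, 1, data_bytes)     # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")  # next IFD: none
  invisible(NULL)
}
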