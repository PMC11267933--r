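#' Read a grayscale image from DICOM, PNG or TIFF
#'
#' Pixel values are returned as stored in the file; for DICOM the rescale
#' slope/intercept are applied when present, so intensities are in the
#' modality's output units.  Accidental RGB input is converted to grayscale
#' with the unweighted channel mean and a warning.  Only single-frame,
#' single-channel (or RGB-convertible) images are supported.
#'
#' @param path Path of the file to read.
#' @param format One of `"auto"`, `"dicom"`, `"png"`, `"tiff"`; `"auto"`
#'   guesses from the file extension.
#' @return A [gray_image] with `bit_depth` taken from the file metadata.
#' @export
read_image <- function(path, format = c("auto", "dicom", "png", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcm = , dicom = "dicom",
                     png = "png",
                     tif = , tiff = "tiff",
                     stop(sprintf("cannot guess format of '%s'; pass `format`",
                                  path), call. = FALSE))
  }
  switch(format,
         dicom = read_dicom_gray(path),
         png   = read_png_gray(path),
         tiff  = read_tiff_gray(path))
}

#' Write a grayscale image as PNG or TIFF
#'
#' PNG supports bit depths 8 and 16; TIFF supports 8, 16 (unsigned integer
#' storage, bit-exact round-trip for integer images) and 32 (IEEE float32
#' storage of `pixels / (2^32 - 1)`, round-trip to float precision).  Writing
#' DICOM is not supported.
#'
#' @param img A [gray_image]; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param path Output path.
#' @param format One of `"auto"`, `"png"`, `"tiff"`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, format = c("auto", "png", "tiff")) {
  img <- as_gray_image(img)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     png = "png", tif = , tiff = "tiff",
                     dcm = , dicom =
                       stop("writing DICOM is not supported", call. = FALSE),
                     stop(sprintf("cannot guess format of '%s'; pass `format`",
                                  path), call. = FALSE))
  }
  bd <- img$bit_depth
  if (format == "png" && !bd %in% c(8L, 16L))
    stop(sprintf("PNG supports bit depths 8 and 16, not %d", bd),
         call. = FALSE)
  top <- 2^bd - 1
  px <- img$pixels
  if (min(px) < 0 || max(px) > top)
    stop(sprintf("intensities outside [0, %d]; quantize() or rescale first",
                 top), call. = FALSE)
  if (format == "png") {
    if (bd == 8L) png::writePNG(px / 255, path)
    else write_png_gray16(round(px), path)
  } else {
    tiff::writeTIFF(px / top, path, bits.per.sample = as.integer(bd),
                    compression = "none", reduce = FALSE)
  }
  invisible(path)
}

read_png_gray <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  bd <- as.integer(info$bit.depth)
  top <- 2^bd - 1
  px <- collapse_channels(arr, "PNG")
  gray_image(strip_attrs(round(px * top)), bit_depth = bd)
}

read_tiff_gray <- function(path) {
  arr <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
  info <- attributes(arr)
  bd <- as.integer(info$bits.per.sample %||% 8L)
  px <- collapse_channels(arr, "TIFF")
  if (bd == 32L) {
    # float storage normalized by 2^32 - 1 (see write_image)
    arr2 <- tiff::readTIFF(path)
    px <- collapse_channels(arr2, "TIFF") * (2^32 - 1)
  }
  gray_image(strip_attrs(px), bit_depth = bd)
}

# Average an H x W x C array down to one channel (unweighted mean), warning
# once; pass matrices through.
collapse_channels <- function(arr, what) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc > 1L)
      warning(sprintf("%s input has %d channels; converted to grayscale by unweighted channel mean",
                      what, nc), call. = FALSE)
    arr <- apply(arr, c(1, 2), mean)
  }
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop readPNG/readTIFF metadata attributes, keeping only dim
strip_attrs <- function(px) {
  matrix(as.numeric(px), nrow(px), ncol(px))
}

## ---- minimal 16-bit grayscale PNG writer -------------------------------
## png::writePNG only emits 8-bit grayscale, so the 16-bit path assembles the
## PNG container directly: IHDR/IDAT/IEND chunks, scanlines filter type 0,
## big-endian samples, zlib stream recovered from memCompress's gzip output.

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
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L),
                 crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

uint32_be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

int32_be <- function(x) {  # signed 32-bit pattern -> big-endian raw
  uint32_be(ifelse(x < 0, x + 2^32, x))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, int32_be(crc32(body)))
}

# R's memCompress(type = "gzip") emits an RFC 1950 zlib stream (header
# 0x78 ..), which is exactly what a PNG IDAT chunk carries.
zlib_deflate <- function(data) {
  z <- memCompress(data, type = "gzip")
  stopifnot(z[1] == as.raw(0x78))
  z
}

write_png_gray16 <- function(px, path) {
  m <- nrow(px); n <- ncol(px)
  v <- as.integer(t(px))                     # row-major sample order
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  samples <- as.raw(rbind(hi, lo))           # big-endian 16-bit
  rows <- matrix(samples, nrow = 2L * n)     # one column per scanline
  scan <- as.raw(rbind(as.raw(0L), rows))    # filter byte 0 per scanline
  ihdr <- c(uint32_be(n), uint32_be(m),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, default coding
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_deflate(as.raw(scan))),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

## ---- minimal DICOM reader ----------------------------------------------
## Single-frame, monochrome (or RGB-convertible) little-endian DICOM only;
## explicit and implicit VR transfer syntaxes.  Enough of Part 10 to read
## the modality output of a CT/MR export; not a general toolkit.

dcm_uint16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_uint32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# VRs carrying a 2-byte reserved field + 4-byte length in explicit syntax
dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Read one element header; returns list(group, elem, vr, len, data_pos)
dcm_element_header <- function(raw, pos, explicit) {
  group <- dcm_uint16(raw, pos); elem <- dcm_uint16(raw, pos + 2L)
  if (group == 0xFFFE) {  # item / delimiter tags: always implicit form
    return(list(group = group, elem = elem, vr = NA_character_,
                len = dcm_uint32(raw, pos + 4L), data_pos = pos + 8L))
  }
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dcm_long_vrs) {
      list(group = group, elem = elem, vr = vr,
           len = dcm_uint32(raw, pos + 8L), data_pos = pos + 12L)
    } else {
      list(group = group, elem = elem, vr = vr,
           len = as.numeric(dcm_uint16(raw, pos + 6L)), data_pos = pos + 8L)
    }
  } else {
    list(group = group, elem = elem, vr = NA_character_,
         len = dcm_uint32(raw, pos + 4L), data_pos = pos + 8L)
  }
}

UNDEF_LEN <- 4294967295  # 0xFFFFFFFF

# Skip past an undefined-length sequence body, returning the position after
# its sequence-delimitation item.
dcm_skip_sequence <- function(raw, pos, explicit) {
  repeat {
    h <- dcm_element_header(raw, pos, explicit)
    if (h$group == 0xFFFE && h$elem == 0xE0DD) return(h$data_pos)
    if (h$group == 0xFFFE && h$elem == 0xE000) {
      pos <- if (h$len == UNDEF_LEN) dcm_skip_item(raw, h$data_pos, explicit)
      else h$data_pos + h$len
    } else {
      stop("malformed DICOM sequence", call. = FALSE)
    }
  }
}

# Skip an undefined-length item (a nested dataset) up to its delimiter.
dcm_skip_item <- function(raw, pos, explicit) {
  repeat {
    h <- dcm_element_header(raw, pos, explicit)
    if (h$group == 0xFFFE && h$elem == 0xE00D) return(h$data_pos)
    pos <- if (h$len == UNDEF_LEN) dcm_skip_sequence(raw, h$data_pos, explicit)
    else h$data_pos + h$len
  }
}

read_dicom_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", path), call. = FALSE)
  pos <- 133L
  ts <- "1.2.840.10008.1.2.1"
  # file meta group (0002,xxxx): always explicit little endian
  while (pos + 7L <= length(raw)) {
    h <- dcm_element_header(raw, pos, explicit = TRUE)
    if (h$group != 2L) break
    if (h$elem == 0x0010)
      ts <- trimws(rawToChar(raw[h$data_pos:(h$data_pos + h$len - 1L)]),
                   whitespace = "[ \\0]")
    pos <- h$data_pos + h$len
  }
  explicit <- switch(ts,
                     "1.2.840.10008.1.2"   = FALSE,
                     "1.2.840.10008.1.2.1" = TRUE,
                     stop(sprintf("unsupported DICOM transfer syntax '%s'", ts),
                          call. = FALSE))
  el <- list()
  while (pos + 7L <= length(raw)) {
    h <- dcm_element_header(raw, pos, explicit)
    if (h$len == UNDEF_LEN) {
      pos <- dcm_skip_sequence(raw, h$data_pos, explicit)
      next
    }
    key <- sprintf("%04x%04x", h$group, h$elem)
    dat <- if (h$len > 0) raw[h$data_pos:(h$data_pos + h$len - 1L)] else raw(0)
    el[[key]] <- list(vr = h$vr, data = dat)
    pos <- h$data_pos + h$len
  }
  get_us <- function(key, default = NULL) {
    e <- el[[key]]
    if (is.null(e)) return(default)
    dcm_uint16(e$data, 1L)
  }
  get_str <- function(key, default = NULL) {
    e <- el[[key]]
    if (is.null(e) || length(e$data) == 0) return(default)
    trimws(rawToChar(e$data), whitespace = "[ \\0]")
  }
  rows <- get_us("00280010"); cols <- get_us("00280011")
  if (is.null(rows) || is.null(cols))
    stop(sprintf("'%s': DICOM file has no image dimensions", path),
         call. = FALSE)
  nframes <- suppressWarnings(as.integer(get_str("00280008", "1")))
  if (!is.na(nframes) && nframes > 1L)
    stop("multi-frame DICOM is not supported", call. = FALSE)
  spp <- get_us("00280002", 1L)
  bits <- get_us("00280100", 16L)
  signed <- identical(get_us("00280103", 0L), 1L)
  slope <- as.numeric(get_str("00281053", "1"))
  intercept <- as.numeric(get_str("00281052", "0"))
  pxe <- el[["7fe00010"]]
  if (is.null(pxe)) stop("DICOM file has no pixel data", call. = FALSE)
  npix <- rows * cols * spp
  size <- bits %/% 8L
  v <- readBin(pxe$data, what = "integer", n = npix, size = size,
               signed = if (size <= 2L) signed else TRUE,
               endian = "little")
  if (size == 4L && !signed) v <- ifelse(v < 0, v + 2^32, as.numeric(v))
  v <- as.numeric(v)
  if (spp > 1L) {  # interleaved channels -> unweighted mean
    warning("DICOM input has multiple samples per pixel; converted to grayscale by unweighted channel mean",
            call. = FALSE)
    v <- rowMeans(matrix(v, ncol = spp, byrow = TRUE))
  }
  px <- matrix(v, nrow = rows, byrow = TRUE)
  px <- slope * px + intercept
  spacing <- get_str("00280030")
  spacing <- if (!is.null(spacing))
    as.numeric(strsplit(spacing, "\\\\")[[1]])[1:2] else NULL
  bd <- if (bits <= 8L) 8L else if (bits <= 16L) 16L else 32L
  gray_image(px, bit_depth = bd, pixel_spacing = spacing)
}
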