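# Minimal baseline TIFF reader/writer. Covers exactly what this package
# needs: uncompressed grayscale or chunky multi-sample images, 8- or 16-bit
# unsigned, single- or multi-page (multi-page = time), both byte orders on
# read, little-endian single-strip on write. Anything else (compression,
# tiles, planar config, float samples) is rejected with a format error.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L)

#' Read a TIFF file
#'
#' @param path file path.
#' @return list of pages; each page is a numeric matrix (grayscale) or a
#'   3D array rows x cols x samples (multi-sample, e.g. RGB).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order_mark <- rawToChar(raw[1:2])
  endian <- if (order_mark == "II") "little"
            else if (order_mark == "MM") "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42L) stop("bad TIFF magic in ", path, call. = FALSE)
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      type_size <- c(1, 1, 2, 4, 8)[type]
      if (is.na(type_size)) next
      total <- type_size * count
      val_off <- if (total <= 4) base + 8 else u32(base + 8)
      vals <- switch(as.character(type),
        "3" = vapply(seq_len(count) - 1L,
                     function(i) u16(val_off + 2 * i), numeric(1)),
        "4" = vapply(seq_len(count) - 1L,
                     function(i) u32(val_off + 4 * i), numeric(1)),
        "1" = as.numeric(raw[(val_off + 1):(val_off + count)]),
        NULL)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    get_tag <- function(name, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[name]])]]
      if (is.null(v)) default else v
    }
    w <- get_tag("ImageWidth"); h <- get_tag("ImageLength")
    if (is.null(w) || is.null(h))
      stop("TIFF page missing dimensions in ", path, call. = FALSE)
    comp <- get_tag("Compression", 1)
    if (comp != 1)
      stop(sprintf("unsupported TIFF compression %d in %s (only uncompressed)",
                   comp, path), call. = FALSE)
    bits <- get_tag("BitsPerSample", 8)
    spp <- get_tag("SamplesPerPixel", 1)
    if (length(unique(bits)) != 1L || !unique(bits) %in% c(8, 16))
      stop(sprintf("unsupported bit depth (%s) in %s: only 8/16-bit",
                   paste(bits, collapse = ","), path), call. = FALSE)
    bits <- bits[1L]
    offsets <- get_tag("StripOffsets")
    counts <- get_tag("StripByteCounts")
    if (is.null(offsets))
      stop("TIFF page missing strip offsets in ", path, call. = FALSE)
    if (is.null(counts)) counts <- rep(w * h * spp * bits / 8, length(offsets))
    data <- raw(0)
    for (i in seq_along(offsets))
      data <- c(data, raw[(offsets[i] + 1):(offsets[i] + counts[i])])
    n_px <- w * h * spp
    vals <- if (bits == 8) {
      as.numeric(readBin(data, "integer", n = n_px, size = 1, signed = FALSE))
    } else {
      as.numeric(readBin(data, "integer", n = n_px, size = 2, signed = FALSE,
                         endian = endian))
    }
    page <- if (spp == 1) {
      matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    } else {
      a <- array(0, dim = c(h, w, spp))
      for (s in seq_len(spp))
        a[, , s] <- matrix(vals[seq(s, n_px, by = spp)], h, w, byrow = TRUE)
      a
    }
    pages[[length(pages) + 1L]] <- page
    ifd_off <- u32(ifd_off + 2 + n_entries * 12)
  }
  if (!length(pages)) stop("TIFF with no pages: ", path, call. = FALSE)
  pages
}

#' Write a TIFF file
#'
#' Little-endian, uncompressed, one strip per page.
#'
#' @param data numeric matrix (one page), 3D array (third dim = pages) or
#'   list of matrices. Values are rounded and clamped to the sample range.
#' @param path output path.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(data, path, bits = 16) {
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16", call. = FALSE)
  pages <- if (is.matrix(data)) list(data)
           else if (is.array(data) && length(dim(data)) == 3L)
             lapply(seq_len(dim(data)[3L]), function(i) data[, , i])
           else if (is.list(data)) data
           else stop("data must be a matrix, 3D array or list of matrices",
                     call. = FALSE)
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset: header(8) + all pixel data blocks
  sizes <- vapply(pages, function(p) length(p) * bits / 8, numeric(1))
  data_offsets <- 8 + c(0, cumsum(sizes))[seq_along(pages)]
  first_ifd <- 8 + sum(sizes)
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (p in pages) {
    v <- as.integer(pmin(pmax(round(t(p)), 0), maxval))  # row-major
    writeBin(v, con, size = bits / 8, endian = "little")
  }
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    ifd_off <- first_ifd + (i - 1) * ifd_size
    next_ifd <- if (i < length(pages)) ifd_off + ifd_size else 0
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) {  # SHORT left-justified in the 4-byte slot
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 3, 1, ncol(p))                  # ImageWidth
    entry(257, 3, 1, nrow(p))                  # ImageLength
    entry(258, 3, 1, bits)                     # BitsPerSample
    entry(259, 3, 1, 1)                        # Compression: none
    entry(262, 3, 1, 1)                        # Photometric: BlackIsZero
    entry(273, 4, 1, data_offsets[i])          # StripOffsets
    entry(277, 3, 1, 1)                        # SamplesPerPixel
    entry(278, 3, 1, nrow(p))                  # RowsPerStrip
    entry(279, 4, 1, sizes[i])                 # StripByteCounts
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an image or time-lapse from a TIFF file
#'
#' Single-page files load as an `intensity_image`; multi-page files load as
#' a `time_lapse` unless `pages_are_channels = TRUE`, in which case `channel`
#' selects one page. For multi-sample (e.g. RGB) pages a `channel` is
#' required.
#'
#' @param path TIFF path.
#' @param channel 1-based channel index, or NULL.
#' @param pages_are_channels interpret pages as channels, not time.
#' @param dt,pixel_size physical calibration for time-lapses.
#' @return `intensity_image` or `time_lapse`.
#' @export
read_image <- function(path, channel = NULL, pages_are_channels = FALSE,
                       dt = 1, pixel_size = 1) {
  pages <- read_tiff(path)
  pick_channel <- function(page) {
    if (is.matrix(page)) {
      if (!is.null(channel) && channel != 1L)
        stop(sprintf("channel %d requested but %s is single-channel",
                     channel, path), call. = FALSE)
      page
    } else {
      if (is.null(channel))
        stop(sprintf("%s has %d samples per pixel: --channel required",
                     path, dim(page)[3L]), call. = FALSE)
      if (channel < 1L || channel > dim(page)[3L])
        stop(sprintf("channel %d out of range (1..%d) in %s",
                     channel, dim(page)[3L], path), call. = FALSE)
      page[, , channel]
    }
  }
  if (length(pages) == 1L) {
    intensity_image(pick_channel(pages[[1L]]), pixel_size = pixel_size)
  } else if (pages_are_channels) {
    if (is.null(channel))
      stop(sprintf("%s has %d channel pages: --channel required",
                   path, length(pages)), call. = FALSE)
    if (channel < 1L || channel > length(pages))
      stop(sprintf("channel %d out of range (1..%d) in %s",
                   channel, length(pages), path), call. = FALSE)
    page <- pages[[channel]]
    if (!is.matrix(page)) page <- page[, , 1L]
    intensity_image(page, pixel_size = pixel_size)
  } else {
    time_lapse(lapply(pages, pick_channel), dt = dt, pixel_size = pixel_size)
  }
}
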