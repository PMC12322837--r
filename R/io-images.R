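# Image stack I/O.  PNG via the `png` package; TIFF via a minimal built-in
# baseline codec (uncompressed, 8/16-bit, grayscale or RGB, multi-page,
# both byte orders on read, little-endian single-strip on write).  No
# TIFF-capable package ships with the target environment, and baseline
# uncompressed TIFF is a simple container, so the codec is implemented
# here; compressed or tiled TIFFs are rejected with a clear error.

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L ||
      !identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop(sprintf("'%s' is not a PNG file", path))
  as.integer(hdr[25])
}

read_png_sections <- function(path) {
  bd <- png_bit_depth(path)
  arr <- png::readPNG(path)
  scale <- 2^bd - 1
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) arr <- arr[, , 1:3] else arr <- arr[, , 1]
  }
  list(arr * scale)
}

# ---- minimal baseline TIFF ----

tiff_read_ifd_value <- function(con, type, count, endian) {
  # returns the tag's numeric values, resolving the offset indirection
  sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)
  sz <- sizes[as.character(type)]
  if (is.na(sz)) return(NULL)
  nbytes <- sz * count
  here <- seek(con, NA)
  raw4 <- readBin(con, "raw", 4L)
  if (nbytes > 4L) {
    off <- readBin(raw4, "integer", 1L, 4L, endian = endian)
    seek(con, off)
  } else {
    seek(con, here)
  }
  vals <- switch(as.character(type),
    `1` = as.integer(readBin(con, "raw", count)),
    `3` = readBin(con, "integer", count, 2L, signed = FALSE, endian = endian),
    `4` = readBin(con, "integer", count, 4L, endian = endian),
    `5` = {
      v <- readBin(con, "integer", 2L * count, 4L, endian = endian)
      v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
    },
    NULL)
  seek(con, here + 4L)
  vals
}

#' Read a (multi-page) baseline TIFF
#'
#' Supports uncompressed, strip-organized, chunky-planar grayscale or RGB
#' images at 8 or 16 bits per sample, in either byte order.  Returns
#' intensities on the file's native scale (0..255 or 0..65535).
#'
#' @param path TIFF file path.
#' @return list of numeric matrices / RGB arrays, one per page.
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  endian <- if (identical(magic[1:2], charToRaw("II"))) "little"
  else if (identical(magic[1:2], charToRaw("MM"))) "big"
  else stop(sprintf("'%s' is not a TIFF file", path))
  if (readBin(magic[3:4], "integer", 1L, 2L, signed = FALSE, endian = endian) != 42L)
    stop(sprintf("'%s' is not a TIFF file (bad magic)", path))
  ifd_off <- readBin(con, "integer", 1L, 4L, endian = endian)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_tags <- readBin(con, "integer", 1L, 2L, signed = FALSE, endian = endian)
    if (length(n_tags) == 0L) stop(sprintf("truncated TIFF file '%s'", path))
    tags <- list()
    for (i in seq_len(n_tags)) {
      tag <- readBin(con, "integer", 1L, 2L, signed = FALSE, endian = endian)
      type <- readBin(con, "integer", 1L, 2L, signed = FALSE, endian = endian)
      count <- readBin(con, "integer", 1L, 4L, endian = endian)
      tags[[as.character(tag)]] <- tiff_read_ifd_value(con, type, count, endian)
    }
    ifd_off <- readBin(con, "integer", 1L, 4L, endian = endian)
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- need(256)
    height <- need(257)
    if (is.null(width) || is.null(height))
      stop(sprintf("TIFF page in '%s' lacks dimensions", path))
    bps <- need(258, 1L)[1]
    if (!(bps %in% c(8L, 16L)))
      stop(sprintf("unsupported TIFF bit depth %d in '%s'", bps, path))
    if (need(259, 1L) != 1L)
      stop(sprintf("compressed TIFF is not supported ('%s')", path))
    spp <- need(277, 1L)
    if (!(spp %in% c(1L, 3L)))
      stop(sprintf("unsupported TIFF samples-per-pixel %d in '%s'", spp, path))
    if (need(284, 1L) != 1L)
      stop(sprintf("planar TIFF layout is not supported ('%s')", path))
    offs <- need(273)
    cnts <- need(279)
    if (is.null(offs) || is.null(cnts))
      stop(sprintf("TIFF page in '%s' lacks strip layout", path))
    buf <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      buf <- c(buf, readBin(con, "raw", cnts[s]))
    }
    npx <- width * height * spp
    vals <- if (bps == 8L) {
      as.integer(buf[seq_len(npx)])
    } else {
      readBin(buf, "integer", npx, 2L, signed = FALSE, endian = endian)
    }
    storage.mode(vals) <- "double"
    # row-major sample order -> our column-major matrices
    pages[[length(pages) + 1L]] <- if (spp == 1L) {
      t(matrix(vals, width, height))
    } else {
      arr <- array(0, c(height, width, 3L))
      for (ch in 1:3)
        arr[, , ch] <- t(matrix(vals[seq(ch, npx, by = 3L)], width, height))
      arr
    }
  }
  pages
}

tiff_tag <- function(tag, type, count, value, endian = "little") {
  # value must fit in 4 bytes (inline); longer values handled by caller
  sz <- c(`3` = 2L, `4` = 4L)[as.character(type)]
  val_raw <- writeBin(as.integer(value), raw(), sz, endian = endian)
  val_raw <- c(val_raw, raw(4L - length(val_raw)))
  c(writeBin(as.integer(tag), raw(), 2L, endian = endian),
    writeBin(as.integer(type), raw(), 2L, endian = endian),
    writeBin(as.integer(count), raw(), 4L, endian = endian),
    val_raw)
}

#' Write a (multi-page) baseline TIFF
#'
#' Writes uncompressed little-endian TIFF, one page per image.  Inputs
#' with a maximum `<= 1` are treated as normalized and scaled to the full
#' range of `bits`; larger values are written as-is (clamped).
#'
#' @param images list of numeric matrices / RGB arrays (or a single one).
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_tiff <- function(images, path, bits = 8L) {
  if (!is.list(images)) images <- list(images)
  images <- lapply(images, function(m)
    if (inherits(m, "image_section")) m$pixels else m)
  stopifnot(bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)
  # patch the first IFD offset at the end; reserve 4 bytes
  writeBin(as.integer(8L), con, 4L, endian = "little")
  pos <- 8L
  ifd_offsets <- integer(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    rgb <- length(dim(img)) == 3L
    ny <- dim(img)[1]
    nx <- dim(img)[2]
    spp <- if (rgb) 3L else 1L
    v <- if (max(img) <= 1) img * maxv else img
    v <- round(pmin(pmax(v, 0), maxv))
    # interleave samples in row-major order
    vals <- if (rgb) {
      out <- integer(nx * ny * 3L)
      for (ch in 1:3) out[seq(ch, length(out), 3L)] <- as.integer(t(v[, , ch]))
      out
    } else {
      as.integer(t(v))
    }
    data_raw <- writeBin(vals, raw(), size = bits %/% 8L, endian = "little")
    data_off <- pos
    writeBin(data_raw, con)
    pos <- pos + length(data_raw)
    bps_off <- NULL
    if (rgb) {   # BitsPerSample needs 3 SHORTs -> external array
      bps_off <- pos
      writeBin(as.integer(rep(bits, 3L)), con, 2L, endian = "little")
      pos <- pos + 6L
    }
    ifd_offsets[i] <- pos
    entries <- list(
      tiff_tag(256, 4, 1, nx),
      tiff_tag(257, 4, 1, ny),
      if (rgb) tiff_tag(258, 3, 3, bps_off) else tiff_tag(258, 3, 1, bits),
      tiff_tag(259, 3, 1, 1),
      tiff_tag(262, 3, 1, if (rgb) 2 else 1),
      tiff_tag(273, 4, 1, data_off),
      tiff_tag(277, 3, 1, spp),
      tiff_tag(278, 4, 1, ny),
      tiff_tag(279, 4, 1, length(data_raw)),
      tiff_tag(284, 3, 1, 1)
    )
    writeBin(as.integer(length(entries)), con, 2L, endian = "little")
    for (e in entries) writeBin(e, con)
    next_off <- if (i < length(images)) 0L else 0L  # patched after the loop
    writeBin(next_off, con, 4L, endian = "little")
    pos <- pos + 2L + 12L * length(entries) + 4L
  }
  # patch the IFD chain
  seek(con, 4L)
  writeBin(ifd_offsets[1], con, 4L, endian = "little")
  for (i in seq_along(images)) {
    seek(con, ifd_offsets[i] + 2L + 12L * 10L)
    writeBin(if (i < length(images)) ifd_offsets[i + 1L] else 0L, con, 4L,
             endian = "little")
  }
  invisible(path)
}

#' Read an ordered image stack
#'
#' Reads each path as PNG or TIFF (by magic bytes, not extension); a
#' multi-page TIFF contributes one section per page, in page order.
#' Sections are indexed by their overall position in the resulting
#' sequence.  Intensities keep the file's native scale.
#'
#' @param paths character vector of file paths, in stack order.
#' @return list of `image_section`s.
#' @export
read_image_stack <- function(paths) {
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("image file does not exist: '%s'", p))
    magic <- readBin(p, "raw", n = 4L)
    imgs <- if (length(magic) >= 4L &&
                identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
      read_png_sections(p)
    } else if (length(magic) >= 2L &&
               (identical(magic[1:2], charToRaw("II")) ||
                identical(magic[1:2], charToRaw("MM")))) {
      read_tiff(p)
    } else {
      stop(sprintf("cannot read '%s': not a PNG or TIFF file", p))
    }
    for (img in imgs) out[[length(out) + 1L]] <- img
  }
  lapply(seq_along(out), function(i) image_section(out[[i]], i - 1L))
}

#' Write an image stack
#'
#' A `.tif`/`.tiff` path receives one multi-page TIFF; a `.png` path (or a
#' directory) receives one numbered PNG per section.
#'
#' @param sections list of `image_section`s (or matrices).
#' @param path output file (TIFF) or template/directory (PNG).
#' @param bits bits per sample for TIFF output.
#' @param slice_spacing optional physical slice spacing, recorded in a
#'   sidecar `<path>.json` metadata file.
#' @return invisibly, the written file path(s).
#' @export
write_image_stack <- function(sections, path, bits = 8L, slice_spacing = NULL) {
  pix <- lapply(sections, function(s) if (inherits(s, "image_section")) s$pixels else s)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff(pix, path, bits = bits)
    files <- path
  } else {
    stem <- if (ext == "png") sub("\\.png$", "", path, ignore.case = TRUE) else
      file.path(path, "slice")
    if (ext != "png") dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- character(length(pix))
    for (i in seq_along(pix)) {
      v <- pix[[i]]
      if (max(v) > 1) v <- v / max(v)
      files[i] <- sprintf("%s_%03d.png", stem, i - 1L)
      png::writePNG(pmin(pmax(v, 0), 1), files[i])
    }
  }
  if (!is.null(slice_spacing)) {
    jsonlite::write_json(
      list(n_slices = length(pix), slice_spacing = slice_spacing),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(files)
}
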