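#' Write an integer image as ASCII PGM (P2)
#'
#' The portable graymap is the package's primary on-disk raster: plain text,
#' supports the detector's 14-bit range (maxval up to 65535), and readable by
#' standard imaging tools.
#'
#' @param pixels integer matrix of counts (rows x cols).
#' @param path output file path.
#' @param maxval maximum grey value declared in the header; defaults to the
#'   smallest of 255/16383/65535 that covers the data.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path, maxval = NULL) {
  stopifnot(is.matrix(pixels))
  m <- round(pixels)
  if (any(m < 0)) stopf("PGM pixels must be non-negative")
  if (is.null(maxval)) {
    top <- max(m, 1)
    maxval <- if (top <= 255) 255L else if (top <= 16383) 16383L else 65535L
  }
  if (max(m) > maxval) stopf("pixel value exceeds declared maxval %d", maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# grainray radiograph %d x %d", nrow(m), ncol(m)),
               sprintf("%d %d", ncol(m), nrow(m)),
               sprintf("%d", maxval)), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII or binary PGM image
#'
#' @param path file path to a P2 (ASCII) or P5 (binary) graymap.
#' @return integer matrix (rows x cols) of grey values.
#' @export
read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # split header tokens, skipping comment lines
  txt <- rawToChar(raw[seq_len(min(length(raw), 512L))])
  magic <- substr(txt, 1, 2)
  if (!magic %in% c("P2", "P5")) stopf("not a PGM file: %s", path)
  if (magic == "P2") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines)]
    tok <- scan(text = paste(lines, collapse = "\n"), what = integer(),
                skip = 1L, quiet = TRUE)
    w <- tok[1]; h <- tok[2]; maxval <- tok[3]
    vals <- tok[-(1:3)]
    if (length(vals) != w * h) stopf("corrupt PGM: expected %d pixels", w * h)
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    # parse header bytes manually for P5
    pos <- 3L
    vals <- integer(3); got <- 0L
    n <- length(raw)
    while (got < 3L && pos <= n) {
      ch <- rawToChar(raw[pos])
      if (ch == "#") { while (pos <= n && rawToChar(raw[pos]) != "\n") pos <- pos + 1L }
      else if (grepl("[0-9]", ch)) {
        num <- ""
        while (pos <= n && grepl("[0-9]", rawToChar(raw[pos]))) {
          num <- paste0(num, rawToChar(raw[pos])); pos <- pos + 1L
        }
        got <- got + 1L; vals[got] <- as.integer(num)
      } else pos <- pos + 1L
    }
    pos <- pos + 1L  # single whitespace after maxval
    w <- vals[1]; h <- vals[2]; maxval <- vals[3]
    bytes <- if (maxval > 255) 2L else 1L
    body <- raw[pos:(pos + w * h * bytes - 1L)]
    px <- if (bytes == 2L) {
      readBin(body, "integer", n = w * h, size = 2L, signed = FALSE,
              endian = "big")
    } else as.integer(body)
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  }
}

#' Write an 8-bit PNG preview of an image
#'
#' Linearly rescales to the 0..255 range for visual inspection; not a data
#' format (the 14-bit counts do not survive).
#'
#' @param pixels numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png_preview <- function(pixels, path) {
  rng <- range(pixels)
  scaled <- if (diff(rng) == 0) pixels * 0 else (pixels - rng[1]) / diff(rng)
  png::writePNG(scaled, path)
  invisible(path)
}

# float images (attenuation maps) round-trip through TSV
write_float_image <- function(values, path) {
  data.table::fwrite(data.table::as.data.table(values), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

read_float_image <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
}

#' Read a radiograph from disk
#'
#' Accepts ASCII/binary PGM (primary format) or 8/16-bit grayscale PNG.
#'
#' @param path image path; format chosen by extension.
#' @param pixel_size_um physical pixel pitch in micrometres (detector default
#'   49.5).
#' @param metadata optional named list of acquisition settings
#'   (voltage_kV, current_uA, exposure_ms, fod_mm).
#' @return a [radiograph] object.
#' @export
read_radiograph <- function(path, pixel_size_um = 49.5, metadata = list()) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    png = {
      arr <- png::readPNG(path)
      if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
      round(arr * 65535)
    },
    stopf("unsupported image format '.%s' (use .pgm or .png)", ext)
  )
  radiograph(px, pixel_size_um = pixel_size_um, metadata = metadata)
}
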