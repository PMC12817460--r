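# Minimal DICOM Part-10 support: explicit-VR little-endian, flat datasets.
# Covers exactly the tag set this pipeline reads and writes; sequences,
# compressed transfer syntaxes and implicit VR are rejected with a clear
# error rather than mis-parsed.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
.u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

.dicom_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else v <- value
  hdr <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), .u32le(length(v)), v)
  } else {
    c(hdr, .u16le(length(v)), v)
  }
}

#' Write a minimal DICOM Part-10 file
#'
#' Writes a flat explicit-VR little-endian dataset holding grayscale pixel
#' data and the header tags the annotation pipeline consumes: SOP instance
#' UID, modality, manufacturer, acquisition date, Body Part Examined
#' (0018,0015) and Photometric Interpretation. Used by the synthetic
#' corpus generator and by tests; it is not a general-purpose DICOM
#' serializer.
#'
#' @param path output file.
#' @param pixels integer matrix (rows x columns) of nonnegative
#'   intensities.
#' @param sop_uid SOP instance UID string.
#' @param modality "CR" or "DX".
#' @param body_part raw Body Part Examined string, or \code{NULL} to omit
#'   the tag entirely (emulating missing headers).
#' @param photometric "MONOCHROME2" (dark background) or "MONOCHROME1".
#' @param manufacturer free text.
#' @param acquisition_date "YYYYMMDD" or \code{NULL}.
#' @param bits_stored stored bit depth (8 or 10-16); bits allocated is 8
#'   when \code{bits_stored <= 8}, else 16.
#' @return \code{path}, invisibly.
#' @export
write_dicom <- function(path, pixels, sop_uid, modality = "CR",
                        body_part = NULL, photometric = "MONOCHROME2",
                        manufacturer = "SYNTH", acquisition_date = NULL,
                        bits_stored = 10L) {
  stopifnot(is.matrix(pixels), all(pixels >= 0))
  alloc <- if (bits_stored <= 8L) 8L else 16L
  maxv <- 2^bits_stored - 1
  if (max(pixels) > maxv) stop("pixel values exceed bits_stored range")
  v <- as.integer(round(as.vector(t(pixels))))   # DICOM is row-major
  pix_raw <- if (alloc == 8L) as.raw(v) else {
    vv <- ifelse(v >= 32768L, v - 65536L, v)
    writeBin(vv, raw(), size = 2L, endian = "little")
  }
  sop_class <- "1.2.840.10008.5.1.4.1.1.1"
  meta <- c(
    .dicom_element(2L, 1L, "OB", as.raw(c(0, 1))),
    .dicom_element(2L, 2L, "UI", sop_class),
    .dicom_element(2L, 3L, "UI", sop_uid),
    .dicom_element(2L, 16L, "UI", .TS_EXPLICIT_LE),
    .dicom_element(2L, 18L, "UI", "1.2.826.0.1.3680043.9999.1")
  )
  body <- c(
    .dicom_element(8L, 22L, "UI", sop_class),
    .dicom_element(8L, 24L, "UI", sop_uid),
    if (!is.null(acquisition_date))
      .dicom_element(8L, 32L, "DA", acquisition_date),
    if (!is.null(acquisition_date))
      .dicom_element(8L, 34L, "DA", acquisition_date),
    .dicom_element(8L, 96L, "CS", modality),
    .dicom_element(8L, 112L, "LO", manufacturer),
    if (!is.null(body_part)) .dicom_element(24L, 21L, "CS", body_part),
    .dicom_element(40L, 2L, "US", .u16le(1L)),
    .dicom_element(40L, 4L, "CS", photometric),
    .dicom_element(40L, 16L, "US", .u16le(nrow(pixels))),
    .dicom_element(40L, 17L, "US", .u16le(ncol(pixels))),
    .dicom_element(40L, 256L, "US", .u16le(alloc)),
    .dicom_element(40L, 257L, "US", .u16le(bits_stored)),
    .dicom_element(40L, 258L, "US", .u16le(bits_stored - 1L)),
    .dicom_element(40L, 259L, "US", .u16le(0L)),
    .dicom_element(32736L, 16L, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(.dicom_element(2L, 0L, "UL", .u32le(length(meta))), meta, body), con)
  invisible(path)
}

.parse_dicom <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("not a DICOM Part-10 file: ", path)
  r <- readBin(path, "raw", n = n)
  if (rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM Part-10 file (missing DICM magic): ", path)
  u16 <- function(i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
  u32 <- function(i) as.integer(r[i]) + 256 * as.integer(r[i + 1L]) +
    65536 * as.integer(r[i + 2L]) + 16777216 * as.integer(r[i + 3L])
  els <- list()
  i <- 133L
  while (i + 7L <= n) {
    group <- u16(i); elem <- u16(i + 2L)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (implicit VR?) in ", path)
    if (vr %in% .LONG_VRS) {
      len <- u32(i + 8L); off <- 12L
    } else {
      len <- u16(i + 6L); off <- 8L
    }
    if (vr == "SQ") stop("unsupported DICOM element (sequence) in ", path)
    start <- i + off
    if (start + len - 1L > n) stop("truncated DICOM element in ", path)
    key <- sprintf("%04x,%04x", group, elem)
    els[[key]] <- list(vr = vr, value = r[seq.int(start, length.out = len)])
    i <- start + len
  }
  ts <- els[["0002,0010"]]
  if (!is.null(ts)) {
    tsv <- .raw_string(ts$value)
    if (tsv != .TS_EXPLICIT_LE)
      stop("unsupported transfer syntax ", tsv, " in ", path)
  }
  els
}

# Decode a DICOM string value: trailing NUL/space padding is not content.
.raw_string <- function(v) {
  pad <- c(as.raw(0L), charToRaw(" "))
  while (length(v) && v[length(v)] %in% pad) v <- v[-length(v)]
  if (!length(v)) return("")
  rawToChar(v)
}

.el_string <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  .raw_string(e$value)
}

.el_us <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  as.integer(e$value[1]) + 256L * as.integer(e$value[2])
}

.header_from_elements <- function(els, path) {
  list(
    sop_uid = .el_string(els, "0008,0018"),
    modality = .el_string(els, "0008,0060"),
    body_part_examined_raw = .el_string(els, "0018,0015"),
    photometric_interpretation = .el_string(els, "0028,0004"),
    manufacturer = .el_string(els, "0008,0070"),
    acquisition_date = .el_string(els, "0008,0022"),
    bits_stored = .el_us(els, "0028,0101"),
    path = path
  )
}

#' Read a DICOM file into an image record
#'
#' Parses a Part-10 explicit-VR little-endian file and returns the pixel
#' matrix together with the header fields used by the pipeline. Absent
#' tags stay absent (\code{NULL}); nothing is invented.
#'
#' @param path DICOM file path.
#' @return an object of class \code{xr_image}: list with \code{header}
#'   (named list), \code{pixels} (numeric matrix, rows x columns),
#'   \code{labels_examined}, \code{labels_visible}.
#' @export
read_image <- function(path) {
  els <- .parse_dicom(path)
  hdr <- .header_from_elements(els, path)
  if (is.null(hdr$sop_uid)) stop("DICOM file lacks SOP instance UID: ", path)
  pix <- els[["7fe0,0010"]]
  if (is.null(pix)) stop("DICOM file has no pixel data: ", path)
  rows <- .el_us(els, "0028,0010"); cols <- .el_us(els, "0028,0011")
  alloc <- .el_us(els, "0028,0100")
  if (is.null(rows) || is.null(cols) || is.null(alloc))
    stop("DICOM file lacks image description tags: ", path)
  v <- if (alloc == 8L) as.integer(pix$value) else {
    x <- readBin(pix$value, "integer", n = length(pix$value) %/% 2L,
                 size = 2L, signed = FALSE, endian = "little")
    as.integer(x)
  }
  if (length(v) < rows * cols) stop("pixel data shorter than Rows x Columns: ", path)
  structure(list(
    header = hdr,
    pixels = matrix(v[seq_len(rows * cols)], nrow = rows, byrow = TRUE),
    labels_examined = NULL,
    labels_visible = NULL
  ), class = "xr_image")
}

#' @export
print.xr_image <- function(x, ...) {
  cat("X-ray image record:", paste(dim(x$pixels), collapse = "x"),
      "pixels; modality", x$header$modality %||% "?", "; body part",
      x$header$body_part_examined_raw %||% "<absent>", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.border_median <- function(px, frac = 0.05) {
  b <- pmax(1L, round(frac * dim(px)))
  idx <- matrix(FALSE, nrow(px), ncol(px))
  idx[c(seq_len(b[1]), nrow(px) - seq_len(b[1]) + 1L), ] <- TRUE
  idx[, c(seq_len(b[2]), ncol(px) - seq_len(b[2]) + 1L)] <- TRUE
  median(px[idx])
}

#' Normalize image polarity to a dark background
#'
#' Inverted radiographs (light background) are intensity-flipped so that
#' the background is dark. An image is deemed inverted when the header
#' says MONOCHROME1, or — when Photometric Interpretation is absent — when
#' the median of a 5\%-wide border exceeds the global mean intensity (the
#' mean, unlike the median, stays informative when background dominates
#' the image area). Inversion
#' maps \eqn{v \mapsto max - v} where \eqn{max} is the stored bit-depth
#' ceiling when known, else the image maximum. The header is updated to
#' MONOCHROME2, making the operation idempotent on records.
#'
#' @param rec an \code{xr_image}.
#' @return the record, polarity-normalized.
#' @export
normalize_polarity <- function(rec) {
  stopifnot(inherits(rec, "xr_image"))
  pi <- rec$header$photometric_interpretation
  inverted <- if (!is.null(pi)) identical(pi, "MONOCHROME1")
              else .border_median(rec$pixels) > mean(rec$pixels)
  if (inverted) {
    maxv <- if (!is.null(rec$header$bits_stored))
      2^rec$header$bits_stored - 1 else max(rec$pixels)
    if (is.integer(rec$pixels)) maxv <- as.integer(maxv)
    rec$pixels <- maxv - rec$pixels
    rec$header$photometric_interpretation <- "MONOCHROME2"
  } else if (is.null(pi)) {
    rec$header$photometric_interpretation <- "MONOCHROME2"
  }
  rec
}

#' Extract DICOM headers to a table
#'
#' Reads the header of every file and assembles one row per readable
#' image, in a fixed column order, with absent tags as empty cells.
#' Unreadable files are skipped with a warning (logged, never fatal).
#'
#' @param paths character vector of DICOM file paths.
#' @param file optional CSV output path (UTF-8, header row).
#' @return data.frame with columns \code{sop_uid, path, modality,
#'   body_part_examined, photometric_interpretation, manufacturer,
#'   acquisition_date, rows, columns}.
#' @export
headers_to_table <- function(paths, file = NULL) {
  rows <- lapply(paths, function(p) {
    els <- tryCatch(.parse_dicom(p), error = function(e) NULL)
    if (is.null(els)) {
      warning("skipping unreadable file: ", p, call. = FALSE)
      return(NULL)
    }
    h <- .header_from_elements(els, p)
    data.frame(
      sop_uid = h$sop_uid %||% "",
      path = p,
      modality = h$modality %||% "",
      body_part_examined = h$body_part_examined_raw %||% "",
      photometric_interpretation = h$photometric_interpretation %||% "",
      manufacturer = h$manufacturer %||% "",
      acquisition_date = h$acquisition_date %||% "",
      rows = .el_us(els, "0028,0010") %||% NA_integer_,
      columns = .el_us(els, "0028,0011") %||% NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(sop_uid = character(0), path = character(0),
                      modality = character(0), body_part_examined = character(0),
                      photometric_interpretation = character(0),
                      manufacturer = character(0), acquisition_date = character(0),
                      rows = integer(0), columns = integer(0))
  if (!is.null(file)) write.csv(tab, file, row.names = FALSE)
  tab
}

#' Export an image record as an 8-bit grayscale PNG
#'
#' Pixels are min-max scaled to 0..255 and written as 8-bit grayscale; a
#' constant image maps to mid-gray (128) by convention. Output bytes are
#' deterministic for a fixed input.
#'
#' @param rec an \code{xr_image} or a plain numeric matrix.
#' @param path output PNG path.
#' @return the 8-bit integer matrix actually written, invisibly.
#' @export
export_png <- function(rec, path) {
  px <- if (inherits(rec, "xr_image")) rec$pixels else rec
  stopifnot(is.matrix(px), all(is.finite(px)))
  rng <- range(px)
  scaled <- if (rng[1] == rng[2]) matrix(128L, nrow(px), ncol(px))
            else matrix(as.integer(round((px - rng[1]) / diff(rng) * 255)),
                        nrow(px), ncol(px))
  png::writePNG(scaled / 255, target = path)
  invisible(scaled)
}
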