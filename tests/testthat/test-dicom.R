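write_fixture <- function(path, px = NULL, ...) {
  if (is.null(px)) px <- matrix(sample(0:1023, 32 * 32, TRUE), 32, 32)
  write_dicom(path, px, sop_uid = "1.2.826.0.1.3680043.9999.3.1", ...)
  px
}

test_that("DICOM header and 16-bit pixels round-trip without loss", {
  set.seed(5)
  f <- tempfile(fileext = ".dcm")
  px <- write_fixture(f, body_part = "BREAST", modality = "DX",
                      acquisition_date = "20210317")
  rec <- read_image(f)
  expect_identical(rec$pixels, px)
  expect_equal(rec$header$body_part_examined_raw, "BREAST")
  expect_equal(rec$header$modality, "DX")
  expect_equal(rec$header$acquisition_date, "20210317")
  expect_equal(rec$header$photometric_interpretation, "MONOCHROME2")
})

test_that("absent tags stay absent; bad files give distinct errors", {
  f <- tempfile(fileext = ".dcm")
  write_fixture(f)  # no body part tag
  expect_null(read_image(f)$header$body_part_examined_raw)

  junk <- tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0L, 200)), junk)
  expect_error(read_image(junk), "DICM")
  expect_error(read_image(tempfile()), "DICOM")
})

test_that("pydicom parses files written by write_dicom identically", {
  # independent reference parser on a tiny fixture
  f <- tempfile(fileext = ".dcm")
  px <- matrix(0:1023, 32, 32)
  write_dicom(f, px, sop_uid = "1.2.3.4.5", body_part = "HAND",
              modality = "CR", photometric = "MONOCHROME2")
  script <- paste(
    "import pydicom, sys",
    sprintf("d = pydicom.dcmread(r'%s')", f),
    "print(d.BodyPartExamined); print(d.Modality); print(d.Rows)",
    "print(int(d.pixel_array[0, 0])); print(int(d.pixel_array[31, 31]))",
    "print(int(d.pixel_array.sum()))", sep = "\n")
  out <- suppressWarnings(
    system2("python", "-", stdout = TRUE, stderr = FALSE, input = script))
  expect_equal(out, c("HAND", "CR", "32", "0", "1023",
                      as.character(sum(px))))
})

test_that("polarity normalization inverts only light-background images, idempotently", {
  base <- matrix(sample(0:1023, 64 * 64, TRUE), 64, 64)
  f1 <- tempfile(fileext = ".dcm"); f2 <- tempfile(fileext = ".dcm")
  write_dicom(f1, base, sop_uid = "1.1", photometric = "MONOCHROME2")
  write_dicom(f2, 1023 - base, sop_uid = "1.2", photometric = "MONOCHROME1")
  r1 <- normalize_polarity(read_image(f1))
  r2 <- normalize_polarity(read_image(f2))
  expect_identical(r1$pixels, base)       # unchanged
  expect_identical(r2$pixels, base)       # inverted back: v -> max - v
  expect_identical(normalize_polarity(r2)$pixels, base)  # idempotent
  expect_equal(r2$header$photometric_interpretation, "MONOCHROME2")
})

test_that("border statistics detect inversion when the header is silent", {
  dark_bg <- matrix(50, 64, 64); dark_bg[20:44, 20:44] <- 900
  light_bg <- 1023 - dark_bg
  mk <- function(px) {
    rec <- structure(list(header = list(photometric_interpretation = NULL,
                                        bits_stored = 10L),
                          pixels = px), class = "xr_image")
    normalize_polarity(rec)
  }
  expect_identical(mk(dark_bg)$pixels, dark_bg)
  expect_identical(mk(light_bg)$pixels, dark_bg)
})

test_that("headers_to_table collects one row per readable file, blanks for absent tags", {
  d <- tempfile(); dir.create(d)
  write_fixture(file.path(d, "a.dcm"), body_part = "HAND")
  write_fixture(file.path(d, "b.dcm"))                     # missing body part
  write_fixture(file.path(d, "c.dcm"), body_part = "KNIE")
  writeBin(as.raw(1:64), file.path(d, "broken.dcm"))
  paths <- file.path(d, c("a.dcm", "b.dcm", "c.dcm", "broken.dcm"))
  out <- tempfile(fileext = ".csv")
  tab <- suppressWarnings(headers_to_table(paths, file = out))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$body_part_examined, c("HAND", "", "KNIE"))
  expect_warning(headers_to_table(paths), "unreadable")
  reread <- read.csv(out, colClasses = "character")
  expect_equal(nrow(reread), 3L)
  vocab <- load_vocabulary()
  expect_equal(normalize_codes(tab$body_part_examined, vocab),
               c(85562004, -1, 72696002))
})

test_that("PNG export min-max scales, with constant images at mid-gray", {
  ramp8 <- matrix(rep(0:255, length.out = 64 * 64), 64, 64)
  f <- tempfile(fileext = ".png")
  written <- export_png(ramp8, f)
  expect_identical(written, matrix(as.integer(ramp8), 64, 64))

  ramp16 <- ramp8 * 257   # 16-bit ramp rescales linearly back to 0..255
  expect_identical(export_png(ramp16, f), matrix(as.integer(ramp8), 64, 64))

  flat <- matrix(700, 16, 16)
  expect_true(all(export_png(flat, f) == 128L))
  expect_true(all(png::readPNG(f) == 128 / 255))
})
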