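test_that("all four volume kinds round-trip bit-exactly through .nii.gz", {
  tmp <- withr::local_tempdir()
  set.seed(42)

  v <- volume3d(array(sample(0:4000, 4 * 5 * 6, replace = TRUE), c(4, 5, 6)),
                spacing = c(0.5, 0.5, 0.5))
  p <- file.path(tmp, "scalar.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_s3_class(v2, "volume3d")
  expect_identical(as.integer(v2$values), as.integer(v$values))
  expect_equal(v2$spacing, v$spacing)

  rgbv <- rgb_volume(array(sample(0:255, 3 * 4 * 5 * 3, replace = TRUE),
                           c(3, 4, 5, 3)), spacing = c(1, 1, 2))
  p <- file.path(tmp, "rgb.nii.gz")
  write_volume(rgbv, p)
  r2 <- read_volume(p)
  expect_s3_class(r2, "rgb_volume")
  expect_identical(r2$values, rgbv$values)
  expect_equal(r2$spacing, rgbv$spacing)

  tv <- tensor_volume(array(rnorm(2 * 3 * 4 * 6), c(2, 3, 4, 6)),
                      spacing = c(1, 1, 1))
  p <- file.path(tmp, "tensor.nii.gz")
  write_volume(tv, p)
  t2 <- read_volume(p)
  expect_s3_class(t2, "tensor_volume")
  expect_identical(t2$values, tv$values)

  lv <- label_volume(array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4)),
                     spacing = c(5, 5, 5),
                     label_names = c(`1` = "head", `2` = "thorax", `3` = "leg"))
  p <- file.path(tmp, "labels.nii.gz")
  write_volume(lv, p)
  l2 <- read_volume(p)
  expect_s3_class(l2, "label_volume")
  expect_identical(l2$values, lv$values)
  expect_identical(unname(l2$label_names[as.character(1:3)]),
                   c("head", "thorax", "leg"))
})

test_that("header encodings follow the on-disk conventions", {
  tmp <- withr::local_tempdir()
  # uint16 with 0.5 mm pixdim reads back with the declared spacing
  v <- volume3d(array(rep(300L, 8), c(2, 2, 2)), spacing = c(0.5, 0.5, 0.5))
  p <- file.path(tmp, "u16.nii.gz")
  write_volume(v, p)
  hdr <- RNifti::niftiHeader(p)
  expect_identical(hdr$datatype, 512L)                 # uint16
  expect_equal(hdr$pixdim[2:4], c(0.5, 0.5, 0.5))
  expect_equal(read_volume(p)$spacing, c(0.5, 0.5, 0.5))

  # RGB datatype code
  rgbv <- rgb_volume(array(0L, c(2, 2, 2, 3)))
  p <- file.path(tmp, "rgb.nii.gz")
  write_volume(rgbv, p)
  expect_identical(RNifti::niftiHeader(p)$datatype, 128L)

  # symmetric-matrix intent with 6 components
  tv <- tensor_volume(array(1, c(2, 2, 2, 6)))
  p <- file.path(tmp, "sm.nii.gz")
  write_volume(tv, p)
  hdr <- RNifti::niftiHeader(p)
  expect_identical(hdr$intent_code, 1005L)
  expect_identical(hdr$dim[6], 6L)
  expect_s3_class(read_volume(p), "tensor_volume")
})

test_that("small integer ranges pick uint8 and real grids survive within float32", {
  tmp <- withr::local_tempdir()
  v <- volume3d(array(7L, c(2, 2, 2)))
  p <- file.path(tmp, "u8.nii.gz")
  write_volume(v, p)
  expect_identical(RNifti::niftiHeader(p)$datatype, 2L)  # uint8

  vr <- volume3d(array(runif(27) * 30, c(3, 3, 3)))
  p <- file.path(tmp, "f32.nii.gz")
  write_volume(vr, p)
  back <- read_volume(p)
  expect_equal(back$values, vr$values, tolerance = 1e-6)
})

test_that("malformed and unsupported inputs give clear errors", {
  tmp <- withr::local_tempdir()
  junk <- file.path(tmp, "junk.nii.gz")
  con <- gzfile(junk, "wb")
  writeBin(as.integer(c(999, 0, 0)), con, size = 4L)
  close(con)
  expect_error(read_volume(junk), "does not look like a NIFTI-1")

  # NIFTI-2 (sizeof_hdr 540) rejected with a clear message
  n2 <- file.path(tmp, "n2.nii.gz")
  con <- gzfile(n2, "wb")
  writeBin(540L, con, size = 4L)
  close(con)
  expect_error(read_volume(n2), "NIFTI-2")

  expect_error(read_volume(file.path(tmp, "nothere.nii.gz")), "not found")
  expect_error(write_volume(volume3d(array(1.5, c(2, 2, 2))) |>
                              (\(v) { v$values[1] <- Inf; v })(),
                            file.path(tmp, "bad.nii.gz")),
               "non-finite")
})

test_that("volume constructors enforce their invariants", {
  expect_error(volume3d(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  expect_error(rgb_volume(array(300, c(2, 2, 2, 3))), "\\[0, 255\\]")
  expect_error(tensor_volume(array(1, c(2, 2, 2, 5))), "6")
  expect_error(label_volume(array(c(-1L, rep(0L, 7)), c(2, 2, 2))),
               "non-negative")
  expect_error(label_volume(array(2L, c(2, 2, 2)), label_names = c(`1` = "a")),
               "without names")
})
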