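test_that("volume constructor enforces its invariants", {
  d <- array(0, c(4, 4, 4))
  expect_s3_class(volume(d, modality = "CT"), "masct_volume")
  expect_error(volume(d, spacing = c(1, 0, 1)), "spacing")
  expect_error(volume(d, direction = matrix(1, 3, 3)), "orthonormal")
  bad <- d; bad[1] <- NaN
  expect_error(volume(bad), "finite")
  expect_error(volume(array(2, c(4, 4, 4)), modality = "MASK"), "mask")
  expect_error(label_volume(array(7L, c(4, 4, 4)),
                            list(spacing = c(1, 1, 1), origin = c(0, 0, 0),
                                 direction = diag(3))), "label codes")
})

test_that("NIfTI write/read round-trips data and geometry", {
  set.seed(1)
  dir <- withr::local_tempdir()
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))   # random orthonormal direction
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  v <- volume(array(rnorm(9 * 8 * 7, 0, 300), c(9, 8, 7)),
              spacing = c(0.9766, 0.9766, 2.5), origin = c(-120.25, 88.5, 10),
              direction = rot, modality = "CT")
  for (ext in c(".nii", ".nii.gz")) {
    f <- file.path(dir, paste0("v", ext))
    write_volume(v, f)
    v2 <- read_volume(f, "CT")
    expect_lt(max(abs(v2$data - v$data)), 1e-3)           # float32 data
    expect_lt(max(abs(v2$data - v$data)) / max(abs(v$data)), 1e-6)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)     # exact geometry
    expect_lt(max(abs(v2$origin - v$origin)), 1e-6)
    expect_lt(max(abs(v2$direction - v$direction)), 1e-6)
  }
  # masks stored as 8-bit with values preserved
  m <- volume(array(as.double(rbinom(4 * 4 * 4, 1, 0.5)), c(4, 4, 4)),
              modality = "MASK")
  f <- file.path(dir, "m.nii.gz")
  write_volume(m, f)
  expect_identical(read_volume(f, "MASK")$data, m$data)
  # NaN rejected before anything is written
  expect_error(write_volume(structure(list(data = array(NaN, c(2, 2, 2)),
                                           spacing = c(1, 1, 1),
                                           origin = c(0, 0, 0),
                                           direction = diag(3),
                                           modality = "CT"),
                                      class = "masct_volume"),
                            file.path(dir, "bad.nii")), "finite")
})

test_that("reading a non-NIfTI file raises a format error, no partial volume", {
  f <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not an image", f)
  expect_error(read_volume(f), class = "masct_io_error")
  expect_error(read_volume(file.path(tempdir(), "does-not-exist.nii")),
               class = "masct_io_error")
})

test_that("our NIfTI writer/reader agree with nibabel", {
  dir <- withr::local_tempdir()
  v <- volume(array(seq_len(6 * 5 * 4) * 1.5, c(6, 5, 4)),
              spacing = c(1, 1.25, 2.5), origin = c(2, -3, 4), modality = "CT")
  f <- file.path(dir, "ours.nii.gz")
  write_volume(v, f)
  datf <- file.path(dir, "dat.bin"); afff <- file.path(dir, "aff.bin")
  script <- file.path(dir, "rd.py")
  writeLines(c(
    "import sys, numpy as np, nibabel as nib",
    "img = nib.load(sys.argv[1])",
    "d = np.asanyarray(img.dataobj).astype('<f8')",
    "d.flatten(order='F').tofile(sys.argv[2])",
    "img.affine.astype('<f8').flatten(order='C').tofile(sys.argv[3])"), script)
  st <- system2("python", c(script, f, datf, afff))
  expect_identical(st, 0L)
  d <- readBin(datf, "double", prod(dim(v$data)))
  expect_lt(max(abs(d - as.vector(v$data))), 1e-3)
  aff <- matrix(readBin(afff, "double", 16), 4, 4, byrow = TRUE)
  A <- v$direction %*% diag(v$spacing)
  expect_lt(max(abs(aff[1:3, 1:3] - A)), 1e-4)
  expect_lt(max(abs(aff[1:3, 4] - v$origin)), 1e-4)
  # and a nibabel-written file read by us
  f2 <- file.path(dir, "theirs.nii.gz")
  script2 <- file.path(dir, "wr.py")
  writeLines(c(
    "import sys, numpy as np, nibabel as nib",
    "rng = np.random.default_rng(0)",
    "d = rng.random((7, 6, 5)).astype('float32')",
    "aff = np.array([[1.,0,0,2],[0,1,0,-3],[0,0,2.5,4],[0,0,0,1]])",
    "nib.save(nib.Nifti1Image(d, aff), sys.argv[1])",
    "d.flatten(order='F').astype('<f8').tofile(sys.argv[2])"), script2)
  st2 <- system2("python", c(script2, f2, datf))
  expect_identical(st2, 0L)
  v2 <- read_volume(f2, "MR_WATER")
  expect_identical(dim(v2$data), c(7L, 6L, 5L))
  expect_lt(max(abs(as.vector(v2$data) -
                      readBin(datf, "double", 210))), 1e-7)
  expect_equal(v2$spacing, c(1, 1, 2.5), tolerance = 1e-6)
  expect_equal(v2$origin, c(2, -3, 4), tolerance = 1e-6)
})

test_that("DICOM series import applies rescale and sorts slices", {
  dir <- withr::local_tempdir()
  nz <- 10
  arr <- array(as.integer(matrix(1024 + seq_len(8 * 6), 8, 6)), c(8, 6, nz))
  for (k in seq_len(nz)) arr[, , k] <- arr[, , k] + k
  ord <- sample(seq_len(nz))  # write files in shuffled order
  for (k in ord)
    write_test_dicom(file.path(dir, sprintf("sl%02d.dcm", which(ord == k))),
                     arr[, , k], ipp = c(0, 0, (k - 1) * 2.5),
                     uid = "1.2.3.4", slope = 1, intercept = -1024)
  v <- read_volume(dir, "CT")
  expect_identical(dim(v$data), c(8L, 6L, 10L))
  expect_equal(v$data, arr - 1024, tolerance = 1e-9)  # HU shift applied
  expect_equal(v$spacing[3], 2.5, tolerance = 1e-9)
  # mixed series rejected
  write_test_dicom(file.path(dir, "other.dcm"), arr[, , 1],
                   ipp = c(0, 0, 99), uid = "9.9.9")
  expect_error(read_volume(dir, "CT"), class = "masct_io_error")
})

test_that("resample_to: identity grid, linear midpoint, mask preservation", {
  ramp <- volume(array(rep(seq(0, 10, length.out = 11), 25), c(11, 5, 5)),
                 spacing = c(1, 1, 1), modality = "MR_WATER")
  expect_equal(resample_to(ramp, ramp)$data, ramp$data, tolerance = 1e-12)
  # sample at midpoints: shift origin by half a voxel along x
  half <- volume(array(0, c(10, 5, 5)), spacing = c(1, 1, 1),
                 origin = c(0.5, 0, 0), modality = "MR_WATER")
  out <- resample_to(ramp, half, "linear")
  expect_equal(as.vector(out$data[1, 1, 1]), 0.5, tolerance = 1e-9)
  expect_equal(as.vector(out$data[5, 3, 2]), 4.5, tolerance = 1e-9)
  # linear interpolation never overshoots
  expect_gte(min(out$data), min(ramp$data))
  expect_lte(max(out$data), max(ramp$data))
  set.seed(2)
  m <- volume(array(as.double(rbinom(250, 1, 0.4)), c(10, 5, 5)),
              modality = "MASK")
  tgt <- volume(array(0, c(7, 4, 3)), spacing = c(1.4, 1.2, 1.6),
                modality = "MASK")
  rs <- resample_to(m, tgt, "nearest")
  expect_true(all(rs$data %in% c(0, 1)))
  expect_error(resample_to(ramp, half, "cubic"))
})
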