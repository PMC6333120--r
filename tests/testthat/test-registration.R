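test_that("rigid landmark fit: identity, translation, rotation, contracts", {
  pts <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 3, 4, 8), 4, 3, byrow = TRUE)
  r0 <- rigid_from_landmarks(pts, pts)
  expect_lt(max(abs(r0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(r0$translation)), 1e-9)
  rt <- rigid_from_landmarks(pts, sweep(pts, 2, c(5, 0, 0), `+`))
  expect_lt(max(abs(rt$rotation - diag(3))), 1e-9)
  expect_equal(rt$translation, c(5, 0, 0), tolerance = 1e-9)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- t(Rz %*% t(pts)) + matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  rr <- rigid_from_landmarks(pts, moved)
  expect_lt(max(abs(rr$rotation - Rz)), 1e-6)
  # exact rigid image -> zero residual
  res <- t(rr$rotation %*% t(pts)) +
    matrix(rr$translation, 4, 3, byrow = TRUE) - moved
  expect_lt(max(abs(res)), 1e-9)
  col <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3, byrow = TRUE)
  expect_error(rigid_from_landmarks(col, col), "collinear")
  expect_error(rigid_from_landmarks(pts[1:2, ], pts[1:2, ]), "points")
})

test_that("apply_deformation: zero field, integer shift, label preservation", {
  set.seed(5)
  v <- volume(array(rnorm(10 * 10 * 6), c(10, 10, 6)), c(1, 1, 2),
              modality = "MR_WATER")
  zero <- deformation_field(array(0, c(10, 10, 6, 3)), v)
  expect_identical(apply_deformation(v, zero, "nearest")$data, v$data)
  # constant displacement of exactly one voxel spacing in x
  one <- deformation_field(array(rep(c(1, 0, 0), each = 600),
                                 c(10, 10, 6, 3)), v)
  shifted <- apply_deformation(v, one, "nearest")$data
  expect_identical(shifted[1:9, , ], v$data[2:10, , ])
  lbl <- volume(array(as.double(sample(0:4, 600, TRUE)), c(10, 10, 6)),
                c(1, 1, 2), modality = "LABELS")
  warped <- apply_deformation(lbl, deformation_field(
    array(rnorm(1800, 0, 1.5), c(10, 10, 6, 3)), v))
  expect_true(all(warped$data %in% 0:4))
  expect_error(apply_deformation(v, zero, "spline"))
})

test_that("B-spline registration: self, translation recovery, determinism", {
  s <- clean_subject(seed = 41)
  w <- s$water
  p <- registration_params(pyramid_levels = 2, iterations_per_level = c(40, 15))
  self <- bspline_register(w, w, rigid_transform(), p)
  mag <- sqrt(rowSums(matrix(self$displacements, ncol = 3)^2))
  expect_lt(mean(mag), 0.1 * min(w$spacing))    # self-registration is ~identity
  # known 4 mm translation, recovered over the body
  tr <- rigid_transform(diag(3), c(4, 0, 0))
  moved <- apply_deformation(
    w, deformation_field(array(rep(c(4, 0, 0), each = prod(dim(w$data))),
                               c(dim(w$data), 3)), w))
  fld <- bspline_register(moved, w, rigid_transform(), p)
  body <- s$labels$labels >= 2
  dx <- fld$displacements[, , , 1][body]
  expect_lt(abs(mean(dx) - 4), 1)
  # full-resolution MSE never worse than the rigid-only start
  expect_lte(attr(fld, "mse_final"), attr(fld, "mse_rigid"))
  expect_true(all(is.finite(attr(fld, "mse_levels"))))
  # determinism: identical inputs give identical fields
  fld2 <- bspline_register(moved, w, rigid_transform(), p)
  expect_identical(fld$displacements, fld2$displacements)
})

test_that("a known smooth field is recovered on the small phantom", {
  base <- clean_subject(seed = 51)
  warped <- fixture("warped_51", function() {
    cfgw <- small_phantom_cfg(
      deformation = list(amplitude_mm = 5, smoothness_mm = 7.5))
    make_subject(cfgw, seed = 51)
  })
  d <- warped$truth_field$displacements
  fx <- apply_deformation(base$water, warped$truth_field)
  fld <- bspline_register(fx, base$water, rigid_transform(),
                          registration_params())
  body <- apply_deformation(masct:::labels_as_volume(base$labels),
                            warped$truth_field)$data >= 2
  de <- fld$displacements - d
  err <- sqrt(de[, , , 1]^2 + de[, , , 2]^2 + de[, , , 3]^2)
  expect_lt(mean(err[body]), 2)
  # and the registration genuinely reduced the image mismatch
  expect_lt(attr(fld, "mse_final"), 0.8 * attr(fld, "mse_rigid"))
})

test_that("field composition matches sequential application", {
  set.seed(7)
  # smooth image: sequential warping interpolates twice, the composed field
  # once, so the two paths only agree up to the image's interpolation error
  raw <- array(rnorm(12 * 12 * 8, 100, 100), c(12, 12, 8))
  v <- volume(array(masct:::cpp_gaussian_smooth(raw, c(12L, 12L, 8L),
                                                c(2, 2, 2)), c(12, 12, 8)),
              c(2, 2, 2), modality = "MR_WATER")
  sm <- function(seed) {
    set.seed(seed)
    arr <- array(rnorm(12 * 12 * 8 * 3, 0, 0.5), c(12, 12, 8, 3))
    for (c in 1:3) arr[, , , c] <- array(
      masct:::cpp_gaussian_smooth(arr[, , , c], c(12L, 12L, 8L), c(3, 3, 3)),
      c(12, 12, 8))
    deformation_field(arr, v)
  }
  f1 <- sm(1); f2 <- sm(2)
  once <- apply_deformation(v, compose_fields(f1, f2))
  twice <- apply_deformation(apply_deformation(v, f2), f1)
  interior <- array(FALSE, c(12, 12, 8)); interior[3:10, 3:10, 3:6] <- TRUE
  expect_lt(max(abs(once$data - twice$data)[interior]), 2)
})
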