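test_that("fuzzy c-means: closed forms, symmetry, oracle and invariants", {
  x <- c(1, 4, 7, 7, 20)
  expect_equal(fuzzy_c_means(x, 1)$centers, mean(x))
  # symmetric two-cluster case: centers symmetric about 5
  r <- fuzzy_c_means(c(0, 0, 0, 10, 10, 10), 2, seed = 5)
  expect_lt(abs(r$centers[1] + r$centers[2] - 10), 1e-3)
  expect_true(all(diff(r$centers) > 0))
  expect_equal(rowSums(r$memberships), rep(1, 6), tolerance = 1e-12)
  # two-Gaussian mixture vs an independent k-means oracle on the same draw
  y <- local_seed_test(11, c(rnorm(1000, 100, 20), rnorm(1000, 500, 20)))
  km <- sort(stats::kmeans(y, centers = 2, nstart = 5)$centers)
  fc <- fuzzy_c_means(y, 2, seed = 11)
  expect_lt(max(abs(fc$centers - km)), 10)
  expect_lt(max(abs(fc$centers - c(100, 500))), 10)
  # FCM objective is non-increasing across iterations
  expect_true(all(diff(fc$objective) <= 1e-8 * fc$objective[1]))
  # degenerate input contract
  expect_error(fuzzy_c_means(c(1, 1, 2), 3), "degenerate")
})

test_that("landmark detection finds generative modes and rejects constants", {
  # air background ~ N(5, 2); fat ring ~ N(50, 10) dark tissue;
  # muscle ~ N(500, 20) bright tissue
  local_seed_test(3, {
    arr <- array(0, c(40, 40, 10))
    musc <- array(FALSE, dim(arr)); musc[14:27, 14:27, ] <- TRUE
    fatr <- array(FALSE, dim(arr)); fatr[6:35, 6:35, ] <- TRUE
    fatr <- fatr & !musc
    arr[musc] <- rnorm(sum(musc), 500, 20)
    arr[fatr] <- abs(rnorm(sum(fatr), 50, 10))
    arr[!musc & !fatr] <- abs(rnorm(sum(!musc & !fatr), 5, 2))
    v <- volume(arr, modality = "MR_WATER")
    lm <- detect_landmarks(v)
    bin <- (quantile(arr, 0.999) - quantile(arr, 0.001)) / 256
    expect_lt(abs(lm$dark_mode - 50), 3 * bin + 5)
    expect_lt(abs(lm$bright_mode - 500), 3 * bin + 5)
    expect_true(lm$valley > lm$dark_mode && lm$valley < lm$bright_mode)
  })
  expect_error(detect_landmarks(volume(array(7, c(8, 8, 8)),
                                       modality = "MR_WATER")), "degenerate")
})

test_that("standardize maps landmarks exactly and is monotone", {
  sc <- standard_scale()
  lm <- tissue_landmarks(120, 300, 520)
  mk <- function(vals) volume(array(vals, c(length(vals), 1, 1)),
                              modality = "MR_WATER")
  at <- function(x) standardize(mk(rep(x, 4)), lm, sc)$data[1, 1, 1]
  expect_equal(at(300), sc$s_valley)
  expect_equal(at(120), sc$s_dark)
  expect_equal(at(520), sc$s_bright)
  expect_equal(at(210), (sc$s_dark + sc$s_valley) / 2)  # segment linearity
  set.seed(4)
  xs <- sort(runif(50, 0, 900))
  ys <- standardize(mk(xs), lm, sc)$data[, 1, 1]
  expect_true(all(diff(ys) >= 0))                        # monotone
  expect_true(all(ys >= 0 & ys <= sc$s_max))             # clamped
  expect_error(standard_scale(s_dark = 500, s_valley = 100), "scale")
})

test_that("standardization is a fixed point once landmarks match the scale", {
  s <- small_subject()
  cfg <- fast_cfg()
  suppressWarnings({
    bc <- correct_bias(s$water, max_iter = 5)
    lm <- detect_landmarks(bc$corrected)
    std <- standardize(bc$corrected, lm, standard_scale())
    lm2 <- detect_landmarks(std)
  })
  fg <- as.vector(std$data)
  fg <- fg[fg > background_threshold(fg)]
  bin <- (quantile(fg, 0.999) - quantile(fg, 0.001)) / 256
  expect_lt(abs(lm2$dark_mode - 100), bin + 1e-9)
  expect_lt(abs(lm2$bright_mode - 1000), bin + 1e-9)
})

test_that("fat enhancement evaluates the blend exactly", {
  mk <- function(x, mod) volume(array(x, c(3, 3, 3)), modality = mod)
  w <- mk(120, "MR_WATER"); f <- mk(60, "MR_FAT")
  expect_equal(fat_enhance(w, f, 0.5)$data[1], 100)
  expect_equal(fat_enhance(mk(0, "MR_WATER"), mk(90, "MR_FAT"), 0.5)$data[1], 30)
  expect_equal(fat_enhance(w, f, 0)$data, w$data)
  expect_identical(fat_enhance(w, f)$modality, "MR_WFE")
  # convex combination bound on random volumes
  set.seed(6)
  wr <- volume(array(runif(200, 0, 1000), c(10, 10, 2)), modality = "MR_WATER")
  fr <- volume(array(runif(200, 0, 1000), c(10, 10, 2)), modality = "MR_FAT")
  out <- fat_enhance(wr, fr, 0.7)$data
  expect_true(all(out >= pmin(wr$data, fr$data) - 1e-9))
  expect_true(all(out <= pmax(wr$data, fr$data) + 1e-9))
  expect_error(fat_enhance(w, f, -1), "alpha")
  bad <- volume(array(60, c(4, 4, 4)), modality = "MR_FAT")
  expect_error(fat_enhance(w, bad), "grid")
})

test_that("bias correction: identity on unbiased data, CoV reduction on gain", {
  # two-tissue slices (stripes along z so both tissues span the gain axis)
  d <- c(32, 48, 24)
  tis <- array(rep(rep(c(200, 600), each = 4, length.out = d[3]),
                   each = d[1] * d[2]), d)
  local_seed_test(8, {
    clean <- tis * (1 + array(rnorm(prod(d), 0, 0.01), d))
    v0 <- volume(clean, modality = "MR_WATER")
    b0 <- correct_bias(v0)
    expect_lt(max(abs(b0$bias$field - 1)), 0.02)          # no-bias identity
    expect_lt(max(abs(b0$corrected$data - clean) / clean), 0.03)
    # 30% linear gain across the in-slice y axis
    gain <- array(rep(rep(1 + 0.3 * seq(0, 1, length.out = d[2]),
                          each = d[1]), d[3]), d)
    vb <- volume(clean * gain, modality = "MR_WATER")
    bc <- correct_bias(vb, k = 2)   # two-tissue input -> two intensity classes
    cov <- function(img, t) sd(img[tis == t]) / mean(img[tis == t])
    for (t in c(200, 600)) {
      expect_lt(cov(bc$corrected$data, t), 0.5 * cov(vb$data, t))
    }
    expect_true(all(bc$corrected$data >= 0))              # positivity
    expect_true(all(bc$bias$field > 0))
  })
})
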