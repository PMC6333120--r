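# independent naive oracle: GRE by direct loops under the stated conventions
naive_gre <- function(tgt, atl, v, r, bins, eps, off = c(0, 0)) {
  d <- dim(tgt)
  diffs <- c()
  for (q in (v[2] - r):(v[2] + r)) {
    for (p in (v[1] - r):(v[1] + r)) {
      pa <- p + off[1]; qa <- q + off[2]
      if (p < 1 || p > d[1] || q < 1 || q > d[2]) next
      if (pa < 1 || pa > d[1] || qa < 1 || qa > d[2]) next
      diffs <- c(diffs, tgt[p, q, v[3]] - atl[pa, qa, v[3]])
    }
  }
  m <- sum(diffs) / length(diffs)
  va <- sum((diffs - m)^2) / length(diffs)
  rg <- range(diffs)
  if (diff(rg) < 1e-300) {
    ent <- 0
  } else {
    wdt <- diff(rg) / bins
    cnt <- rep(0, bins)
    for (x in diffs) {
      b <- min(floor((x - rg[1]) / wdt), bins - 1)
      cnt[b + 1] <- cnt[b + 1] + 1
    }
    pr <- cnt[cnt > 0] / length(diffs)
    ent <- -sum(pr * log2(pr))
  }
  ((m^2 + eps) * (va + eps) * (ent + eps))^(1 / 3)
}

test_that("patch statistics match hand computations", {
  z <- patch_stats(rep(0, 25))
  expect_equal(unlist(z), c(m2 = 0, var = 0, ent = 0))
  cst <- patch_stats(rep(10, 25))
  expect_equal(unlist(cst), c(m2 = 100, var = 0, ent = 0))
  s <- patch_stats(c(1, 2, 3, 4), entropy_bins = 4)
  expect_equal(s$m2, 6.25)
  expect_equal(s$var, 1.25)
  expect_equal(s$ent, 2.0)
  expect_error(patch_stats(numeric(0)), "empty")
})

test_that("gre_at: identical images floor at epsilon; hand value 2.5", {
  tv <- textured_volume()
  p <- gre_params()
  expect_equal(gre_at(tv, tv, c(30, 30, 2), p), p$epsilon, tolerance = 1e-9)
  # the [1,2,3,4] difference patch in the epsilon->0 limit
  a <- volume(array(0, c(4, 1, 1)), modality = "MR_WFE")
  b <- volume(array(-(1:4), c(4, 1, 1)), modality = "MR_WFE")
  tiny <- gre_params(patch_radius_vox = 2, entropy_bins = 4, epsilon = 1e-12)
  expect_equal(gre_at(a, b, c(2, 1, 1), tiny), 2.5, tolerance = 1e-6)
})

test_that("gre_at agrees with the brute-force oracle at random voxels", {
  tv <- textured_volume(seed = 9)
  av <- textured_volume(seed = 10)
  p <- gre_params()
  set.seed(12)
  for (i in 1:100) {
    v <- c(sample(64, 1), sample(64, 1), sample(3, 1))
    expect_equal(gre_at(tv, av, v, p),
                 naive_gre(tv$data, av$data, v, p$patch_radius_vox,
                           p$entropy_bins, p$epsilon),
                 tolerance = 1e-9)
  }
})

test_that("neighborhood search: offset census, degenerate radius, recovery", {
  offs <- search_offsets(c(1, 1), 2)
  expect_identical(nrow(offs), 13L)       # integer pairs with i^2+j^2 <= 4
  expect_identical(as.integer(offs[1, ]), c(0L, 0L))  # sorted by magnitude
  expect_identical(nrow(search_offsets(c(1, 1), 0)), 1L)
  # anisotropic in-plane spacing changes the census
  expect_identical(nrow(search_offsets(c(2, 1), 2)), 7L)
  tv <- textured_volume(seed = 13)
  p0 <- gre_params(search_radius_mm = 0)
  ns0 <- neighborhood_search(tv, tv, c(20, 20, 2), p0)
  expect_equal(ns0$gre_min, gre_at(tv, tv, c(20, 20, 2), p0))
  # atlas shifted by one in-plane voxel is found at interior voxels
  sh <- tv$data * 0
  sh[2:64, , ] <- tv$data[1:63, , ]
  atl <- volume(sh, tv$spacing, modality = "MR_WFE")
  p <- gre_params()
  hit <- 0; tot <- 0
  set.seed(14)
  for (i in 1:60) {
    v <- c(sample(10:55, 1), sample(10:55, 1), 2)
    ns <- neighborhood_search(tv, atl, v, p)
    tot <- tot + 1
    if (identical(ns$best_offset, c(1L, 0L))) hit <- hit + 1
  }
  expect_gte(hit / tot, 0.95)
})

test_that("fuse: weighted-average arithmetic, identity, convexity, masks", {
  # two atlases, CT 100 and 200 HU, gre 1 and 3 -> 125 HU
  n <- c(9, 9, 3)
  tgt <- textured_volume(n, seed = 20)
  mk_ct <- function(x) volume(array(x, n), tgt$spacing, modality = "CT")
  # force known GREs by constructing constant difference maps: a constant
  # nonzero diff c has m2 = c^2, var = ent = 0 -> GRE ~ (c^2 eps^2)^(1/3).
  # Instead check the arithmetic directly through the R reference path and
  # the exported fuse() on a single-voxel mask equivalent: use atlases whose
  # gre we measure, then verify the weighted mean.
  a1 <- textured_volume(n, seed = 21)
  a2 <- textured_volume(n, seed = 22)
  p <- gre_params()
  fz <- fuse(list(mr = list(a1, a2), ct = list(mk_ct(100), mk_ct(200))), tgt, p)
  v <- c(5, 5, 2)
  g1 <- fz$gre[[1]]$gre_min[5, 5, 2]; g2 <- fz$gre[[2]]$gre_min[5, 5, 2]
  expect_equal(fz$sct$data[5, 5, 2],
               (100 / g1 + 200 / g2) / (1 / g1 + 1 / g2), tolerance = 1e-9)
  expect_equal((1 * 100 + (1 / 3) * 200) / (1 + 1 / 3), 125) # stated example
  # single-pair atlas: sct equals that pair's (offset-corrected) CT
  fz1 <- fuse(list(mr = list(tgt), ct = list(mk_ct(150))), tgt, p)
  expect_equal(max(abs(fz1$sct$data - 150)), 0)
  # convexity of the fused value
  ct1 <- volume(array(runif(prod(n), -500, 1500), n), tgt$spacing,
                modality = "CT")
  ct2 <- volume(array(runif(prod(n), -500, 1500), n), tgt$spacing,
                modality = "CT")
  fz2 <- fuse(list(mr = list(a1, a2), ct = list(ct1, ct2)), tgt, p)
  for (k in 1:3) for (j in 1:9) for (i in 1:9) {
    o1 <- c(fz2$gre[[1]]$best_i[i, j, k], fz2$gre[[1]]$best_j[i, j, k])
    o2 <- c(fz2$gre[[2]]$best_i[i, j, k], fz2$gre[[2]]$best_j[i, j, k])
    vals <- c(ct1$data[min(max(i + o1[1], 1), 9), min(max(j + o1[2], 1), 9), k],
              ct2$data[min(max(i + o2[1], 1), 9), min(max(j + o2[2], 1), 9), k])
    expect_gte(fz2$sct$data[i, j, k], min(vals) - 1e-9)
    expect_lte(fz2$sct$data[i, j, k], max(vals) + 1e-9)
  }
  # permutation invariance
  fz3 <- fuse(list(mr = list(a2, a1), ct = list(ct2, ct1)), tgt, p)
  expect_identical(fz3$sct$data, fz2$sct$data)
  # body mask: outside voxels take -1000
  msk <- volume(array(0, n), tgt$spacing, modality = "MR_WFE")
  msk$data[3:7, 3:7, ] <- 1
  msk$modality <- "MASK"
  fzm <- fuse(list(mr = list(a1), ct = list(ct1)), tgt,
              gre_params(body_mask = msk))
  expect_true(all(fzm$sct$data[msk$data == 0] == -1000))
  expect_error(fuse(list(mr = list(), ct = list()), tgt, p), "empty")
})

test_that("vectorized fusion equals the naive per-voxel loop on a crop", {
  n <- c(16, 16, 4)
  tgt <- textured_volume(n, seed = 30)
  a1 <- textured_volume(n, seed = 31)
  a2 <- textured_volume(n, seed = 32)
  set.seed(33)
  c1 <- volume(array(rnorm(prod(n), 100, 300), n), tgt$spacing, modality = "CT")
  c2 <- volume(array(rnorm(prod(n), 0, 300), n), tgt$spacing, modality = "CT")
  p <- gre_params()
  fz <- fuse(list(mr = list(a1, a2), ct = list(c1, c2)), tgt, p)
  for (t in 1:50) {
    v <- c(sample(16, 1), sample(16, 1), sample(4, 1))
    w <- numeric(2); ctv <- numeric(2)
    for (a in 1:2) {
      am <- list(a1, a2)[[a]]; ac <- list(c1, c2)[[a]]
      ns <- neighborhood_search(tgt, am, v, p)
      w[a] <- 1 / ns$gre_min
      iv <- min(max(v[1] + ns$best_offset[1], 1), 16)
      jv <- min(max(v[2] + ns$best_offset[2], 1), 16)
      ctv[a] <- ac$data[iv, jv, v[3]]
    }
    expect_equal(fz$sct$data[v[1], v[2], v[3]], sum(w * ctv) / sum(w),
                 tolerance = 1e-6)
  }
})

test_that("self-atlas dominance: an exact MR match controls the fusion", {
  n <- c(24, 24, 4)
  tgt <- textured_volume(n, seed = 40)
  own_ct <- volume(array(rnorm(prod(n), 200, 400), n), tgt$spacing,
                   modality = "CT")
  others_mr <- lapply(41:44, function(s) textured_volume(n, seed = s))
  others_ct <- lapply(45:48, function(s) {
    set.seed(s); volume(array(rnorm(prod(n), 0, 400), n), tgt$spacing,
                        modality = "CT")
  })
  fz <- fuse(list(mr = c(list(tgt), others_mr),
                  ct = c(list(own_ct), others_ct)), tgt, gre_params())
  expect_lt(max(abs(fz$sct$data - own_ct$data)), 1)
})
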