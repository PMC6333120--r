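small_cohort <- function() {
  fixture("small_cohort3", function() make_cohort(small_phantom_cfg(), 3, 17))
}

test_that("build_atlas assembles one grid-consistent pair per subject", {
  a <- fixture("small_atlas3", function()
    suppressWarnings(build_atlas(small_cohort(), fast_cfg())))
  expect_s3_class(a, "masct_atlas")
  expect_length(a$pairs, 3)
  for (p in a$pairs) {
    expect_true(masct:::same_grid(p$ct_reg, p$mr_wfe))
    expect_lte(max(p$mr_wfe$data), a$standard_scale$s_max)
  }
  expect_identical(vapply(a$pairs, function(p) p$subject_id, character(1)),
                   c("phantom01", "phantom02", "phantom03"))
})

test_that("a self-aligned subject round-trips its CT through registration", {
  s <- clean_subject(seed = 61)
  s$id <- "clean61"
  pair <- suppressWarnings(build_atlas_pair(s, fast_cfg()))
  body <- body_mask(s$ct)
  expect_lt(mae(s$ct, pair$ct_reg, body), 10)
})

test_that("subjects with missing landmarks are skipped with a warning", {
  cohort <- small_cohort()
  broken <- cohort
  broken[[2]]$landmarks <- NULL
  expect_warning(a <- build_atlas(broken, fast_cfg()), "skipped")
  expect_length(a$pairs, 2)
  nolm <- lapply(cohort, function(s) { s$landmarks <- NULL; s })
  expect_error(suppressWarnings(build_atlas(nolm, fast_cfg())), "0 pairs")
})

test_that("atlas serialization round-trips through a directory", {
  a <- fixture("small_atlas3", function()
    suppressWarnings(build_atlas(small_cohort(), fast_cfg())))
  a2pairs <- a; a2pairs$pairs <- a$pairs[1:2]
  dir <- withr::local_tempdir()
  save_atlas(a2pairs, dir)
  b <- load_atlas(dir)
  expect_length(b$pairs, 2)
  for (i in 1:2) {
    expect_lt(max(abs(b$pairs[[i]]$ct_reg$data - a2pairs$pairs[[i]]$ct_reg$data)),
              1e-3)
    expect_lt(max(abs(b$pairs[[i]]$landmarks - a2pairs$pairs[[i]]$landmarks)),
              1e-9)
  }
  expect_equal(b$build_config$registration$grid_spacing_mm,
               a2pairs$build_config$registration$grid_spacing_mm)
  expect_equal(unclass(b$standard_scale), unclass(a2pairs$standard_scale))
  # schema-version and missing-manifest contracts
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                           simplifyVector = FALSE)
  mf$schema_version <- 99
  writeLines(jsonlite::toJSON(mf, auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  expect_error(load_atlas(dir), "schema version")
  empty <- withr::local_tempdir()
  expect_error(load_atlas(empty), class = "masct_io_error")
})

test_that("propagation puts every pair on the target grid, self-match is tight", {
  a <- fixture("small_atlas3", function()
    suppressWarnings(build_atlas(small_cohort(), fast_cfg())))
  cohort <- small_cohort()
  cfg <- fast_cfg()
  suppressWarnings(tgt <- preprocess_mr(cohort[[1]]$water, cohort[[1]]$fat, cfg))
  prop <- propagate_atlas(a, tgt$wfe, cohort[[1]]$landmarks$mr,
                          masct:::config_regparams(cfg))
  expect_length(prop$entries, 3)
  rng <- diff(range(tgt$wfe$data))
  for (i in seq_along(prop$entries)) {
    e <- prop$entries[[i]]
    expect_true(masct:::same_grid(e$mr_wfe, tgt$wfe))
    # warped CT stays inside the input HU range plus the -1000 fill
    # (linear interpolation cannot overshoot)
    expect_gte(min(e$ct_reg$data), min(a$pairs[[i]]$ct_reg$data, -1000) - 1e-6)
    expect_lte(max(e$ct_reg$data), max(a$pairs[[i]]$ct_reg$data) + 1e-6)
  }
  # the target's own pair must match itself almost perfectly
  own <- prop$entries[[1]]
  mse_self <- mean((own$mr_wfe$data - tgt$wfe$data)^2)
  expect_lt(mse_self, (0.01 * rng)^2)
  # registration helped: per-pair MSE strictly below rigid-only MSE
  for (e in prop$entries[2:3]) {
    expect_lt(attr(e$field, "mse_final"), attr(e$field, "mse_rigid"))
  }
})
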