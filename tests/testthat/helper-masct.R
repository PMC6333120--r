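# Shared fixtures, built lazily in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small phantom configuration used by most module tests
small_phantom_cfg <- function(...) {
  phantom_config(grid = c(48, 48, 32), spacing = c(1, 1, 2), ...)
}

# pipeline configuration scaled down for small-grid tests
fast_cfg <- function(...) {
  masct_config(registration = list(pyramid_levels = 2,
                                   iterations_per_level = c(40, 10)),
               bias = list(max_iter = 5), ...)
}

small_subject <- function(seed = 21) {
  fixture(paste0("small_subject_", seed),
          function() make_subject(small_phantom_cfg(), seed = seed))
}

# noise- and bias-free subject (pristine rendering of the warped template)
clean_subject <- function(seed = 31, amplitude = 0) {
  fixture(paste0("clean_subject_", seed, "_", amplitude), function() {
    zero_sd <- function(m) { m$sd[] <- 0; m }
    cfgc <- small_phantom_cfg(
      deformation = list(amplitude_mm = amplitude, smoothness_mm = 7.5),
      bias_amplitude = 0, noise = list(model = "gaussian", sigma = 0))
    cfgc$hu <- zero_sd(cfgc$hu)
    cfgc$mr_water <- zero_sd(cfgc$mr_water)
    cfgc$mr_fat <- zero_sd(cfgc$mr_fat)
    make_subject(cfgc, seed = seed)
  })
}

# smooth textured slice pair (informative patches for GRE tests)
textured_volume <- function(n = c(64, 64, 3), seed = 9, sigma = 2) {
  local_seed_test(seed, {
    raw <- array(rnorm(prod(n), 500, 120), n)
    sm <- masct:::cpp_gaussian_smooth(raw, as.integer(n), c(sigma, sigma, 0))
    volume(array(sm, n), c(1, 1, 2.5), modality = "MR_WFE")
  })
}

local_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# minimal explicit-VR little-endian single-frame DICOM writer (fixture only)
write_test_dicom <- function(path, img, ipp, uid, ps = c(1, 1),
                             iop = c(1, 0, 0, 0, 1, 0),
                             slope = 1, intercept = -1024) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  elem <- function(group, el, vr, payload) {
    writeBin(as.integer(c(group, el)), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW")) {
      writeBin(raw(2), con)
      writeBin(length(payload), con, size = 4, endian = "little")
    } else {
      writeBin(length(payload), con, size = 2, endian = "little")
    }
    writeBin(payload, con)
  }
  ds <- function(x) {
    r <- charToRaw(paste(format(x, trim = TRUE), collapse = "\\"))
    if (length(r) %% 2) c(r, charToRaw(" ")) else r
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  ui <- function(x) {
    r <- charToRaw(x)
    if (length(r) %% 2) c(r, raw(1)) else r
  }
  elem(0x0020, 0x000E, "UI", ui(uid))
  elem(0x0020, 0x0032, "DS", ds(ipp))
  elem(0x0020, 0x0037, "DS", ds(iop))
  elem(0x0028, 0x0010, "US", us(ncol(img)))   # rows
  elem(0x0028, 0x0011, "US", us(nrow(img)))   # columns
  elem(0x0028, 0x0030, "DS", ds(ps))
  elem(0x0028, 0x0100, "US", us(16))
  elem(0x0028, 0x0103, "US", us(1))
  elem(0x0028, 0x1052, "DS", ds(intercept))
  elem(0x0028, 0x1053, "DS", ds(slope))
  px <- writeBin(as.integer(as.vector(img)), raw(), size = 2,
                 endian = "little")
  elem(0x7FE0, 0x0010, "OW", px)
  invisible(path)
}

expect_volume_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a$data - b$data)), tol)
  expect_lt(max(abs(a$spacing - b$spacing)), 1e-6)
  expect_lt(max(abs(a$origin - b$origin)), 1e-6)
  expect_lt(max(abs(a$direction - b$direction)), 1e-6)
}
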