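#' Default pipeline configuration
#'
#' Full parameter tree used by atlas building, propagation, fusion and
#' evaluation. Values from a JSON config file and per-call overrides are
#' merged over these defaults with [merge_config()].
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return a named list of class `masct_config`.
#' @export
masct_config <- function(...) {
  base <- list(
    seed = 1,
    alpha = 0.5,                 # fat-enhancement blend weight
    hist_bins = 256,
    smooth_window = 5,
    air_threshold_hu = -250,
    crop_slices = 0,             # end slices dropped per volume
    scale = list(s_dark = 100, s_valley = 500, s_bright = 1000, s_max = 1200),
    bias = list(basis_order = 2, k = 3, max_iter = 20, tol = 1e-4),
    fcm = list(fuzzifier = 2, tol = 1e-4, max_iter = 200),
    registration = list(grid_spacing_mm = 20, pyramid_levels = 3,
                        iterations_per_level = c(100, 60, 25),
                        subsample = c(1, 1, 1),
                        regularization_weight = 0.1),
    gre = list(patch_radius_vox = 2, entropy_bins = 32, epsilon = 1e-6,
               search_radius_mm = 2.0)
  )
  cfg <- merge_config(base, list(...))
  class(cfg) <- "masct_config"
  cfg
}

#' Merge configuration trees
#'
#' Recursive merge: values in `override` replace values in `base`; nested
#' lists are merged element-wise.
#'
#' @param base,override named lists.
#' @return merged list.
#' @export
merge_config <- function(base, override) {
  if (length(override) == 0) return(base)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

config_scale <- function(cfg) do.call(standard_scale, cfg$scale)

config_regparams <- function(cfg) do.call(registration_params, cfg$registration)

config_greparams <- function(cfg, body_mask = NULL) {
  a <- cfg$gre
  gre_params(a$patch_radius_vox, a$entropy_bins, a$epsilon,
             a$search_radius_mm, body_mask)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
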