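# Atlas construction and propagation. An atlas pair stores a subject's
# planning CT deformed onto its own MR grid (ct_reg) together with the
# standardized fat-enhanced water image (mr_wfe) and the subject's physical
# landmark points used for rigid initialization.

#' Run the full MR conditioning chain on a water/fat pair
#'
#' Bias correction, landmark detection, histogram standardization of both
#' series, then the fat-enhanced blend.
#'
#' @param water,fat MR `masct_volume`s (`MR_WATER`, `MR_FAT`) on one grid.
#' @param cfg [masct_config()].
#' @return list with `water_std`, `fat_std`, `wfe`, `landmarks_water`,
#'   `landmarks_fat`.
#' @export
preprocess_mr <- function(water, fat, cfg = masct_config()) {
  scale <- config_scale(cfg)
  chain <- function(v) {
    bc <- correct_bias(v, cfg$bias$basis_order, cfg$bias$k, cfg$bias$tol,
                       cfg$bias$max_iter, cfg$seed)
    lm <- detect_landmarks(bc$corrected, cfg$seed, cfg$hist_bins,
                           cfg$smooth_window, cfg$fcm)
    list(std = standardize(bc$corrected, lm, scale), landmarks = lm)
  }
  w <- chain(water)
  f <- chain(fat)
  list(water_std = w$std, fat_std = f$std,
       wfe = fat_enhance(w$std, f$std, cfg$alpha),
       landmarks_water = w$landmarks, landmarks_fat = f$landmarks)
}

crop_end_slices <- function(v, k) {
  if (k <= 0) return(v)
  d <- dim(v$data)
  if (2 * k >= d[3]) stop("crop_slices leaves no slices", call. = FALSE)
  keep <- (k + 1):(d[3] - k)
  orig <- v$origin + v$direction %*% (c(0, 0, k * v$spacing[3]))
  volume(v$data[, , keep, drop = FALSE], v$spacing, as.vector(orig),
         v$direction, v$modality)
}

new_atlas_pair <- function(ct_reg, mr_wfe, landmarks, subject_id, provenance) {
  stopifnot(same_grid(ct_reg, mr_wfe))
  structure(list(ct_reg = ct_reg, mr_wfe = mr_wfe, landmarks = landmarks,
                 subject_id = subject_id, provenance = provenance),
            class = "masct_atlas_pair")
}

#' Build a co-registered CT-MR atlas
#'
#' Per subject: the MR chain ([preprocess_mr()]) conditions water and fat and
#' produces the fat-enhanced water image; the CT chain ([condition_ct()])
#' produces the bone-/fat-suppressed standardized CT; the conditioned CT is
#' registered (landmark rigid + B-spline, MSE) onto the standardized water
#' image; and the resulting field is applied to the ORIGINAL planning CT to
#' obtain `ct_reg` on the MR grid. Subjects whose processing fails (e.g.
#' missing landmarks) are skipped with a warning.
#'
#' @param subjects list; each element needs `id`, `ct`, `water`, `fat` and
#'   `landmarks` (list with `mr` and `ct`: n x 3 matrices of matched
#'   physical points, n >= 3).
#' @param cfg [masct_config()].
#' @return object of class `masct_atlas` with `pairs`, `standard_scale` and
#'   `build_config`.
#' @export
build_atlas <- function(subjects, cfg = masct_config()) {
  pairs <- list()
  for (s in subjects) {
    pair <- tryCatch(build_atlas_pair(s, cfg), error = function(e) {
      warning(sprintf("subject '%s' skipped: %s",
                      s$id %||% "?", conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(pair)) pairs[[length(pairs) + 1L]] <- pair
  }
  if (length(pairs) == 0) stop("atlas build produced 0 pairs", call. = FALSE)
  ids <- vapply(pairs, function(p) p$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  structure(list(pairs = pairs, standard_scale = config_scale(cfg),
                 build_config = unclass(cfg)),
            class = "masct_atlas")
}

#' Build one atlas pair (single subject)
#' @param s subject (see [build_atlas()]).
#' @param cfg [masct_config()].
#' @return a `masct_atlas_pair`.
#' @export
build_atlas_pair <- function(s, cfg = masct_config()) {
  if (is.null(s$landmarks) || is.null(s$landmarks$mr) || is.null(s$landmarks$ct))
    stop("missing landmarks")
  if (is.null(s$ct) || is.null(s$water) || is.null(s$fat))
    stop("subject must provide ct, water and fat volumes")
  ct <- crop_end_slices(s$ct, cfg$crop_slices)
  water <- crop_end_slices(s$water, cfg$crop_slices)
  fat <- crop_end_slices(s$fat, cfg$crop_slices)
  mr <- preprocess_mr(water, fat, cfg)
  ctc <- condition_ct(ct, config_scale(cfg), cfg$air_threshold_hu,
                      cfg$fcm, cfg$seed)
  ct_on_mr <- if (same_grid(ctc$ct_sbsfs, mr$water_std)) ctc$ct_sbsfs
              else resample_to(ctc$ct_sbsfs, mr$water_std, "linear")
  init <- rigid_from_landmarks(as.matrix(s$landmarks$mr),
                               as.matrix(s$landmarks$ct))
  field <- bspline_register(mr$water_std, ct_on_mr, init,
                            config_regparams(cfg))
  ct_reg <- apply_deformation(ct, field, "linear")
  new_atlas_pair(ct_reg, mr$wfe, as.matrix(s$landmarks$mr), s$id,
                 list(package_version = as.character(packageVersion("masct")),
                      config = unclass(cfg)))
}

ATLAS_SCHEMA_VERSION <- 1L

#' Save an atlas directory
#'
#' Layout: `manifest.json` plus `<id>_ctreg.nii.gz` / `<id>_mrwfe.nii.gz`
#' per pair. `load_atlas(save_atlas(a))` round-trips data to float32 and the
#' configuration exactly.
#'
#' @param a `masct_atlas`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_atlas <- function(a, dir) {
  stopifnot(inherits(a, "masct_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(a$pairs, function(p) {
    ctf <- sprintf("%s_ctreg.nii.gz", p$subject_id)
    mrf <- sprintf("%s_mrwfe.nii.gz", p$subject_id)
    write_volume(p$ct_reg, file.path(dir, ctf))
    write_volume(p$mr_wfe, file.path(dir, mrf))
    list(id = p$subject_id, ct_reg = ctf, mr_wfe = mrf,
         landmarks = as.matrix(p$landmarks), provenance = p$provenance)
  })
  manifest <- list(schema_version = ATLAS_SCHEMA_VERSION,
                   standard_scale = unclass(a$standard_scale),
                   build_config = a$build_config,
                   subjects = subjects)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load an atlas directory written by [save_atlas()]
#' @param dir atlas directory.
#' @return a `masct_atlas`.
#' @export
load_atlas <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    io_stop("not an atlas directory (missing manifest.json): %s", dir)
  manifest <- tryCatch(jsonlite::fromJSON(mf, simplifyVector = FALSE),
                       error = function(e)
                         io_stop("corrupt atlas manifest: %s",
                                 conditionMessage(e)))
  if (!identical(as.integer(manifest$schema_version), ATLAS_SCHEMA_VERSION))
    stop(sprintf("unsupported atlas schema version: %s",
                 manifest$schema_version), call. = FALSE)
  scale <- do.call(standard_scale, manifest$standard_scale)
  # re-parse with vector simplification for the config tree only, so numeric
  # vectors (e.g. iterations per level) come back as vectors, not lists
  cfg <- jsonlite::fromJSON(mf, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)$build_config
  pairs <- lapply(manifest$subjects, function(s) {
    lm <- do.call(rbind, lapply(s$landmarks, unlist))
    new_atlas_pair(read_volume(file.path(dir, s$ct_reg), "CT"),
                   read_volume(file.path(dir, s$mr_wfe), "MR_WFE"),
                   lm, s$id, s$provenance)
  })
  structure(list(pairs = pairs, standard_scale = scale, build_config = cfg),
            class = "masct_atlas")
}

#' Propagate an atlas onto a new subject's MR
#'
#' For each atlas pair, the pair's fat-enhanced water image is registered
#' (landmark rigid + B-spline) onto the target's, and the resulting field is
#' applied to both the pair's MR and its `ct_reg`, yielding one propagated
#' entry per pair on the target grid.
#'
#' @param a `masct_atlas`.
#' @param target_mr_wfe target fat-enhanced water image, preprocessed with
#'   the identical MR chain and the atlas's standard scale.
#' @param target_landmarks n x 3 matrix of the target's physical landmark
#'   points (matched to the atlas pairs' landmarks).
#' @param params [registration_params()] (defaults from the atlas build
#'   config).
#' @return object of class `masct_propagated` with one entry per pair
#'   (`id`, `mr_wfe`, `ct_reg`, `field`).
#' @export
propagate_atlas <- function(a, target_mr_wfe, target_landmarks,
                            params = NULL) {
  stopifnot(inherits(a, "masct_atlas"))
  if (target_mr_wfe$modality != "MR_WFE")
    stop("target must be an MR_WFE volume", call. = FALSE)
  if (max(target_mr_wfe$data) > a$standard_scale$s_max + 1e-6)
    stop("target intensities exceed the atlas standard scale", call. = FALSE)
  if (is.null(params))
    params <- do.call(registration_params,
                      a$build_config$registration %||% list())
  entries <- lapply(a$pairs, function(p) {
    init <- rigid_from_landmarks(as.matrix(target_landmarks),
                                 as.matrix(p$landmarks))
    field <- bspline_register(target_mr_wfe, p$mr_wfe, init, params)
    list(id = p$subject_id,
         mr_wfe = apply_deformation(p$mr_wfe, field, "linear"),
         ct_reg = apply_deformation(p$ct_reg, field, "linear"),
         field = field)
  })
  structure(list(entries = entries, target_geom = geom_of(target_mr_wfe)),
            class = "masct_propagated")
}

#' End-to-end synthetic CT for a new subject
#'
#' Preprocesses the target water/fat pair with the atlas's configuration,
#' propagates every atlas pair, and fuses with 1/GRE weighting.
#'
#' @param a `masct_atlas`.
#' @param water,fat target MR `masct_volume`s.
#' @param landmarks target physical landmark points (n x 3).
#' @param body_mask optional mask restricting fusion (e.g. from
#'   [body_mask()] on a reference CT, or a phantom's ground truth).
#' @param cfg configuration override; defaults to the atlas build config.
#' @return list with `sct`, `prop` (propagated atlas), `gre`, `target`
#'   (preprocessed target images).
#' @export
synthesize_sct <- function(a, water, fat, landmarks, body_mask = NULL,
                           cfg = NULL) {
  if (is.null(cfg)) cfg <- do.call(masct_config, a$build_config)
  water <- crop_end_slices(water, cfg$crop_slices)
  fat <- crop_end_slices(fat, cfg$crop_slices)
  target <- preprocess_mr(water, fat, cfg)
  prop <- propagate_atlas(a, target$wfe, landmarks, config_regparams(cfg))
  fz <- fuse(prop, target$wfe, config_greparams(cfg, body_mask))
  list(sct = fz$sct, prop = prop, gre = fz$gre, target = target)
}
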