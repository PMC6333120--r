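# CT conditioning: air removal, FCM tissue classification, bone suppression
# and CT-to-MR intensity standardization, producing the bone- and
# fat-suppressed standardized CT whose contrast mimics the standardized
# water-only MR (the registration target).

#' Air mask of a CT volume
#'
#' Air is every voxel strictly below the HU threshold (default -250 HU).
#'
#' @param ct CT `masct_volume` in Hounsfield units.
#' @param threshold_hu threshold; strict `<` comparison.
#' @return `masct_volume` mask (1 = air).
#' @export
mask_air <- function(ct, threshold_hu = -250) {
  if (ct$modality != "CT") stop("`ct` must be a CT volume", call. = FALSE)
  m <- array(as.double(ct$data < threshold_hu), dim(ct$data))
  volume(m, ct$spacing, ct$origin, ct$direction, "MASK")
}

#' CT tissue cluster centers
#' @param fat_center,muscle_center,bone_center HU centers with
#'   `-250 < fat < muscle < bone`.
#' @return object of class `masct_ct_centers`.
#' @export
ct_cluster_centers <- function(fat_center, muscle_center, bone_center) {
  cc <- structure(list(fat_center = fat_center, muscle_center = muscle_center,
                       bone_center = bone_center), class = "masct_ct_centers")
  if (!(cc$fat_center > -250 && cc$fat_center < cc$muscle_center &&
        cc$muscle_center < cc$bone_center))
    stop("CT centers must satisfy -250 < fat < muscle < bone", call. = FALSE)
  cc
}

#' Classify non-air CT voxels into fat, muscle and bone
#'
#' Three-class fuzzy c-means on the non-air voxels; clusters are ordered by
#' ascending center (fat < muscle < bone) and voxels labeled by maximum
#' membership. For speed the clustering subsamples at most `max_samples`
#' voxels (seeded) and then assigns all voxels by nearest center.
#'
#' @param ct CT `masct_volume`.
#' @param air_mask mask from [mask_air()] on the same grid.
#' @param fcm FCM parameters (`fuzzifier`, `tol`, `max_iter`).
#' @param seed clustering seed.
#' @param max_samples subsample cap for the FCM stage.
#' @return list with `labels` (a [label_volume()]: 0 air, 2 fat, 3 muscle,
#'   4 bone) and `centers` ([ct_cluster_centers()]).
#' @export
classify_tissues_ct <- function(ct, air_mask, fcm = list(), seed = 1,
                                max_samples = 200000) {
  if (!same_grid(ct, air_mask))
    stop("`air_mask` must share the CT grid", call. = FALSE)
  fcm <- modifyList(list(fuzzifier = 2, tol = 1e-4, max_iter = 200), fcm)
  nonair <- air_mask$data == 0
  x <- ct$data[nonair]
  if (length(unique(x)) < 3)
    stop("degenerate input: fewer than 3 distinct HU values outside air",
         call. = FALSE)
  xs <- if (length(x) > max_samples)
    local_seed(seed, x[sample.int(length(x), max_samples)]) else x
  cl <- fuzzy_c_means(xs, 3, fcm$fuzzifier, fcm$tol, fcm$max_iter, seed,
                      nstart = 5)
  centers <- cl$centers
  # refine on the full data with one hard-assignment pass
  assign_idx <- max.col(-outer(x, centers, function(a, b) (a - b)^2))
  for (j in 1:3) if (any(assign_idx == j)) centers[j] <- mean(x[assign_idx == j])
  centers <- sort(centers)
  assign_idx <- max.col(-outer(x, centers, function(a, b) (a - b)^2))
  lab <- array(0L, dim(ct$data))
  lab[nonair] <- assign_idx + 1L  # 2 fat, 3 muscle, 4 bone
  list(labels = label_volume(lab, ct),
       centers = ct_cluster_centers(centers[1], centers[2], centers[3]))
}

#' Suppress bone in a CT volume
#'
#' Bone-labeled voxels are set to air HU; every other voxel is unchanged.
#'
#' @param ct CT `masct_volume`.
#' @param labels [label_volume()] aligned with `ct`.
#' @param air_hu replacement value (default -1000 HU).
#' @return bone-suppressed CT `masct_volume`.
#' @export
suppress_bone <- function(ct, labels, air_hu = -1000) {
  if (!identical(dim(ct$data), dim(labels$labels)))
    stop("`labels` must be aligned with `ct`", call. = FALSE)
  out <- ct$data
  out[labels$labels == 4L] <- air_hu
  volume(out, ct$spacing, ct$origin, ct$direction, "CT")
}

#' Standardize a bone-suppressed CT into the water-MR intensity frame
#'
#' Piecewise-linear monotone map sending (air HU, fat center, muscle center)
#' to (0, `s_dark`, `s_bright`): fat maps near the water image's dark
#' landmark (fat is dark on water images, so this simultaneously suppresses
#' fat), muscle maps to the bright landmark, and the already bone-suppressed
#' voxels land at 0 together with air. Output is clamped to `[0, s_max]`.
#'
#' @param ct_bs bone-suppressed CT from [suppress_bone()].
#' @param centers [ct_cluster_centers()] from [classify_tissues_ct()].
#' @param scale [standard_scale()] shared with the MR chain.
#' @param air_hu the air HU used for suppression.
#' @return standardized, bone- and fat-suppressed CT `masct_volume`.
#' @export
standardize_ct_to_mr <- function(ct_bs, centers, scale = standard_scale(),
                                 air_hu = -1000) {
  if (!inherits(centers, "masct_ct_centers"))
    stop("`centers` must be ct_cluster_centers", call. = FALSE)
  if (!(air_hu < centers$fat_center))
    stop("air HU must lie below the fat center", call. = FALSE)
  y <- pw_linear_map(as.vector(ct_bs$data),
                     c(air_hu, centers$fat_center, centers$muscle_center),
                     c(0, scale$s_dark, scale$s_bright),
                     lo = 0, hi = scale$s_max)
  volume(array(y, dim(ct_bs$data)), ct_bs$spacing, ct_bs$origin,
         ct_bs$direction, "CT")
}

#' Body mask of a CT volume
#'
#' Largest connected non-air component, closed with an ellipsoidal
#' structuring element (default radius 3 voxels per axis). Used to exclude
#' the background from evaluation.
#'
#' @param ct CT `masct_volume`.
#' @param threshold_hu air threshold passed to [mask_air()].
#' @param closing_radius per-axis voxel radius of the morphological closing.
#' @return `masct_volume` mask (1 = body).
#' @export
body_mask <- function(ct, threshold_hu = -250, closing_radius = c(3, 3, 3)) {
  air <- mask_air(ct, threshold_hu)
  nonair <- array(as.integer(air$data == 0), dim(air$data))
  comp <- cpp_largest_component(nonair, dim(nonair))
  r <- as.integer(round(closing_radius))
  closed <- cpp_binary_morph(cpp_binary_morph(comp, dim(comp), r, 1L),
                             dim(comp), r, 0L)
  volume(array(as.double(closed), dim(comp)), ct$spacing, ct$origin,
         ct$direction, "MASK")
}

#' Full CT conditioning chain
#'
#' [mask_air()] -> [classify_tissues_ct()] -> [suppress_bone()] ->
#' [standardize_ct_to_mr()].
#'
#' @param ct CT `masct_volume`.
#' @param scale [standard_scale()].
#' @param threshold_hu air threshold.
#' @param fcm,seed passed to [classify_tissues_ct()].
#' @return list with `ct_sbsfs` (conditioned CT), `labels`, `centers`.
#' @export
condition_ct <- function(ct, scale = standard_scale(), threshold_hu = -250,
                         fcm = list(), seed = 1) {
  air <- mask_air(ct, threshold_hu)
  cls <- classify_tissues_ct(ct, air, fcm = fcm, seed = seed)
  ct_bs <- suppress_bone(ct, cls$labels)
  list(ct_sbsfs = standardize_ct_to_mr(ct_bs, cls$centers, scale),
       labels = cls$labels, centers = cls$centers)
}
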