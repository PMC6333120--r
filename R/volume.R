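#' @useDynLib masct, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim quantile rnorm runif sd var median
#' @importFrom utils modifyList packageVersion
NULL

MODALITIES <- c("CT", "MR_WATER", "MR_FAT", "MR_WFE", "MASK", "LABELS", "SCT")

#' 3-D image volume with physical geometry
#'
#' The common carrier for CT (Hounsfield units), MR (arbitrary units), masks
#' and synthetic CT. The world mapping is
#' `world = origin + direction %*% (index * spacing)` with 0-based voxel
#' indices and millimetre coordinates. By package convention sagittal slices
#' lie along the first array axis and axial slices along the third.
#'
#' @param data 3-D numeric array; all values must be finite. Masks must be
#'   binary (0/1).
#' @param spacing per-axis voxel size in mm, all > 0.
#' @param origin physical position (mm) of voxel (0, 0, 0).
#' @param direction 3x3 orthonormal direction matrix.
#' @param modality one of `"CT"`, `"MR_WATER"`, `"MR_FAT"`, `"MR_WFE"`,
#'   `"MASK"`, `"LABELS"`, `"SCT"`.
#' @return An object of class `masct_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3), modality = "CT") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "double"
  v <- structure(
    list(data = data, spacing = as.double(spacing),
         origin = as.double(origin),
         direction = matrix(as.double(direction), 3, 3),
         modality = match.arg(modality, MODALITIES)),
    class = "masct_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("spacing must be 3 positive finite values", call. = FALSE)
  if (length(v$origin) != 3L || any(!is.finite(v$origin)))
    stop("origin must be 3 finite values", call. = FALSE)
  d <- v$direction
  if (max(abs(crossprod(d) - diag(3))) > 1e-6 || abs(abs(det(d)) - 1) > 1e-6)
    stop("direction matrix must be orthonormal", call. = FALSE)
  if (anyNA(v$data) || any(!is.finite(v$data)))
    stop("volume data must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (v$modality == "MASK" && !all(v$data %in% c(0, 1)))
    stop("mask volumes may contain only 0 and 1", call. = FALSE)
  invisible(v)
}

#' @export
print.masct_volume <- function(x, ...) {
  cat(sprintf("<masct_volume> %s  %s  spacing %s mm  range [%.6g, %.6g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Integer label volume
#'
#' Tissue label map sharing a [volume()] geometry. Codes: 0 background /
#' outside-body air, 1 interior air, 2 fat, 3 muscle, 4 bone.
#'
#' @param labels 3-D integer array with values in 0..4.
#' @param geometry a `masct_volume` (or compatible list) supplying spacing,
#'   origin and direction.
#' @return An object of class `masct_labels`.
#' @export
label_volume <- function(labels, geometry) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:4))
    stop("label codes restricted to {0, 1, 2, 3, 4}", call. = FALSE)
  structure(
    list(labels = labels, spacing = as.double(geometry$spacing),
         origin = as.double(geometry$origin),
         direction = matrix(as.double(geometry$direction), 3, 3)),
    class = "masct_labels")
}

#' @export
print.masct_labels <- function(x, ...) {
  cat(sprintf("<masct_labels> %s  codes {%s}\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sort(unique(as.vector(x$labels))), collapse = ",")))
  invisible(x)
}

labels_as_volume <- function(lv) {
  volume(array(as.double(lv$labels), dim(lv$labels)), lv$spacing, lv$origin,
         lv$direction, "LABELS")
}

geom_of <- function(v) {
  list(dim = dim(v$data %||% v$labels), spacing = v$spacing,
       origin = v$origin, direction = v$direction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

same_grid <- function(a, b, tol = 1e-6) {
  ga <- geom_of(a); gb <- geom_of(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$direction - gb$direction)) < tol
}

modality_fill <- function(modality) {
  switch(modality, CT = -1000, SCT = -1000, MASK = 0, LABELS = 0, 0)
}

#' Resample a volume onto a reference grid
#'
#' Values are interpolated in physical space; voxels of the reference grid
#' that fall outside the source support are filled with the modality default
#' (CT/SCT: -1000 HU; MR: 0; mask/labels: 0).
#'
#' @param v source `masct_volume`.
#' @param reference `masct_volume` whose grid and geometry define the output.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A `masct_volume` on the reference grid with `v`'s modality.
#' @export
resample_to <- function(v, reference, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (v$modality %in% c("MASK", "LABELS")) interpolation <- "nearest"
  gs <- geom_of(v); gd <- geom_of(reference)
  out <- cpp_resample(as.double(v$data), as.integer(gs$dim), gs$spacing,
                      gs$origin, gs$direction, as.integer(gd$dim), gd$spacing,
                      gd$origin, gd$direction, NULL,
                      if (interpolation == "nearest") 1L else 0L,
                      modality_fill(v$modality))
  volume(out, gd$spacing, gd$origin, gd$direction, v$modality)
}

#' World coordinates of all voxels (n x 3, mm)
#' @param v a `masct_volume` or `masct_labels`.
#' @keywords internal
world_grid <- function(v) {
  g <- geom_of(v)
  idx <- as.matrix(expand.grid(x = seq_len(g$dim[1]) - 1,
                               y = seq_len(g$dim[2]) - 1,
                               z = seq_len(g$dim[3]) - 1))
  sweep(t(g$direction %*% t(idx * rep(g$spacing, each = nrow(idx)))),
        2, g$origin, `+`)
}

# run expr with a local deterministic RNG state, restoring the caller's
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
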