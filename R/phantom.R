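# Seeded digital pelvis phantom: paired CT / water-MR / fat-MR volumes with
# ground-truth labels, landmark points, a smooth inter-subject deformation,
# multiplicative MR bias and noise. Structure sizes scale with the grid
# extent so small test grids still contain every structure.

#' Phantom cohort configuration
#'
#' @param grid voxel grid size (>= 32 per axis).
#' @param spacing voxel spacing mm (default 1 x 1 x 2.5 mm, a typical pelvis
#'   protocol slice thickness).
#' @param hu,mr_water,mr_fat per-tissue intensity models: lists with `mean`
#'   and `sd` over (air, fat, muscle, bone). Values are generator
#'   conventions chosen to emulate the contrast the method assumes: on the
#'   water image muscle is the bright mode and fat dark, on the fat image
#'   fat is bright, and the CT histogram has three non-air modes.
#' @param deformation `amplitude_mm` (maximum displacement magnitude) and
#'   `smoothness_mm` (Gaussian correlation scale) of the random
#'   template-to-subject field.
#' @param bias_amplitude relative amplitude of the smooth multiplicative MR
#'   gain field.
#' @param noise MR measurement noise: `model` (`"rician"` or `"gaussian"`)
#'   and `sigma`.
#' @return object of class `masct_phantom_config`.
#' @export
phantom_config <- function(grid = c(96, 96, 48), spacing = c(1, 1, 2.5),
                           hu = list(mean = c(air = -1000, fat = -100,
                                              muscle = 40, bone = 700),
                                     sd = c(air = 10, fat = 15, muscle = 10,
                                            bone = 100)),
                           mr_water = list(mean = c(air = 30, fat = 120,
                                                    muscle = 520, bone = 150),
                                           sd = c(air = 10, fat = 15,
                                                  muscle = 25, bone = 20)),
                           mr_fat = list(mean = c(air = 30, fat = 520,
                                                  muscle = 120, bone = 140),
                                         sd = c(air = 10, fat = 25,
                                                muscle = 15, bone = 20)),
                           deformation = list(amplitude_mm = 5,
                                              smoothness_mm = 7.5),
                           bias_amplitude = 0.2,
                           noise = list(model = "rician", sigma = 15)) {
  if (any(grid < 32))
    stop("phantom grid must be >= 32 voxels per axis", call. = FALSE)
  if (deformation$amplitude_mm < 0 || bias_amplitude < 0 || noise$sigma < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(grid = as.integer(grid), spacing = as.double(spacing),
                 hu = hu, mr_water = mr_water, mr_fat = mr_fat,
                 deformation = deformation, bias_amplitude = bias_amplitude,
                 noise = noise),
            class = "masct_phantom_config")
}

phantom_coords <- function(cfg) {
  n <- cfg$grid; sp <- cfg$spacing
  x <- (seq_len(n[1]) - 1) * sp[1]
  y <- (seq_len(n[2]) - 1) * sp[2]
  z <- (seq_len(n[3]) - 1) * sp[3]
  list(X = array(rep(x, times = n[2] * n[3]), n),
       Y = array(rep(rep(y, each = n[1]), times = n[3]), n),
       Z = array(rep(z, each = n[1] * n[2]), n),
       c = c((n[1] - 1) * sp[1], (n[2] - 1) * sp[2], (n[3] - 1) * sp[3]) / 2,
       h = c((n[1] - 1) * sp[1], (n[2] - 1) * sp[2], (n[3] - 1) * sp[3]) / 2)
}

#' Deterministic pelvis-like template label map
#'
#' Elliptical body with a subcutaneous fat ring and muscle interior; bone as
#' two femoral-head spheres, a pelvic-ring shell and a sacrum block; one
#' interior air pocket (rectum analog). Landmarks: the two femoral-head
#' centers (trochanter analogs), the sacrum center and an anterior body
#' marker (4 non-collinear points for rigid initialization).
#'
#' @param cfg [phantom_config()].
#' @return list with `labels` ([label_volume()]) and `landmarks` (4 x 3
#'   matrix, physical mm).
#' @export
make_template <- function(cfg = phantom_config()) {
  co <- phantom_coords(cfg)
  cx <- co$c[1]; cy <- co$c[2]; cz <- co$c[3]
  hx <- co$h[1]; hy <- co$h[2]; hz <- co$h[3]
  X <- co$X - cx; Y <- co$Y - cy; Z <- co$Z - cz
  lab <- array(0L, cfg$grid)
  body <- (X / (0.92 * hx))^2 + (Y / (0.80 * hy))^2 <= 1
  inner <- (X / (0.75 * hx))^2 + (Y / (0.63 * hy))^2 <= 1
  lab[body] <- 2L              # subcutaneous fat ring
  lab[inner] <- 3L             # muscle interior
  rs <- 0.19 * hx              # femoral-head spheres
  fem <- list(c(cx - 0.55 * hx, cy + 0.10 * hy, cz),
              c(cx + 0.55 * hx, cy + 0.10 * hy, cz))
  for (f in fem) {
    sph <- ((co$X - f[1])^2 + (co$Y - f[2])^2 + (co$Z - f[3])^2) <= rs^2
    lab[sph & lab > 0] <- 4L
  }
  ring_out <- (X / (0.42 * hx))^2 + ((Y + 0.12 * hy) / (0.34 * hy))^2 <= 1
  ring_in <- (X / (0.29 * hx))^2 + ((Y + 0.12 * hy) / (0.21 * hy))^2 <= 1
  ring <- ring_out & !ring_in & abs(Z) <= 0.55 * hz
  lab[ring & lab > 0] <- 4L
  sac <- abs(X) <= 0.21 * hx & Y >= 0.38 * hy & Y <= 0.59 * hy &
    abs(Z) <= 0.33 * hz
  lab[sac & lab > 0] <- 4L
  air <- (X^2 + (Y - 0.25 * hy)^2) <= (0.10 * hx)^2 & abs(Z) <= 0.26 * hz
  lab[air] <- 1L               # interior air pocket
  geometry <- list(spacing = cfg$spacing, origin = c(0, 0, 0),
                   direction = diag(3))
  landmarks <- rbind(fem[[1]], fem[[2]],
                     c(cx, cy + 0.49 * hy, cz),
                     c(cx, cy - 0.55 * hy, cz))
  rownames(landmarks) <- c("trochanter_left", "trochanter_right",
                           "sacrum", "anterior")
  list(labels = label_volume(lab, geometry), landmarks = landmarks)
}

smooth_random_field <- function(cfg) {
  n <- cfg$grid
  N <- prod(n)
  sig <- cfg$deformation$smoothness_mm / cfg$spacing
  comps <- lapply(1:3, function(a) {
    w <- array(rnorm(N), n)
    s <- cpp_gaussian_smooth(w, n, sig)
    array(s, n)
  })
  mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
  amp <- cfg$deformation$amplitude_mm
  sc <- if (max(mag) > 0) amp / max(mag) else 0
  array(c(comps[[1]] * sc, comps[[2]] * sc, comps[[3]] * sc), c(n, 3))
}

# trilinear sample of a (nx,ny,nz,3) displacement array at physical points
sample_field_at <- function(disp, geometry, pts) {
  n <- dim(disp)[1:3]
  out <- matrix(0, nrow(pts), 3)
  for (r in seq_len(nrow(pts))) {
    v <- as.vector(t(geometry$direction) %*%
                     (pts[r, ] - geometry$origin)) / geometry$spacing
    v <- pmin(pmax(v, 0), n - 1)
    i0 <- pmin(floor(v), n - 2); f <- v - i0
    for (cc in 1:3) {
      acc <- 0
      for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
        w <- (if (di) f[1] else 1 - f[1]) * (if (dj) f[2] else 1 - f[2]) *
          (if (dk) f[3] else 1 - f[3])
        acc <- acc + w * disp[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1, cc]
      }
      out[r, cc] <- acc
    }
  }
  out
}

render_tissue <- function(lab, model, zero_noise = FALSE) {
  # label codes: 0/1 air, 2 fat, 3 muscle, 4 bone
  class_of <- c(1L, 1L, 2L, 3L, 4L)[lab + 1L]
  out <- model$mean[class_of]
  if (!zero_noise && any(model$sd > 0))
    out <- out + model$sd[class_of] * rnorm(length(lab))
  array(out, dim(lab))
}

#' Generate one phantom subject
#'
#' The template is warped by a random smooth displacement field (white noise
#' smoothed to the configured correlation scale and rescaled to the
#' configured maximum amplitude); tissue intensities are drawn per label;
#' the MR channels are corrupted by a smooth multiplicative bias field and
#' Rician (or Gaussian) noise; landmarks are mapped through the inverse
#' warp so they stay attached to the anatomy. The same seed reproduces the
#' subject bit-exactly.
#'
#' @param cfg [phantom_config()].
#' @param seed integer seed.
#' @param id subject identifier.
#' @return list (`id`, `ct`, `water`, `fat`, `labels`, `landmarks`
#'   (`$mr`/`$ct`), `truth_field` ([deformation_field()] mapping subject
#'   coordinates to template coordinates), `seed`).
#' @export
make_subject <- function(cfg = phantom_config(), seed = 1,
                         id = sprintf("phantom_s%d", seed)) {
  tpl <- make_template(cfg)
  geometry <- list(spacing = cfg$spacing, origin = c(0, 0, 0),
                   direction = diag(3))
  n <- cfg$grid
  local_seed(seed, {
    disp <- if (cfg$deformation$amplitude_mm > 0) smooth_random_field(cfg)
            else array(0, c(n, 3))
    lab_arr <- array(
      as.integer(cpp_resample(array(as.double(tpl$labels$labels), n),
                              as.integer(n), cfg$spacing, c(0, 0, 0), diag(3),
                              as.integer(n), cfg$spacing, c(0, 0, 0), diag(3),
                              as.double(disp), 1L, 0)), n)
    labels <- label_volume(lab_arr, geometry)
    # invert the pull-back field at the landmark points:
    # find p with p + d(p) = p_template
    lm <- tpl$landmarks
    for (it in 1:20) {
      lm <- tpl$landmarks - sample_field_at(disp, geometry, lm)
    }
    dimnames(lm) <- dimnames(tpl$landmarks)
    ct <- volume(render_tissue(lab_arr, cfg$hu), cfg$spacing,
                 modality = "CT")
    make_mr <- function(model, modality) {
      img <- render_tissue(lab_arr, model)
      if (cfg$bias_amplitude > 0) {
        b <- cpp_gaussian_smooth(array(rnorm(prod(n)), n), as.integer(n),
                                 30 / cfg$spacing)
        b <- 1 + cfg$bias_amplitude * b / max(abs(b))
        img <- img * array(b, n)
      }
      sg <- cfg$noise$sigma
      if (sg > 0) {
        if (identical(cfg$noise$model, "rician")) {
          img <- sqrt((img + sg * rnorm(length(img)))^2 +
                        (sg * rnorm(length(img)))^2)
        } else {
          img <- img + sg * rnorm(length(img))
        }
      }
      volume(array(pmax(img, 0), n), cfg$spacing, modality = modality)
    }
    water <- make_mr(cfg$mr_water, "MR_WATER")
    fat <- make_mr(cfg$mr_fat, "MR_FAT")
    list(id = id, ct = ct, water = water, fat = fat, labels = labels,
         landmarks = list(mr = lm, ct = lm),
         truth_field = deformation_field(disp, geometry), seed = seed)
  })
}

#' Generate a phantom cohort
#'
#' @param cfg [phantom_config()].
#' @param n number of subjects.
#' @param master_seed master seed; per-subject seeds are derived from it.
#' @return list of subjects (see [make_subject()]) with unique ids.
#' @export
make_cohort <- function(cfg = phantom_config(), n = 6, master_seed = 7) {
  stopifnot(n >= 1)
  base <- (as.integer(master_seed) %% 100000L) * 1000L
  lapply(seq_len(n), function(i)
    make_subject(cfg, seed = base + i, id = sprintf("phantom%02d", i)))
}
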