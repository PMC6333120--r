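# Landmark-initialized rigid alignment + cubic B-spline free-form deformable
# registration with a mean-squared-error cost, multiresolution schedule and
# analytic-gradient L-BFGS-B optimization. Fields use pull-back semantics:
# the displacement lives on the fixed grid and maps fixed physical points to
# moving physical points.

#' Rigid transform (rotation + translation)
#' @param rotation 3x3 orthonormal matrix with det = +1.
#' @param translation length-3 translation in mm.
#' @return object of class `masct_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.double(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with det = +1", call. = FALSE)
  structure(list(rotation = rotation, translation = as.double(translation)),
            class = "masct_rigid")
}

#' Least-squares rigid transform from matched landmark points
#'
#' Orthogonal Procrustes with translation: minimizes
#' \eqn{\sum_i \| R f_i + t - m_i \|^2} over proper rotations (Kabsch
#' algorithm). Used to initialize registration from paired anatomical
#' landmarks such as the greater trochanters.
#'
#' @param fixed_pts,moving_pts n x 3 matrices (n >= 3, non-collinear) of
#'   matched physical points in mm.
#' @return a [rigid_transform()].
#' @export
rigid_from_landmarks <- function(fixed_pts, moving_pts) {
  f <- as.matrix(fixed_pts); m <- as.matrix(moving_pts)
  if (nrow(f) != nrow(m) || nrow(f) < 3 || ncol(f) != 3 || ncol(m) != 3)
    stop("need >= 3 matched 3-D points", call. = FALSE)
  fc <- colMeans(f); mc <- colMeans(m)
  fcn <- sweep(f, 2, fc); mcn <- sweep(m, 2, mc)
  sv_f <- svd(fcn)$d
  if (sv_f[2] < 1e-8 * max(sv_f[1], 1))
    stop("landmark points are collinear", call. = FALSE)
  H <- crossprod(fcn, mcn)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.vector(mc - R %*% fc))
}

#' Dense deformation field
#' @param displacements array of dim `c(nx, ny, nz, 3)`: per-voxel world-frame
#'   displacement in mm on the fixed grid.
#' @param geometry a `masct_volume` (or geometry list) carrying the fixed
#'   grid's spacing/origin/direction.
#' @return object of class `masct_field`.
#' @export
deformation_field <- function(displacements, geometry) {
  if (length(dim(displacements)) != 4L || dim(displacements)[4] != 3L)
    stop("`displacements` must have dim (nx, ny, nz, 3)", call. = FALSE)
  if (any(!is.finite(displacements)))
    stop("displacement field must be finite", call. = FALSE)
  structure(list(displacements = displacements,
                 spacing = as.double(geometry$spacing),
                 origin = as.double(geometry$origin),
                 direction = matrix(as.double(geometry$direction), 3, 3)),
            class = "masct_field")
}

field_geom <- function(field) {
  list(dim = dim(field$displacements)[1:3], spacing = field$spacing,
       origin = field$origin, direction = field$direction)
}

#' Registration parameters
#'
#' @param grid_spacing_mm B-spline control-point spacing (scalar or per-axis).
#' @param pyramid_levels multiresolution levels (downsampling 2^(L-1) ... 1).
#' @param iterations_per_level optimizer iterations; scalar or one per level
#'   (coarse to fine).
#' @param metric only `"mse"` is supported.
#' @param subsample per-axis integer subsampling of the fixed grid at the
#'   finest level (default 1 x 1 x 1, i.e. none).
#' @param regularization_weight bending-energy weight on the control lattice.
#' @return object of class `masct_regparams`.
#' @export
registration_params <- function(grid_spacing_mm = 20, pyramid_levels = 3,
                                iterations_per_level = c(100, 60, 25),
                                metric = "mse", subsample = c(1, 1, 1),
                                regularization_weight = 0.1) {
  if (metric != "mse") stop("only the MSE metric is supported", call. = FALSE)
  gs <- rep(as.double(grid_spacing_mm), length.out = 3)
  if (any(gs <= 0)) stop("grid_spacing_mm must be > 0", call. = FALSE)
  ss <- rep(as.integer(subsample), length.out = 3)
  if (any(ss < 1)) stop("subsample factors must be >= 1", call. = FALSE)
  it <- rep(as.integer(iterations_per_level), length.out = pyramid_levels)
  structure(list(grid_spacing_mm = gs, pyramid_levels = as.integer(pyramid_levels),
                 iterations_per_level = it, metric = metric, subsample = ss,
                 regularization_weight = as.double(regularization_weight)),
            class = "masct_regparams")
}

smooth_downsample <- function(v, factor, subsample = c(1, 1, 1)) {
  f <- factor * subsample
  if (all(f == 1)) return(v)
  sm <- if (factor > 1)
    cpp_gaussian_smooth(v$data, dim(v$data), rep(factor / 2, 3))
  else v$data
  g <- geom_of(v)
  ndim <- pmax(as.integer(ceiling(g$dim / f)), 2L)
  nsp <- g$spacing * f
  out <- cpp_resample(sm, as.integer(g$dim), g$spacing, g$origin, g$direction,
                      ndim, nsp, g$origin, g$direction, NULL, 0L,
                      modality_fill(v$modality))
  volume(out, nsp, g$origin, g$direction, v$modality)
}

mse_between <- function(a, b) mean((a - b)^2)

#' B-spline deformable registration
#'
#' Optimizes a cubic B-spline free-form deformation composed with a rigid
#' initialization so that the warped moving image matches the fixed image
#' under a mean-squared-error cost, over a coarse-to-fine pyramid. The
#' result is the dense composition `phi(x) = R x + t + d(x)` expressed as one
#' displacement field on the fixed grid. If optimization fails to improve on
#' the rigid-only alignment at full resolution the B-spline part is dropped,
#' so the returned field is never worse than the initialization.
#'
#' @param fixed,moving `masct_volume`s with comparable (standardized)
#'   intensities.
#' @param init [rigid_transform()] initialization (identity default).
#' @param params [registration_params()].
#' @return a [deformation_field()] with attributes `mse_rigid`,
#'   `mse_levels` (full-resolution MSE after each level) and `mse_final`.
#' @export
bspline_register <- function(fixed, moving, init = rigid_transform(),
                             params = registration_params()) {
  stopifnot(inherits(fixed, "masct_volume"), inherits(moving, "masct_volume"))
  gf <- geom_of(fixed)
  delta <- params$grid_spacing_mm
  m_int <- pmax(1L, as.integer(ceiling(((gf$dim - 1) * gf$spacing) / delta)))
  cdim <- m_int + 3L
  ncoef <- prod(cdim)
  coef <- numeric(3 * ncoef)
  fill <- modality_fill(moving$modality)
  factors <- rev(2^(seq_len(params$pyramid_levels) - 1))
  cost_full <- function(cf, lambda = 0) {
    gm <- geom_of(moving)
    gradz <- numeric(length(moving$data)) # unused when want_grad = 0
    res <- cpp_bspline_cost_grad(fixed$data, as.integer(gf$dim), gf$spacing,
                                 gf$origin, gf$direction, moving$data,
                                 as.integer(gm$dim), gm$spacing, gm$origin,
                                 gm$direction, gradz, gradz, gradz,
                                 init$rotation, init$translation, cf,
                                 as.integer(cdim), delta, as.integer(gf$dim),
                                 gf$spacing, gf$origin, gf$direction,
                                 lambda, fill, 0L)
    res$value
  }
  mse_rigid <- cost_full(numeric(3 * ncoef))
  mse_levels <- numeric(0)
  for (lev in seq_along(factors)) {
    f <- factors[lev]
    sub <- if (f == 1) params$subsample else c(1L, 1L, 1L)
    fx <- smooth_downsample(fixed, f, sub)
    mv <- smooth_downsample(moving, f)
    gfx <- geom_of(fx); gmv <- geom_of(mv)
    grad <- cpp_gradient_world(mv$data, as.integer(gmv$dim), gmv$spacing,
                               gmv$direction)
    last_par <- NULL; last <- NULL
    eval_all <- function(par) {
      cpp_bspline_cost_grad(fx$data, as.integer(gfx$dim), gfx$spacing,
                            gfx$origin, gfx$direction, mv$data,
                            as.integer(gmv$dim), gmv$spacing, gmv$origin,
                            gmv$direction, grad$gx, grad$gy, grad$gz,
                            init$rotation, init$translation, par,
                            as.integer(cdim), delta, as.integer(gf$dim),
                            gf$spacing, gf$origin, gf$direction,
                            params$regularization_weight, fill, 1L)
    }
    ensure <- function(par) {
      if (is.null(last_par) || !identical(par, last_par)) {
        last <<- eval_all(par)
        last_par <<- par
      }
    }
    res <- optim(coef,
                 fn = function(par) { ensure(par); last$value },
                 gr = function(par) { ensure(par); last$grad },
                 method = "L-BFGS-B",
                 control = list(maxit = params$iterations_per_level[lev]))
    if (!is.finite(res$value))
      stop(sprintf("non-finite registration cost at pyramid level %d", lev),
           call. = FALSE)
    coef <- res$par
    mse_levels <- c(mse_levels, cost_full(coef))
  }
  if (mse_levels[length(mse_levels)] > mse_rigid) {
    coef <- numeric(3 * ncoef)  # keep the rigid-only alignment
    mse_levels <- c(mse_levels, mse_rigid)
  }
  disp_b <- cpp_bspline_disp(coef, as.integer(cdim), delta,
                             as.integer(gf$dim), gf$spacing, gf$origin,
                             gf$direction, as.integer(gf$dim), gf$spacing,
                             gf$origin, gf$direction)
  N <- prod(gf$dim)
  p <- world_grid(fixed)
  rigid_disp <- t(init$rotation %*% t(p)) +
    matrix(init$translation, N, 3, byrow = TRUE) - p
  disp <- array(as.vector(matrix(disp_b, N, 3) + rigid_disp),
                c(gf$dim, 3))
  field <- deformation_field(disp, fixed)
  attr(field, "mse_rigid") <- mse_rigid
  attr(field, "mse_levels") <- mse_levels
  attr(field, "mse_final") <- mse_levels[length(mse_levels)]
  attr(field, "coef") <- coef
  field
}

#' Warp a volume through a deformation field
#'
#' Pull-back warp: `out(x) = v(x + d(x))`, output on the field's grid,
#' out-of-support voxels filled with the modality default.
#'
#' @param v `masct_volume` to warp (the moving image).
#' @param field [deformation_field()] on the output grid.
#' @param interpolation `"linear"` or `"nearest"` (label maps and masks
#'   always use nearest).
#' @return warped `masct_volume`.
#' @export
apply_deformation <- function(v, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (v$modality %in% c("MASK", "LABELS")) interpolation <- "nearest"
  gs <- geom_of(v); gd <- field_geom(field)
  out <- cpp_resample(as.double(v$data), as.integer(gs$dim), gs$spacing,
                      gs$origin, gs$direction, as.integer(gd$dim), gd$spacing,
                      gd$origin, gd$direction, as.double(field$displacements),
                      if (interpolation == "nearest") 1L else 0L,
                      modality_fill(v$modality))
  volume(out, gd$spacing, gd$origin, gd$direction, v$modality)
}

#' Compose two deformation fields
#'
#' Returns the field of the composed map `x -> x + d1(x) + d2(x + d1(x))`
#' on `f1`'s grid (apply `f1` first, then `f2`).
#'
#' @param f1,f2 [deformation_field()]s.
#' @return composed [deformation_field()] on `f1`'s grid.
#' @export
compose_fields <- function(f1, f2) {
  g1 <- field_geom(f1); g2 <- field_geom(f2)
  N <- prod(g1$dim)
  d2_at <- vapply(1:3, function(c) {
    cpp_resample(as.double(f2$displacements[, , , c]), as.integer(g2$dim),
                 g2$spacing, g2$origin, g2$direction, as.integer(g1$dim),
                 g1$spacing, g1$origin, g1$direction,
                 as.double(f1$displacements), 0L, 0)
  }, numeric(N))
  deformation_field(array(as.vector(f1$displacements) + as.vector(d2_at),
                          c(g1$dim, 3)),
                    list(spacing = g1$spacing, origin = g1$origin,
                         direction = g1$direction))
}
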