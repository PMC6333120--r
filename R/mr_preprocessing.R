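# MR conditioning chain: bias reduction -> landmark detection -> histogram
# standardization -> fat-enhanced water image. Water and fat series both run
# through the full chain; only the water/fat pair is used downstream.

#' Standard intensity scale for landmark standardization
#'
#' Target frame the three histogram landmarks are mapped onto. The absolute
#' values are a package convention (only relative placement matters); a fixed
#' frame makes atlas and new-patient images directly comparable.
#'
#' @param s_dark,s_valley,s_bright targets for the dark mode, valley and
#'   bright mode.
#' @param s_max cap for the linear extension above the bright mode.
#' @return object of class `masct_scale`.
#' @export
standard_scale <- function(s_dark = 100, s_valley = 500, s_bright = 1000,
                           s_max = 1200) {
  s <- structure(list(s_dark = s_dark, s_valley = s_valley,
                      s_bright = s_bright, s_max = s_max),
                 class = "masct_scale")
  if (!(0 <= s$s_dark && s$s_dark < s$s_valley && s$s_valley < s$s_bright &&
        s$s_bright < s$s_max))
    stop("standard scale must satisfy 0 <= dark < valley < bright < max",
         call. = FALSE)
  s
}

#' Intensity landmarks of an MR histogram
#'
#' @param dark_mode,valley,bright_mode intensities with
#'   `dark_mode < valley < bright_mode`, all finite and >= 0.
#' @param source_modality `"MR_WATER"` or `"MR_FAT"`.
#' @return object of class `masct_landmarks`.
#' @export
tissue_landmarks <- function(dark_mode, valley, bright_mode,
                             source_modality = "MR_WATER") {
  lm <- structure(list(dark_mode = dark_mode, valley = valley,
                       bright_mode = bright_mode,
                       source_modality = match.arg(source_modality,
                                                   c("MR_WATER", "MR_FAT"))),
                  class = "masct_landmarks")
  vals <- c(lm$dark_mode, lm$valley, lm$bright_mode)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      !(lm$dark_mode < lm$valley && lm$valley < lm$bright_mode))
    stop("landmarks must satisfy 0 <= dark_mode < valley < bright_mode",
         call. = FALSE)
  lm
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  as.vector(stats::filter(x, rep(1 / window, window), sides = 2,
                          circular = FALSE)) -> y
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Detect dark-mode / valley / bright-mode landmarks on an MR image
#'
#' Foreground voxels (above the air/tissue [background_threshold()], which
#' excludes the dark air background) are split into dark and bright clusters
#' with
#' two-class fuzzy c-means; the smoothed per-cluster histogram modes give the
#' dark and bright landmarks and the minimum of the full smoothed histogram
#' strictly between them gives the valley. If the histogram has no interior
#' minimum the midpoint of the two modes is used with a warning.
#'
#' @param v bias-corrected MR `masct_volume` (`MR_WATER` or `MR_FAT`).
#' @param seed seed for the FCM initialization.
#' @param hist_bins histogram bin count (over the 0.1-99.9 percentile range).
#' @param smooth_window moving-average window (bins) before mode picking.
#' @param fcm FCM parameter list (`fuzzifier`, `tol`, `max_iter`).
#' @return a [tissue_landmarks()] object.
#' @export
detect_landmarks <- function(v, seed = 1, hist_bins = 256, smooth_window = 5,
                             fcm = list()) {
  if (!v$modality %in% c("MR_WATER", "MR_FAT"))
    stop("landmark detection expects an MR volume", call. = FALSE)
  fcm <- modifyList(list(fuzzifier = 2, tol = 1e-4, max_iter = 200), fcm)
  x <- as.vector(v$data)
  if (length(unique(x)) < 2)
    stop("degenerate input: constant image has no dark/bright clusters",
         call. = FALSE)
  fg <- x[x > background_threshold(x, hist_bins, smooth_window)]
  if (length(unique(fg)) < 2)
    stop("degenerate input: foreground has fewer than two intensity levels",
         call. = FALSE)
  # cluster on a seeded subsample for speed; split the full foreground by
  # distance to the two centers
  xs <- if (length(fg) > 50000)
    local_seed(seed, fg[sample.int(length(fg), 50000)]) else fg
  cl <- fuzzy_c_means(xs, 2, fcm$fuzzifier, fcm$tol, fcm$max_iter, seed,
                      nstart = 3)
  hard <- ifelse(abs(fg - cl$centers[1]) <= abs(fg - cl$centers[2]), 1L, 2L)
  rng <- quantile(fg, c(0.001, 0.999), names = FALSE)
  if (diff(rng) <= 0) rng <- range(fg)
  breaks <- seq(rng[1], rng[2], length.out = hist_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin_of <- function(s) pmin(pmax(findInterval(s, breaks,
                                               rightmost.closed = TRUE), 1),
                             hist_bins)
  counts_of <- function(s) tabulate(bin_of(s), nbins = hist_bins)
  h_dark <- moving_average(counts_of(fg[hard == 1]), smooth_window)
  h_bright <- moving_average(counts_of(fg[hard == 2]), smooth_window)
  h_full <- moving_average(counts_of(fg), smooth_window)
  dark_mode <- mids[which.max(h_dark)]
  bright_mode <- mids[which.max(h_bright)]
  between <- which(mids > dark_mode & mids < bright_mode)
  if (length(between) == 0) {
    warning("no interior histogram minimum; using the midpoint of the modes")
    valley <- (dark_mode + bright_mode) / 2
  } else {
    # take the middle of the minimal plateau: on spiky (near-noiseless)
    # histograms many interior bins tie at zero and the first one would sit
    # right next to the dark mode
    hmin <- min(h_full[between])
    minimal <- between[h_full[between] <= hmin + 1e-12]
    valley <- mids[minimal[ceiling(length(minimal) / 2)]]
    if (valley <= dark_mode || valley >= bright_mode)
      valley <- (dark_mode + bright_mode) / 2
  }
  tissue_landmarks(dark_mode, valley, bright_mode, v$modality)
}

# piecewise-linear monotone map through (src, dst) knots, end segments
# extended linearly, output clamped to [lo, hi]
pw_linear_map <- function(x, src, dst, lo = 0, hi = Inf) {
  n <- length(src)
  stopifnot(n == length(dst), n >= 2, all(diff(src) > 0), all(diff(dst) > 0))
  y <- stats::approx(src, dst, xout = pmin(pmax(x, src[1]), src[n]),
                     method = "linear", ties = "ordered")$y
  below <- x < src[1]
  if (any(below)) {
    s <- (dst[2] - dst[1]) / (src[2] - src[1])
    y[below] <- dst[1] + (x[below] - src[1]) * s
  }
  above <- x > src[n]
  if (any(above)) {
    s <- (dst[n] - dst[n - 1]) / (src[n] - src[n - 1])
    y[above] <- dst[n] + (x[above] - src[n]) * s
  }
  pmin(pmax(y, lo), hi)
}

#' Standardize an MR image onto the standard intensity scale
#'
#' Piecewise-linear monotone map sending the detected
#' (dark mode, valley, bright mode) to the scale's
#' (`s_dark`, `s_valley`, `s_bright`), linearly extended beyond the outer
#' landmarks and clamped to `[0, s_max]`.
#'
#' @param v MR `masct_volume`.
#' @param lm [tissue_landmarks()] detected on `v`.
#' @param scale [standard_scale()] target frame.
#' @return standardized `masct_volume` (modality preserved).
#' @export
standardize <- function(v, lm, scale = standard_scale()) {
  if (!inherits(scale, "masct_scale")) stop("`scale` must be a standard_scale")
  if (!inherits(lm, "masct_landmarks")) stop("`lm` must be tissue_landmarks")
  y <- pw_linear_map(as.vector(v$data),
                     c(lm$dark_mode, lm$valley, lm$bright_mode),
                     c(scale$s_dark, scale$s_valley, scale$s_bright),
                     lo = 0, hi = scale$s_max)
  volume(array(y, dim(v$data)), v$spacing, v$origin, v$direction, v$modality)
}

#' Fat-enhanced water image
#'
#' Voxelwise blend of the standardized water and fat images,
#' \eqn{MR_{W,FE} = (MR_{S,W} + \alpha MR_{S,F}) / (1 + \alpha)}, improving
#' fat/air discrimination in the water image. The default weight is
#' \eqn{\alpha = 0.5}. The output is a convex combination, so it is bounded
#' voxelwise by the two inputs.
#'
#' @param water_std,fat_std standardized water / fat `masct_volume`s on one
#'   grid.
#' @param alpha non-negative blend weight.
#' @return `masct_volume` with modality `MR_WFE`.
#' @export
fat_enhance <- function(water_std, fat_std, alpha = 0.5) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (!same_grid(water_std, fat_std))
    stop("water and fat images must share one grid", call. = FALSE)
  out <- (water_std$data + alpha * fat_std$data) / (1 + alpha)
  volume(out, water_std$spacing, water_std$origin, water_std$direction,
         "MR_WFE")
}

#' Reduce MR intensity inhomogeneity
#'
#' Estimates a smooth multiplicative gain per sagittal slice (first array
#' axis) by alternating fuzzy-membership / class-center updates with a
#' weighted least-squares fit of a low-order 2-D polynomial gain that
#' minimizes \eqn{\sum_k \sum_x u_k^2 (I(x) - b(x) c_k)^2}. The gain is
#' normalized to mean 1 per slice, so the global intensity scale is
#' preserved, and the corrected image is `I / b`.
#'
#' @param v MR `masct_volume` with non-negative intensities.
#' @param basis_order polynomial order of the per-slice gain (default 2).
#' @param k number of intensity classes (default 3).
#' @param tol convergence threshold on the class centers.
#' @param max_iter alternation iterations per slice (default 20).
#' @param seed seed for the FCM center initialization.
#' @return list with `corrected` (`masct_volume`) and `bias` (class
#'   `masct_bias`: positive gain array plus `basis_order`).
#' @export
correct_bias <- function(v, basis_order = 2, k = 3, tol = 1e-4, max_iter = 20,
                         seed = 1) {
  if (!v$modality %in% c("MR_WATER", "MR_FAT", "MR_WFE"))
    stop("bias correction expects an MR volume", call. = FALSE)
  if (min(v$data) < 0)
    stop("bias correction expects non-negative intensities", call. = FALSE)
  d <- dim(v$data)
  bias <- array(1, d)
  # polynomial basis on the in-slice (y, z) plane, coordinates in [-1, 1]
  yy <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
  zz <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
  gy <- rep(yy, times = d[3])
  gz <- rep(zz, each = d[2])
  phi <- do.call(cbind, lapply(0:basis_order, function(p) {
    do.call(cbind, lapply(0:(basis_order - p), function(q) gy^p * gz^q))
  }))
  skipped <- 0L
  for (i in seq_len(d[1])) {
    I <- as.vector(v$data[i, , ])
    if (all(I == 0)) { skipped <- skipped + 1L; next }
    keep <- I > 0
    if (sum(keep) < ncol(phi) || length(unique(I[keep])) < k) {
      skipped <- skipped + 1L
      next
    }
    b <- rep(1, length(I))
    samp <- if (sum(keep) > 20000)
      local_seed(seed + i, I[keep][sample.int(sum(keep), 20000)]) else I[keep]
    centers <- fuzzy_c_means(samp, k, seed = seed + i, max_iter = 30)$centers
    for (it in seq_len(max_iter)) {
      d2 <- matrix(0, sum(keep), k)
      for (j in seq_len(k)) d2[, j] <- (I[keep] - b[keep] * centers[j])^2
      u2 <- memberships_from_d2(d2, 1)^2
      new_centers <- colSums(u2 * b[keep] * I[keep]) / colSums(u2 * b[keep]^2)
      wts <- as.vector(u2 %*% centers^2)
      bstar <- as.vector(u2 %*% centers) * I[keep] / pmax(wts, 1e-12)
      pk <- phi[keep, , drop = FALSE]
      coefs <- solve(crossprod(pk, wts * pk), crossprod(pk, wts * bstar))
      bfit <- as.vector(phi %*% coefs)
      b <- pmax(bfit, 0.1)
      b <- b / mean(b[keep])
      shift <- max(abs(new_centers - centers))
      centers <- sort(new_centers)
      if (shift < tol) break
    }
    bias[i, , ] <- b
  }
  if (skipped > 0)
    warning(sprintf("%d all-zero/degenerate sagittal slice(s) skipped (gain 1)",
                    skipped))
  corrected <- v$data / bias
  list(corrected = volume(corrected, v$spacing, v$origin, v$direction,
                          v$modality),
       bias = structure(list(field = bias, basis_order = basis_order),
                        class = "masct_bias"))
}
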