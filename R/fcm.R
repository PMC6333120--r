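#' Fuzzy c-means clustering of 1-D intensities
#'
#' Soft clustering minimizing \eqn{\sum_{ik} u_{ik}^m (x_i - c_k)^2} with the
#' standard alternating membership/center updates. Centers are initialized
#' with seeded k-means++ sampling so results are deterministic, and are
#' returned in ascending order with the membership columns permuted to match.
#'
#' @param samples numeric vector of intensities.
#' @param k number of clusters (>= 1, at most the number of distinct values).
#' @param fuzzifier fuzziness exponent m > 1 (m = 2 default).
#' @param tol convergence threshold on the maximum center shift.
#' @param max_iter iteration cap.
#' @param seed integer seed for center initialization.
#' @param nstart number of seeded k-means++ restarts; the run with the
#'   lowest final objective wins. More restarts guard against merge/split
#'   local optima when cluster spreads differ strongly (e.g. wide bone vs
#'   narrow fat/muscle HU classes).
#' @return list with `centers` (ascending), `memberships` (n x k rows summing
#'   to 1), `objective` (per-iteration trace, non-increasing) and `iterations`.
#' @export
fuzzy_c_means <- function(samples, k, fuzzifier = 2, tol = 1e-4,
                          max_iter = 200, seed = 1, nstart = 1) {
  x <- as.double(samples)
  if (length(x) == 0) stop("`samples` must be non-empty", call. = FALSE)
  if (anyNA(x)) stop("`samples` must not contain NA", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (fuzzifier <= 1) stop("`fuzzifier` must be > 1", call. = FALSE)
  ux <- unique(x)
  if (k > length(ux))
    stop(sprintf("degenerate input: k = %d exceeds %d distinct values",
                 k, length(ux)), call. = FALSE)
  if (k == 1) {
    return(list(centers = mean(x),
                memberships = matrix(1, length(x), 1),
                objective = sum((x - mean(x))^2), iterations = 0L))
  }
  p <- 1 / (fuzzifier - 1)
  run_one <- function(s) {
    centers <- local_seed(s, kmeanspp_init(x, k))
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(x, centers, function(a, b) (a - b)^2)
      um <- memberships_from_d2(d2, p)^fuzzifier
      obj <- c(obj, sum(um * d2))
      new_centers <- colSums(um * x) / colSums(um)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    list(centers = centers, objective = obj)
  }
  best <- NULL
  for (r in seq_len(max(1L, nstart))) {
    cand <- run_one(seed + (r - 1L) * 101L)
    if (is.null(best) ||
        cand$objective[length(cand$objective)] <
          best$objective[length(best$objective)])
      best <- cand
  }
  ord <- order(best$centers)
  d2 <- outer(x, best$centers[ord], function(a, b) (a - b)^2)
  u <- memberships_from_d2(d2, p)
  list(centers = best$centers[ord], memberships = u,
       objective = best$objective, iterations = length(best$objective))
}

memberships_from_d2 <- function(d2, p) {
  eps <- 1e-300
  mn <- d2[, 1]
  for (j in seq_len(ncol(d2))[-1]) mn <- pmin(mn, d2[, j])
  w <- (d2 + eps)^(-p)
  u <- w / rowSums(w)
  zero_row <- which(mn < 1e-24)
  if (length(zero_row)) {
    u[zero_row, ] <- 0
    u[cbind(zero_row, max.col(-d2[zero_row, , drop = FALSE]))] <- 1
  }
  u
}

kmeanspp_init <- function(x, k) {
  n <- length(x)
  centers <- x[sample.int(n, 1)]
  d2 <- (x - centers[1])^2
  while (length(centers) < k) {
    if (sum(d2) <= 0) {
      cand <- setdiff(unique(x), centers)
      centers <- c(centers, cand[1])
    } else {
      centers <- c(centers, x[sample.int(n, 1, prob = d2)])
    }
    d2 <- pmin(d2, (x - centers[length(centers)])^2)
  }
  centers
}

#' Background (air) threshold of an MR intensity sample
#'
#' MR magnitude images of the pelvis have a dominant dark air peak. The
#' threshold is the first local minimum of the smoothed histogram after that
#' peak (the air/tissue valley). Plain Otsu thresholding is the fallback,
#' but on its own it can split bright muscle from all darker tissue instead
#' of air from body, which would drop fat from the foreground.
#'
#' @param x numeric vector of intensities.
#' @param bins histogram bin count.
#' @param smooth_window moving-average window (bins).
#' @return threshold value; samples `> threshold` are foreground.
#' @export
background_threshold <- function(x, bins = 256, smooth_window = 5) {
  r <- quantile(x, c(0.001, 0.999), names = FALSE)
  if (diff(r) <= 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = bins + 1)
  cnt <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                            1), bins), nbins = bins)
  h <- moving_average(cnt, smooth_window)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  lower <- seq_len(floor(bins / 2))
  peak <- lower[which.max(h[lower])]
  if (h[peak] < max(h) * 0.2) return(otsu_threshold(x, bins))
  for (i in seq(peak + 1, bins - 1)) {
    if (h[i] <= h[i - 1] && h[i] <= h[i + 1] && h[i] < 0.25 * h[peak])
      return(mids[i])
  }
  otsu_threshold(x, bins)
}

#' Otsu's threshold of a numeric vector
#'
#' Histogram-based threshold maximizing between-class variance; used to
#' separate image foreground (body) from the dark air background before
#' clustering MR intensities.
#'
#' @param x numeric vector.
#' @param bins histogram bin count.
#' @return threshold value; samples `> threshold` are foreground.
#' @export
otsu_threshold <- function(x, bins = 256) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = bins + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  h$mids[which.max(sigma_b)]
}
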