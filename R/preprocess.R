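#' Downscale a volume in x and y by local-mean area resampling
#'
#' Each output pixel is the area-weighted mean of the input pixels it
#' covers; z is untouched. The output extent on each scaled axis is
#' `max(1, floor(n * factor))` and the voxel calibration of y and x is
#' divided by the realized factor, so physical extents are preserved.
#'
#' @param image A [vn_volume()].
#' @param factor Scale factor in (0, 1]; 1 is the identity.
#' @return A [vn_volume()].
#' @export
downscale_xy <- function(image, factor) {
  stopifnot(inherits(image, "vn_volume"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1) {
    stop("`factor` must be a single value in (0, 1]", call. = FALSE)
  }
  if (factor == 1) return(image)
  d <- dim(image$voxels)
  ny_out <- max(1L, floor(d[2] * factor))
  nx_out <- max(1L, floor(d[3] * factor))
  Wy <- area_resample_weights(d[2], ny_out)
  Wx <- area_resample_weights(d[3], nx_out)
  out <- array(0, c(d[1], ny_out, nx_out))
  for (k in seq_len(d[1])) {
    out[k, , ] <- Wy %*% image$voxels[k, , ] %*% t(Wx)
  }
  vs <- image$voxel_size
  vs[2] <- vs[2] * d[2] / ny_out
  vs[3] <- vs[3] * d[3] / nx_out
  vn_volume(out, bit_depth = image$bit_depth, voxel_size = vs)
}

# m x n row-stochastic matrix: output cell j covers input interval
# [(j-1)*s, j*s) with s = n/m; weight = overlap length / s
area_resample_weights <- function(n, m) {
  s <- n / m
  W <- matrix(0, m, n)
  for (j in seq_len(m)) {
    lo <- (j - 1) * s
    hi <- j * s
    i_lo <- floor(lo) + 1
    i_hi <- min(n, ceiling(hi))
    for (i in i_lo:i_hi) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[j, i] <- ov / s
    }
  }
  W
}

#' Linear brightness windowing
#'
#' Maps the intensity window `[low, high]` linearly onto the full bit-depth
#' range with clipping: values at or below `low` become 0, values at or
#' above `high` become `2^bit_depth - 1`. Output intensities are rounded to
#' integers with `round()` (round-half-to-even). Used to lift weakly
#' fluorescing vessels above the segmentation threshold.
#'
#' @param image A [vn_volume()].
#' @param low,high Window bounds, `low < high`.
#' @return A [vn_volume()].
#' @export
rescale_brightness <- function(image, low, high) {
  stopifnot(inherits(image, "vn_volume"))
  if (low >= high) stop("`low` must be smaller than `high`", call. = FALSE)
  maxval <- 2^image$bit_depth - 1
  v <- (image$voxels - low) / (high - low)
  v[v < 0] <- 0
  v[v > 1] <- 1
  out <- round(v * maxval)
  vn_volume(out, bit_depth = image$bit_depth, voxel_size = image$voxel_size)
}

#' Per-slice rolling-ball background subtraction
#'
#' Estimates the background of every z-slice by grayscale opening with a
#' non-flat hemispherical (rolling-ball) structuring function of the given
#' radius and subtracts it, clipping at 0. Flat backgrounds are removed
#' exactly; features narrower than the ball are preserved.
#'
#' @param image A [vn_volume()].
#' @param radius Ball radius in pixels, > 0.
#' @return A [vn_volume()].
#' @export
subtract_background <- function(image, radius) {
  stopifnot(inherits(image, "vn_volume"))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("`radius` must be a single positive value", call. = FALSE)
  }
  d <- dim(image$voxels)
  out <- array(0, d)
  for (k in seq_len(d[1])) {
    slice <- matrix(image$voxels[k, , ], d[2], d[3])
    bg <- .cpp_rolling_ball_slice(slice, radius)
    res <- slice - bg
    res[res < 0] <- 0
    out[k, , ] <- res
  }
  vn_volume(out, bit_depth = image$bit_depth, voxel_size = image$voxel_size)
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves the volume with a normalized separable Gaussian kernel, one
#' sigma per axis (voxels), with half-sample reflective boundary handling.
#' A sigma of 0 disables smoothing on that axis. Kernel support is
#' `ceiling(4 * sigma)` on each side.
#'
#' @param image A [vn_volume()].
#' @param sigma Sigma in voxels: scalar or `(sz, sy, sx)`.
#' @return A [vn_volume()].
#' @export
gaussian_blur_3d <- function(image, sigma) {
  stopifnot(inherits(image, "vn_volume"))
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (length(sigma) != 3 || anyNA(sigma) || any(sigma < 0)) {
    stop("`sigma` must be 1 or 3 non-negative values", call. = FALSE)
  }
  v <- image$voxels
  d <- dim(v)
  for (axis in 1:3) {
    if (sigma[axis] == 0) next
    k <- gaussian_kernel(sigma[axis])
    v <- .cpp_conv1d(v, as.integer(d), k, axis - 1L)
  }
  dim(v) <- d
  maxval <- 2^image$bit_depth - 1
  v[v < 0] <- 0
  v[v > maxval] <- maxval
  vn_volume(v, bit_depth = image$bit_depth, voxel_size = image$voxel_size)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Run the full preprocessing stage
#'
#' Fixed order: downscale -> brightness windowing -> optional background
#' subtraction -> Gaussian smoothing. The order is not configurable, which
#' removes a silent source of irreproducibility.
#'
#' @param image A [vn_volume()].
#' @param params A [vn_params()].
#' @return A preprocessed [vn_volume()].
#' @export
preprocess_volume <- function(image, params = vn_params()) {
  stopifnot(inherits(image, "vn_volume"), inherits(params, "vn_params"))
  out <- downscale_xy(image, params$scale_xy)
  high <- params$brightness_max
  if (is.null(high)) high <- 2^image$bit_depth - 1
  out <- rescale_brightness(out, params$brightness_min, high)
  if (!is.null(params$background_radius)) {
    out <- subtract_background(out, params$background_radius)
  }
  gaussian_blur_3d(out, params$gaussian_sigma)
}
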