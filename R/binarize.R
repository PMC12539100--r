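#' Yen's automatic threshold
#'
#' Builds a 256-bin histogram spanning the observed intensity range of the
#' volume and returns the bin boundary that maximizes Yen's
#' maximum-correlation criterion. Foreground is defined as voxels strictly
#' above the returned threshold. Ties in the criterion are broken towards
#' the lowest threshold, which makes the result deterministic.
#'
#' @param image A [vn_volume()] (or bare numeric array) with at least two
#'   distinct intensity values.
#' @return The threshold intensity (length-1 numeric).
#' @references Yen, Chang & Chang (1995), "A new criterion for automatic
#'   multilevel thresholding", IEEE Trans. Image Processing 4(3).
#' @export
yen_threshold <- function(image) {
  v <- if (inherits(image, "vn_volume")) image$voxels else image
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("constant image: no threshold exists", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(
    pmin(256L, findInterval(v, breaks, rightmost.closed = TRUE)),
    nbins = 256L
  )
  k <- yen_cut_from_histogram(h)
  breaks[k + 1]
}

# index (1..255) of the optimal cut after bin k, from bin counts
yen_cut_from_histogram <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  total_sq <- P1sq[256]
  k <- 1:255
  crit <- rep(-Inf, 255)
  valid <- P1[k] > 0 & P1[k] < 1
  kk <- k[valid]
  p2sq <- total_sq - P1sq[kk]
  # quadratic-entropy (maximum-correlation) criterion; zero tail mass in
  # either class gives -Inf and is never selected
  crit[valid] <- ifelse(
    P1sq[kk] > 0 & p2sq > 0,
    -log(P1sq[kk] * p2sq) + 2 * log(P1[kk] * (1 - P1[kk])),
    -Inf
  )
  which.max(crit)  # first maximum = lowest threshold on ties
}

#' Remove small particles from a binary mask
#'
#' By default removes, per z-slice, 2D 8-connected foreground components
#' with area below `min_pixels` — the slice-wise semantics of the classic
#' particle-analysis step on image stacks. With `particles_3d = TRUE`,
#' removal operates on 3D 26-connected components (volume in voxels).
#' `min_pixels = 0` is the identity; the operation only ever deletes
#' foreground.
#'
#' @param binary A [vn_binary()].
#' @param min_pixels Minimum component area (2D) or volume (3D).
#' @param particles_3d Use volumetric components instead of slice-wise.
#' @return A [vn_binary()].
#' @export
remove_small_particles <- function(binary, min_pixels, particles_3d = FALSE) {
  stopifnot(inherits(binary, "vn_binary"))
  if (!is.numeric(min_pixels) || length(min_pixels) != 1 || min_pixels < 0) {
    stop("`min_pixels` must be a single non-negative value", call. = FALSE)
  }
  if (min_pixels == 0) return(binary)
  mask <- binary$mask
  d <- dim(mask)
  if (particles_3d) {
    labels <- .cpp_label(mask, as.integer(d), 26L)
    sizes <- tabulate(labels[labels > 0])
    kill <- which(sizes < min_pixels)
    mask[labels %in% kill] <- FALSE
  } else {
    for (k in seq_len(d[1])) {
      sl <- array(mask[k, , ], c(1L, d[2], d[3]))
      labels <- .cpp_label(sl, c(1L, d[2], d[3]), 26L)  # 26 in-plane == 2D 8
      sizes <- tabulate(labels[labels > 0])
      kill <- which(sizes < min_pixels)
      if (length(kill)) {
        sl[labels %in% kill] <- FALSE
        mask[k, , ] <- sl[1, , ]
      }
    }
  }
  vn_binary(mask, binary$voxel_size)
}

#' 3D closing by maximum then minimum filtering
#'
#' Applies a 3D maximum filter (dilation) with an ellipsoidal neighbourhood
#' of per-axis radii `max_radius`, followed by a 3D minimum filter
#' (erosion) with `min_radius`. Equal radii realize a morphological
#' closing, which bridges fragmentation gaps up to twice the radius.
#' Out-of-volume voxels count as background for the maximum filter and as
#' foreground for the minimum filter, so closing never shrinks objects at
#' the volume border.
#'
#' @param binary A [vn_binary()].
#' @param max_radius,min_radius Per-axis radii `(rz, ry, rx)` in voxels;
#'   scalars broadcast.
#' @return A [vn_binary()].
#' @export
close_3d <- function(binary, max_radius, min_radius = max_radius) {
  stopifnot(inherits(binary, "vn_binary"))
  expand <- function(r) {
    r <- as.integer(r)
    if (length(r) == 1) r <- rep(r, 3L)
    if (length(r) != 3 || anyNA(r) || any(r < 0)) {
      stop("radii must be 1 or 3 non-negative integers", call. = FALSE)
    }
    r
  }
  rmax <- expand(max_radius)
  rmin <- expand(min_radius)
  d <- as.integer(dim(binary$mask))
  m <- binary$mask
  if (any(rmax > 0)) m <- .cpp_minmax(m, d, rmax, TRUE, 0L)
  if (any(rmin > 0)) m <- .cpp_minmax(m, d, rmin, FALSE, 0L)
  dim(m) <- d
  vn_binary(m, binary$voxel_size)
}

#' Fill enclosed cavities in a binary volume
#'
#' Every 6-connected background component that does not touch the volume
#' border becomes foreground; border-connected background is untouched.
#' Enclosed cavities would otherwise survive thinning as closed shells and
#' contaminate the skeleton with artifactual loops.
#'
#' @param binary A [vn_binary()].
#' @return A [vn_binary()].
#' @export
fill_holes_3d <- function(binary) {
  stopifnot(inherits(binary, "vn_binary"))
  mask <- binary$mask
  d <- as.integer(dim(mask))
  bg <- !mask
  labels <- .cpp_label(bg, d, 6L)
  border_labels <- unique(c(
    labels[c(1, d[1]), , ], labels[, c(1, d[2]), ], labels[, , c(1, d[3])]
  ))
  border_labels <- border_labels[border_labels > 0]
  fill <- bg & !(labels %in% border_labels)
  dim(fill) <- d
  vn_binary(mask | fill, binary$voxel_size)
}

#' Full binarization stage
#'
#' Applies, in fixed order: Yen thresholding (foreground strictly above
#' threshold) -> small-particle removal -> 3D closing (maximum then
#' minimum filter) -> hole filling.
#'
#' @param image A preprocessed [vn_volume()].
#' @param params A [vn_params()].
#' @return A [vn_binary()].
#' @export
binarize_volume <- function(image, params = vn_params()) {
  stopifnot(inherits(image, "vn_volume"), inherits(params, "vn_params"))
  thr <- yen_threshold(image)
  b <- vn_binary(image$voxels > thr, image$voxel_size)
  b <- remove_small_particles(b, params$particle_min_size, params$particles_3d)
  b <- close_3d(b, params$closing_max_radius, params$closing_min_radius)
  fill_holes_3d(b)
}

#' Foreground volume fraction
#'
#' Foreground voxel count divided by total voxel count of the imaged grid.
#'
#' @param binary A [vn_binary()].
#' @return A fraction in \[0, 1\].
#' @export
volume_fraction <- function(binary) {
  stopifnot(inherits(binary, "vn_binary"))
  mean(binary$mask)
}
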