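#' Calibrated 3D image volumes
#'
#' A `vn_volume` holds a single-channel 3D intensity grid with physical
#' voxel calibration; a `vn_binary` holds a 3D logical mask with the same
#' calibration. Voxels are indexed `[z, y, x]` (1-based in R), with `dim =
#' c(nz, ny, nx)`: the z index runs over TIFF pages, so page `k` of a stack
#' is `voxels[k, , ]`.
#'
#' @param voxels Numeric 3D array, dim `c(nz, ny, nx)`, intensities within
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Integer, 8 or 16.
#' @param voxel_size Numeric length-3 vector `(dz, dy, dx)` in micrometres
#'   per voxel; all components must be positive.
#' @return An object of class `vn_volume`.
#' @examples
#' v <- vn_volume(array(0, c(4, 8, 8)), bit_depth = 8, voxel_size = c(2, 1, 1))
#' dim(v$voxels)
#' @export
vn_volume <- function(voxels, bit_depth = 8L, voxel_size = c(1, 1, 1)) {
  voxels <- as_array3d(voxels)
  bit_depth <- as.integer(bit_depth)
  voxel_size <- check_voxel_size(voxel_size)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (length(voxels) == 0) stop("voxel grid must be non-empty", call. = FALSE)
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1) {
    stop("intensities must lie within [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(
    list(voxels = voxels, bit_depth = bit_depth, voxel_size = voxel_size),
    class = "vn_volume"
  )
}

#' @rdname vn_volume
#' @param mask Logical 3D array, dim `c(nz, ny, nx)`.
#' @export
vn_binary <- function(mask, voxel_size = c(1, 1, 1)) {
  mask <- as_array3d(mask)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  structure(
    list(mask = mask, voxel_size = check_voxel_size(voxel_size)),
    class = "vn_binary"
  )
}

as_array3d <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3) {
    stop("expected a 3D array with dim (nz, ny, nx)", call. = FALSE)
  }
  x
}

check_voxel_size <- function(vs) {
  vs <- as.numeric(vs)
  if (length(vs) == 1) vs <- rep(vs, 3)
  if (length(vs) != 3 || anyNA(vs) || any(vs <= 0)) {
    stop("`voxel_size` must be 3 positive values (dz, dy, dx) in um",
         call. = FALSE)
  }
  names(vs) <- c("dz", "dy", "dx")
  vs
}

#' @export
print.vn_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<vn_volume> %d x %d x %d (z,y,x), %d-bit, voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$bit_depth,
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' @export
print.vn_binary <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<vn_binary> %d x %d x %d (z,y,x), %d foreground voxels (%.2f%%)\n",
    d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)
  ))
  invisible(x)
}

# shared helpers -------------------------------------------------------------

dim3 <- function(x) {
  if (inherits(x, "vn_volume")) dim(x$voxels)
  else if (inherits(x, c("vn_binary", "vn_skeleton"))) dim(x$mask)
  else dim(x)
}

#' Physical volume of the imaged grid in cubic millimetres
#'
#' `(nz*dz) * (ny*dy) * (nx*dx) * 1e-9` with calibration in micrometres.
#'
#' @param x A `vn_volume`, `vn_binary` or `vn_skeleton`.
#' @return Volume in mm^3.
#' @export
image_volume_mm3 <- function(x) {
  d <- dim3(x)
  vs <- x$voxel_size
  prod(d * vs) * 1e-9
}
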