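#' Pipeline parameters
#'
#' Bundles every tunable of the processing pipeline. Defaults are chosen to
#' give reasonable segmentation on typical confocal vasculature stacks and
#' on the bundled phantoms; real data usually needs per-dataset adjustment
#' (see the methods vignette for diagnostics).
#'
#' @param brightness_min,brightness_max Intensity window for the linear
#'   brightness adjustment; values at or below `brightness_min` map to 0,
#'   values at or above `brightness_max` map to full scale. `NULL` for
#'   `brightness_max` means the bit-depth maximum.
#' @param background_radius Rolling-ball radius in pixels for per-slice
#'   background subtraction; `NULL` (default) skips the step.
#' @param gaussian_sigma Gaussian smoothing sigma in voxels, one value per
#'   axis `(sz, sy, sx)`; a scalar is broadcast to all three axes. 0
#'   disables smoothing on that axis.
#' @param particle_min_size Minimum 2D particle area (pixels, per z-slice);
#'   smaller 8-connected components are removed from the binary mask.
#' @param particles_3d If `TRUE`, particle removal uses 3D 26-connected
#'   components (volume in voxels) instead of the slice-wise 2D semantics.
#' @param closing_max_radius,closing_min_radius Per-axis radii
#'   `(rz, ry, rx)` in voxels of the ellipsoidal 3D maximum (dilation) and
#'   minimum (erosion) filters that bridge fragmented vessels.
#' @param prune_length Terminal skeleton branches shorter than this are
#'   removed (single pass); units are voxels unless `prune_calibrated`.
#' @param prune_calibrated If `TRUE`, `prune_length` is interpreted in
#'   micrometres of calibrated path length.
#' @param prune_iterative If `TRUE`, pruning repeats until no terminal
#'   branch is below threshold (default: one pass).
#' @param scale_xy Downscaling factor in (0, 1] applied to x and y before
#'   everything else; 1 disables.
#' @return An object of class `vn_params`.
#' @examples
#' p <- vn_params(gaussian_sigma = 2, prune_length = 5)
#' p$gaussian_sigma
#' @export
vn_params <- function(brightness_min = 0,
                      brightness_max = NULL,
                      background_radius = NULL,
                      gaussian_sigma = c(1.5, 1.5, 1.5),
                      particle_min_size = 5,
                      particles_3d = FALSE,
                      closing_max_radius = c(1, 1, 1),
                      closing_min_radius = c(1, 1, 1),
                      prune_length = 5,
                      prune_calibrated = FALSE,
                      prune_iterative = FALSE,
                      scale_xy = 1) {
  expand3 <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) == 1) v <- rep(v, 3)
    if (length(v) != 3 || anyNA(v) || any(v < 0)) {
      stop(sprintf("`%s` must be 1 or 3 non-negative values", what),
           call. = FALSE)
    }
    v
  }
  p <- list(
    brightness_min = as.numeric(brightness_min),
    brightness_max = if (is.null(brightness_max)) NULL else as.numeric(brightness_max),
    background_radius = if (is.null(background_radius)) NULL else as.numeric(background_radius),
    gaussian_sigma = expand3(gaussian_sigma, "gaussian_sigma"),
    particle_min_size = as.numeric(particle_min_size),
    particles_3d = isTRUE(particles_3d),
    closing_max_radius = expand3(closing_max_radius, "closing_max_radius"),
    closing_min_radius = expand3(closing_min_radius, "closing_min_radius"),
    prune_length = as.numeric(prune_length),
    prune_calibrated = isTRUE(prune_calibrated),
    prune_iterative = isTRUE(prune_iterative),
    scale_xy = as.numeric(scale_xy)
  )
  if (!is.null(p$brightness_max) && p$brightness_min >= p$brightness_max) {
    stop("`brightness_min` must be smaller than `brightness_max`", call. = FALSE)
  }
  if (!is.null(p$background_radius) && p$background_radius <= 0) {
    stop("`background_radius` must be positive (or NULL to skip)", call. = FALSE)
  }
  if (p$particle_min_size < 0) stop("`particle_min_size` must be >= 0", call. = FALSE)
  if (p$prune_length < 0) stop("`prune_length` must be >= 0", call. = FALSE)
  if (p$scale_xy <= 0 || p$scale_xy > 1) {
    stop("`scale_xy` must be in (0, 1]", call. = FALSE)
  }
  structure(p, class = "vn_params")
}

#' @export
print.vn_params <- function(x, ...) {
  cat("<vn_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Read pipeline parameters from a YAML file
#'
#' Reads a flat YAML mapping whose keys are the arguments of [vn_params()];
#' absent keys fall back to the defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A [vn_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(vn_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown parameter(s) in %s: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  do.call(vn_params, vals)
}
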