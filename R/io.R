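#' Read a calibrated z-stack from a multi-page TIFF
#'
#' Reads a single-channel multi-page TIFF into a [vn_volume()]. Voxel
#' calibration is resolved with the precedence: explicit
#' `calibration_override` > ImageJ-style TIFF metadata (a `spacing=` entry
#' in the ImageDescription plus the x/y resolution tags) > a JSON sidecar
#' `<path>.json` as written by [write_volume()]. If none of these yields a
#' calibration, reading fails: network measurements need physical units.
#'
#' @param path Path to a TIFF file.
#' @param calibration_override Optional `(dz, dy, dx)` in micrometres,
#'   overriding any stored calibration.
#' @return A [vn_volume()].
#' @seealso [write_volume()], [discover_batch()]
#' @export
read_volume <- function(path, calibration_override = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  if (length(dim(first)) == 3 && dim(first)[3] > 1) {
    stop("multi-channel TIFF input is not supported; supply a single-channel stack",
         call. = FALSE)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  })
  bits <- attr(first, "bits.per.sample")
  bit_depth <- if (is.null(bits) || bits <= 8) 8L else 16L

  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  vox <- array(0, c(nz, ny, nx))
  for (k in seq_len(nz)) vox[k, , ] <- pages[[k]]

  vs <- calibration_override
  if (is.null(vs)) vs <- calibration_from_tiff_info(first)
  if (is.null(vs)) vs <- calibration_from_sidecar(path)
  if (is.null(vs)) {
    stop(sprintf(
      "no voxel calibration found for %s; pass `calibration_override`", path
    ), call. = FALSE)
  }
  vn_volume(vox, bit_depth = bit_depth, voxel_size = vs)
}

calibration_from_tiff_info <- function(page) {
  desc <- attr(page, "description")
  xres <- attr(page, "x.resolution")
  if (is.null(desc) || is.null(xres) || !is.finite(xres) || xres <= 0) {
    return(NULL)
  }
  m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
  if (length(m) < 2) return(NULL)
  dz <- as.numeric(m[2])
  dx <- 1 / xres
  yres <- attr(page, "y.resolution")
  dy <- if (!is.null(yres) && is.finite(yres) && yres > 0) 1 / yres else dx
  if (!is.finite(dz) || dz <= 0) return(NULL)
  c(dz, dy, dx)
}

calibration_from_sidecar <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) return(NULL)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vs <- meta$voxel_size_um
  if (is.null(vs) || length(vs) != 3) return(NULL)
  as.numeric(vs)
}

#' Write a volume or binary mask as a multi-page TIFF
#'
#' Intensity volumes are stored at their native bit depth; binary masks are
#' stored 8-bit with foreground = 255 and background = 0. The voxel
#' calibration (and bit depth) is recorded in a JSON sidecar `<path>.json`,
#' which [read_volume()] picks up again, so write/read round-trips preserve
#' both voxels and calibration.
#'
#' @param image A [vn_volume()] or [vn_binary()].
#' @param path Output TIFF path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("output directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  if (inherits(image, "vn_binary") || inherits(image, "vn_skeleton")) {
    vox <- array(ifelse(image$mask, 255, 0), dim3(image))
    bit_depth <- 8L
  } else if (inherits(image, "vn_volume")) {
    vox <- image$voxels
    bit_depth <- image$bit_depth
  } else {
    stop("`image` must be a vn_volume, vn_binary or vn_skeleton", call. = FALSE)
  }
  maxval <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(vox)[1]), function(k) {
    matrix(vox[k, , ] / maxval, nrow = dim(vox)[2], ncol = dim(vox)[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth,
                  compression = "LZW")
  jsonlite::write_json(
    list(voxel_size_um = unname(image$voxel_size), bit_depth = bit_depth),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Discover input stacks for a batch run
#'
#' Lists files in `directory` matching a filename glob, in deterministic
#' lexicographic order (C locale), so repeated batch runs see the same
#' ordering.
#'
#' @param directory Directory to search.
#' @param pattern Filename glob, e.g. `"*.tif"`.
#' @return Character vector of full paths, lexicographically sorted.
#' @export
discover_batch <- function(directory, pattern = "*.tif") {
  if (!dir.exists(directory)) {
    stop(sprintf("directory not found: %s", directory), call. = FALSE)
  }
  rx <- utils::glob2rx(pattern)
  files <- list.files(directory, pattern = rx, full.names = TRUE)
  files[order(basename(files), method = "radix")]
}
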