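#' Network measurements for one image
#'
#' Produces the seven per-image measurements of the pipeline: volume
#' fraction of the binary mask, network length (skeleton voxel count, raw
#' and per mm^3 of imaged volume), numbers of skeletons, segments,
#' junctions and end points, and the list of per-segment calibrated
#' lengths. A calibrated total network length in micrometres (sum of
#' segment lengths) is included as an extra column for cross-study use.
#'
#' @param binary The [vn_binary()] mask the skeleton was derived from.
#' @param graph The `vn_graph` from [extract_graph()] (after pruning).
#' @param skeleton The matching `vn_skeleton`.
#' @param image_id Identifier recorded in the output row.
#' @return A one-row tibble of class `vn_measurements` with a
#'   `segment_lengths` list-column.
#' @export
measure_network <- function(binary, graph, skeleton, image_id = "image") {
  stopifnot(inherits(binary, "vn_binary"), inherits(graph, "vn_graph"),
            inherits(skeleton, "vn_skeleton"))
  if (!identical(dim(binary$mask), dim(skeleton$mask))) {
    stop("binary and skeleton shapes differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(unname(binary$voxel_size),
                        unname(skeleton$voxel_size)))) {
    stop("binary and skeleton calibrations differ", call. = FALSE)
  }
  vol_mm3 <- image_volume_mm3(binary)
  seg_lengths <- vapply(graph$segments, function(s) s$length_um, 1.0)
  out <- tibble::tibble(
    image_id = image_id,
    volume_fraction = volume_fraction(binary),
    network_length_voxels = sum(skeleton$mask),
    network_length_per_mm3 = sum(skeleton$mask) / vol_mm3,
    network_length_um = sum(seg_lengths),
    n_skeletons = unname(graph$counts["skeletons"]),
    n_segments = unname(graph$counts["segments"]),
    n_junctions = unname(graph$counts["junctions"]),
    n_endpoints = unname(graph$counts["endpoints"]),
    image_volume_mm3 = vol_mm3,
    segment_lengths = list(seg_lengths)
  )
  class(out) <- c("vn_measurements", class(out))
  out
}

#' Normalize network counts to the imaged volume
#'
#' Divides each count column by the imaged volume in mm^3, producing
#' per-mm^3 densities. Densities are computed against the full imaged
#' bounding volume.
#'
#' @param measurements A `vn_measurements` tibble from [measure_network()]
#'   (or [run_batch()]).
#' @param image_volume_mm3 Optional volume override; defaults to the
#'   `image_volume_mm3` column.
#' @return A tibble with `*_per_mm3` columns for the four counts.
#' @export
normalize_counts <- function(measurements, image_volume_mm3 = NULL) {
  vol <- if (is.null(image_volume_mm3)) measurements$image_volume_mm3
         else image_volume_mm3
  if (any(vol <= 0)) stop("image volume must be positive", call. = FALSE)
  out <- measurements
  out$n_skeletons_per_mm3 <- out$n_skeletons / vol
  out$n_segments_per_mm3 <- out$n_segments / vol
  out$n_junctions_per_mm3 <- out$n_junctions / vol
  out$n_endpoints_per_mm3 <- out$n_endpoints / vol
  out
}

#' Long table of per-segment lengths
#'
#' @param measurements A `vn_measurements` tibble.
#' @return A tibble with columns `image_id`, `segment_id`, `length_um`.
#' @export
segment_length_table <- function(measurements) {
  purrr::map2_dfr(
    measurements$image_id, measurements$segment_lengths,
    function(id, lens) {
      tibble::tibble(
        image_id = id,
        segment_id = seq_along(lens),
        length_um = as.numeric(lens)
      )
    }
  )
}
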