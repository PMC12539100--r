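#' Medial-axis thinning of a binary volume
#'
#' Reduces the mask to a one-voxel-thick centerline by iterative deletion
#' of simple points: six directional border-peeling subiterations per
#' cycle, candidates re-checked and deleted sequentially in a fixed
#' (z, y, x) scan order. Deletion of simple points preserves the number of
#' 26-connected components, tunnels and cavities exactly, and voxels with
#' at most one foreground neighbour (line ends) are never deleted.
#'
#' @param binary A [vn_binary()].
#' @return A `vn_skeleton`: the thinned mask plus per-voxel classes
#'   (see [classify_skeleton_voxels()]).
#' @export
thin_3d <- function(binary) {
  stopifnot(inherits(binary, "vn_binary"))
  d <- as.integer(dim(binary$mask))
  m <- .cpp_thin3d(binary$mask, d)
  dim(m) <- d
  new_skeleton(m, binary$voxel_size)
}

new_skeleton <- function(mask, voxel_size) {
  structure(
    list(mask = mask, classes = classify_skeleton_voxels(mask),
         voxel_size = check_voxel_size(voxel_size)),
    class = "vn_skeleton"
  )
}

#' @export
print.vn_skeleton <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<vn_skeleton> %d x %d x %d (z,y,x), %d voxels (%d end, %d slab, %d junction)\n",
    d[1], d[2], d[3], sum(x$mask),
    sum(x$classes == 1L), sum(x$classes == 2L), sum(x$classes == 3L)
  ))
  invisible(x)
}

#' Classify skeleton voxels by neighbour count
#'
#' Classes follow the usual skeleton-analysis convention, by the number of
#' foreground 26-neighbours within the mask: at most 1 -> end point
#' (isolated voxels included), exactly 2 -> slab, 3 or more -> junction.
#'
#' @param mask Logical 3D array (a thinning output).
#' @return Integer array: 0 background, 1 end, 2 slab, 3 junction.
#' @export
classify_skeleton_voxels <- function(mask) {
  mask <- as_mask(mask)
  d <- as.integer(dim(mask))
  cnt <- .cpp_neighbor_count(mask, d)
  cls <- array(0L, d)
  cls[mask & cnt <= 1L] <- 1L
  cls[mask & cnt == 2L] <- 2L
  cls[mask & cnt >= 3L] <- 3L
  cls
}

# adjacency among foreground voxels: returns list(idx = linear indices,
# coords = n x 3, nbrs = list of integer neighbour ids)
skeleton_adjacency <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  coords <- arrayInd(idx, d)
  id_arr <- array(0L, d)
  id_arr[idx] <- seq_len(n)
  from <- integer(0); to <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nz <- coords[, 1] + dz; ny <- coords[, 2] + dy; nx <- coords[, 3] + dx
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    lin <- nz[ok] + d[1] * ((ny[ok] - 1) + d[2] * (nx[ok] - 1))
    nbid <- id_arr[lin]
    hit <- nbid > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nbid[hit])
  }
  nbrs <- vector("list", n)
  if (length(from)) {
    sp <- split(to, from)
    nbrs[as.integer(names(sp))] <- lapply(sp, sort)
  }
  nbrs[vapply(nbrs, is.null, logical(1))] <- list(integer(0))
  list(idx = idx, coords = coords, nbrs = nbrs, n = n)
}

#' Decompose a skeleton into its graph of segments
#'
#' Merges 26-adjacent junction voxels into junction nodes (so a thick
#' crossing counts once), walks slab chains between terminal voxels to
#' enumerate segments, and labels 26-connected components as skeletons. A
#' segment terminates in two junction nodes, two end points, or one of
#' each; closed slab rings with no terminal voxel yield one loop segment;
#' an isolated voxel is one zero-length segment. Per-segment lengths are
#' the summed Euclidean distances of consecutive voxel centres in
#' calibrated micrometres.
#'
#' @param skeleton A `vn_skeleton` from [thin_3d()].
#' @return A `vn_graph` with elements `segments` (list), `counts` (named
#'   vector: skeletons, segments, junctions, endpoints) and the junction /
#'   endpoint coordinates; [tidy()] gives a per-segment tibble.
#' @export
extract_graph <- function(skeleton) {
  stopifnot(inherits(skeleton, "vn_skeleton"))
  mask <- skeleton$mask
  cls <- skeleton$classes
  vs <- skeleton$voxel_size
  d <- dim(mask)

  adj <- skeleton_adjacency(mask)
  n <- adj$n
  if (n == 0) {
    return(new_graph(list(), 0L, 0L, matrix(numeric(0), 0, 3),
                     list(), integer(0), vs))
  }
  vclass <- cls[adj$idx]
  comp <- .cpp_label(mask, as.integer(d), 26L)[adj$idx]
  n_skeletons <- max(comp)

  # junction clusters
  jmask <- array(FALSE, d)
  jmask[adj$idx[vclass == 3L]] <- TRUE
  jlab_arr <- .cpp_label(jmask, as.integer(d), 26L)
  jcluster <- jlab_arr[adj$idx]          # 0 for non-junction voxels
  n_junctions <- max(0L, max(jcluster))
  clusters <- split(seq_len(n)[jcluster > 0], jcluster[jcluster > 0])

  terminal <- vclass != 2L               # ends and junction voxels
  endpoints_id <- which(vclass == 1L)

  segments <- list()
  visited <- logical(n)                  # slab voxels consumed by a walk
  add_segment <- function(path_ids, kinds) {
    path <- adj$coords[path_ids, , drop = FALSE]
    segments[[length(segments) + 1L]] <<- list(
      path_ids = path_ids,
      path = path,
      length_um = segment_length(path, vs),
      end_kinds = kinds,
      end_clusters = c(jcluster[path_ids[1]], jcluster[path_ids[length(path_ids)]]),
      n_nonjunction = sum(vclass[path_ids] != 3L),
      skeleton_id = comp[path_ids[1]]
    )
  }
  kind_of <- function(v) if (vclass[v] == 3L) "junction" else "end"

  for (t in which(terminal)) {
    for (nb in adj$nbrs[[t]]) {
      if (vclass[nb] == 2L) {
        if (visited[nb]) next
        path <- c(t, nb)
        visited[nb] <- TRUE
        prev <- t; cur <- nb
        repeat {
          nxt <- adj$nbrs[[cur]]
          nxt <- nxt[nxt != prev]
          # a slab has exactly two neighbours; prefer an unvisited slab or a
          # terminal (guards against revisiting on tight loops)
          if (length(nxt) > 1) nxt <- nxt[terminal[nxt] | !visited[nxt]]
          nxt <- nxt[1]
          if (is.na(nxt)) break  # degenerate chain; keep what was walked
          path <- c(path, nxt)
          if (terminal[nxt]) break
          visited[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        add_segment(path, c(kind_of(t), kind_of(path[length(path)])))
      } else if (nb > t) {
        # two adjacent terminal voxels: a two-voxel segment, unless both
        # belong to the same junction cluster (cluster-internal adjacency)
        if (vclass[t] == 3L && vclass[nb] == 3L &&
            jcluster[t] == jcluster[nb]) next
        add_segment(c(t, nb), c(kind_of(t), kind_of(nb)))
      }
    }
    if (length(adj$nbrs[[t]]) == 0) {
      # isolated voxel: a single zero-length segment
      add_segment(t, c("isolated", "isolated"))
    }
  }

  # pure slab cycles (no terminal voxel anywhere on the ring)
  for (s in which(vclass == 2L & !visited)) {
    if (visited[s]) next
    nb2 <- adj$nbrs[[s]]
    path <- c(s, nb2[1])
    visited[s] <- TRUE; visited[nb2[1]] <- TRUE
    prev <- s; cur <- nb2[1]
    repeat {
      nxt <- adj$nbrs[[cur]]
      nxt <- nxt[nxt != prev][1]
      path <- c(path, nxt)
      if (nxt == s) break
      visited[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    add_segment(path, c("loop", "loop"))
  }

  new_graph(segments, n_skeletons, n_junctions,
            adj$coords[endpoints_id, , drop = FALSE],
            lapply(clusters, function(ix) adj$coords[ix, , drop = FALSE]),
            comp, vs)
}

new_graph <- function(segments, n_skeletons, n_junctions, endpoints,
                      junction_clusters, comp, voxel_size) {
  structure(
    list(
      segments = segments,
      junction_clusters = junction_clusters,
      endpoints = endpoints,
      counts = c(
        skeletons = as.integer(n_skeletons),
        segments = length(segments),
        junctions = as.integer(n_junctions),
        endpoints = nrow(endpoints)
      ),
      voxel_size = voxel_size
    ),
    class = "vn_graph"
  )
}

#' @export
print.vn_graph <- function(x, ...) {
  cat(sprintf(
    "<vn_graph> %d skeleton(s), %d segment(s), %d junction(s), %d end point(s)\n",
    x$counts["skeletons"], x$counts["segments"],
    x$counts["junctions"], x$counts["endpoints"]
  ))
  invisible(x)
}

#' @describeIn extract_graph One row per segment: id, skeleton id, voxel
#'   count, calibrated length and terminal kinds.
#' @param x A `vn_graph`.
#' @param ... Unused.
#' @export
tidy.vn_graph <- function(x, ...) {
  if (length(x$segments) == 0) {
    return(tibble::tibble(
      segment_id = integer(0), skeleton_id = integer(0),
      n_voxels = integer(0), length_um = numeric(0),
      end_kind_1 = character(0), end_kind_2 = character(0)
    ))
  }
  tibble::tibble(
    segment_id = seq_along(x$segments),
    skeleton_id = vapply(x$segments, function(s) as.integer(s$skeleton_id), 1L),
    n_voxels = vapply(x$segments, function(s) nrow(s$path), 1L),
    length_um = vapply(x$segments, function(s) s$length_um, 1.0),
    end_kind_1 = vapply(x$segments, function(s) s$end_kinds[1], ""),
    end_kind_2 = vapply(x$segments, function(s) s$end_kinds[2], "")
  )
}

#' Calibrated length of a voxel path
#'
#' Sum of Euclidean distances between consecutive voxel centres, with each
#' axis scaled by its calibration in micrometres. Consecutive voxels must
#' be 26-adjacent.
#'
#' @param path Integer matrix, one row per voxel, columns (z, y, x).
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return Length in micrometres.
#' @export
segment_length <- function(path, voxel_size) {
  vs <- check_voxel_size(voxel_size)
  if (!is.matrix(path)) path <- matrix(path, ncol = 3)
  if (nrow(path) < 2) return(0)
  steps <- diff(path)
  if (any(abs(steps) > 1) || any(rowSums(abs(steps)) == 0)) {
    stop("consecutive path voxels must be distinct and 26-adjacent",
         call. = FALSE)
  }
  sum(sqrt((steps[, 1] * vs[1])^2 + (steps[, 2] * vs[2])^2 +
             (steps[, 3] * vs[3])^2))
}

#' Prune short terminal skeleton branches
#'
#' Single pass: every segment with at least one end-point terminus and at
#' least one junction terminus whose size (non-junction voxel count, or
#' calibrated length with `calibrated = TRUE`) is below `prune_length` is
#' deleted from the mask; junction voxels are retained. Voxels are then
#' re-classified and the graph re-extracted. Free-floating segments
#' (bounded by two end points) are never pruned, and `prune_length = 0` is
#' the identity. With `iterative = TRUE` the pass repeats until no branch
#' is below threshold.
#'
#' @param graph A `vn_graph` extracted from `skeleton`.
#' @param skeleton The matching `vn_skeleton`.
#' @param prune_length Threshold (voxels, or micrometres if `calibrated`).
#' @param calibrated Interpret `prune_length` in micrometres.
#' @param iterative Repeat until stable.
#' @return A list with elements `graph` and `skeleton`.
#' @export
prune_short_end_segments <- function(graph, skeleton, prune_length,
                                     calibrated = FALSE, iterative = FALSE) {
  stopifnot(inherits(graph, "vn_graph"), inherits(skeleton, "vn_skeleton"))
  if (prune_length < 0) stop("`prune_length` must be >= 0", call. = FALSE)
  repeat {
    kinds <- lapply(graph$segments, function(s) s$end_kinds)
    prunable <- vapply(kinds, function(k) {
      ("end" %in% k) && ("junction" %in% k)
    }, logical(1))
    size <- vapply(graph$segments, function(s) {
      if (calibrated) s$length_um else as.numeric(s$n_nonjunction)
    }, 1.0)
    kill <- prunable & size < prune_length
    if (!any(kill)) break
    mask <- skeleton$mask
    d <- dim(mask)
    for (s in graph$segments[kill]) {
      ids <- s$path
      drop <- rep(TRUE, nrow(ids))
      # retain junction voxels sitting at segment termini
      cls_at <- skeleton$classes[cbind(ids[, 1], ids[, 2], ids[, 3])]
      drop[cls_at == 3L] <- FALSE
      sel <- ids[drop, , drop = FALSE]
      if (nrow(sel)) mask[cbind(sel[, 1], sel[, 2], sel[, 3])] <- FALSE
    }
    skeleton <- new_skeleton(mask, skeleton$voxel_size)
    graph <- extract_graph(skeleton)
    if (!iterative) break
  }
  list(graph = graph, skeleton = skeleton)
}

#' Skeletonize a binary volume and extract its pruned network graph
#'
#' Convenience wrapper: [thin_3d()], [extract_graph()], then
#' [prune_short_end_segments()] with the parameters' pruning settings.
#'
#' @param binary A [vn_binary()].
#' @param params A [vn_params()].
#' @return A list with elements `skeleton` (`vn_skeleton`) and `graph`
#'   (`vn_graph`).
#' @export
skeletonize_volume <- function(binary, params = vn_params()) {
  sk <- thin_3d(binary)
  g <- extract_graph(sk)
  prune_short_end_segments(g, sk, params$prune_length,
                           calibrated = params$prune_calibrated,
                           iterative = params$prune_iterative)
}
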