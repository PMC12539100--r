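#' Specify a synthetic vessel phantom
#'
#' A phantom is a set of tubular structures drawn around centerline
#' polylines on a calibrated canvas, with confocal-like corruption:
#' smooth multiplicative intensity heterogeneity within vessels, additive
#' Gaussian noise, constant background fluorescence, optionally weak
#' (low-contrast) vessels and fragmentation gaps. The ground-truth
#' topology (skeleton, segment, junction and end-point counts and segment
#' lengths) is derived from the centerline graph itself, before any
#' corruption, so it is independent of the analysis code and can serve as
#' an oracle for the whole pipeline.
#'
#' @param canvas_shape `(nz, ny, nx)` canvas in voxels.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param paths List of centerline polylines, each an m x 3 matrix of
#'   voxel coordinates (z, y, x), 1-based; a closed path repeats its first
#'   vertex at the end. Paths sharing an endpoint vertex are connected.
#' @param radii Tube radius in voxels, one per path (or scalar).
#' @param foreground,background Mean intensities of vessel and background.
#' @param heterogeneity Amplitude in \[0, 1) of the smooth multiplicative
#'   intensity modulation within vessels (0 = homogeneous).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param gaps List of fragmentation gaps, each `c(path, position,
#'   length)`: tube voxels whose nearest centerline arc position (voxel
#'   units) falls within `[position, position + length]` are erased from
#'   the rendered image (the truth is untouched).
#' @param bit_depth 8 or 16.
#' @param seed Integer seed making the rendering deterministic.
#' @return A `vn_phantom_spec`.
#' @seealso [render_phantom()], [make_test_suite()]
#' @export
phantom_spec <- function(canvas_shape = c(96, 96, 96),
                         voxel_size = c(1, 1, 1),
                         paths = list(),
                         radii = 3,
                         foreground = 200,
                         background = 10,
                         heterogeneity = 0,
                         noise_sd = 0,
                         gaps = list(),
                         bit_depth = 8,
                         seed = 1L) {
  canvas_shape <- as.integer(canvas_shape)
  stopifnot(length(canvas_shape) == 3, all(canvas_shape >= 1))
  voxel_size <- check_voxel_size(voxel_size)
  paths <- lapply(paths, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 3, nrow(p) >= 2)
    p
  })
  if (length(radii) == 1) radii <- rep(radii, length(paths))
  stopifnot(length(radii) == length(paths))
  if (foreground <= background) {
    stop("foreground mean must exceed background mean", call. = FALSE)
  }
  if (heterogeneity < 0 || heterogeneity >= 1) {
    stop("`heterogeneity` must be in [0, 1)", call. = FALSE)
  }
  for (i in seq_along(paths)) {
    margin <- radii[i]
    p <- paths[[i]]
    for (a in 1:3) {
      if (any(p[, a] < 1 + margin - 1e-9) ||
          any(p[, a] > canvas_shape[a] - margin + 1e-9)) {
        stop(sprintf("path %d leaves the canvas margin (radius %g)", i, margin),
             call. = FALSE)
      }
    }
  }
  structure(
    list(canvas_shape = canvas_shape, voxel_size = voxel_size, paths = paths,
         radii = as.numeric(radii), foreground = foreground,
         background = background, heterogeneity = heterogeneity,
         noise_sd = noise_sd, gaps = gaps, bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "vn_phantom_spec"
  )
}

# rasterize tubes of one path; returns mask, best squared distance and the
# arc parameter (voxel units) of the nearest centerline point per voxel
render_tube_path <- function(d, verts, radius, aspect) {
  mask <- array(FALSE, d)
  bestd2 <- array(Inf, d)
  tpar <- array(NA_real_, d)
  seg_len <- sqrt(rowSums((diff(verts))^2))
  cum <- c(0, cumsum(seg_len))
  r2 <- radius^2
  for (i in seq_len(nrow(verts) - 1)) {
    p <- verts[i, ]; q <- verts[i + 1, ]
    lo <- pmax(1, floor(pmin(p, q) - radius - 1))
    hi <- pmin(d, ceiling(pmax(p, q) + radius + 1))
    zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
    g <- as.matrix(expand.grid(z = zz, y = yy, x = xx))
    dv <- (q - p) * aspect
    len2 <- sum(dv^2)
    w <- sweep(g, 2, p) * matrix(aspect, nrow(g), 3, byrow = TRUE)
    tl <- if (len2 > 0) pmin(1, pmax(0, (w %*% dv)[, 1] / len2)) else 0
    res <- w - outer(tl, dv)
    d2 <- rowSums(res^2)
    sel <- d2 <= r2
    if (!any(sel)) next
    lin <- g[sel, 1] + d[1] * ((g[sel, 2] - 1) + d[2] * (g[sel, 3] - 1))
    d2_sel <- d2[sel]
    tl_sel <- if (length(tl) == 1) rep(tl, sum(sel)) else tl[sel]
    better <- d2_sel < bestd2[lin]
    mask[lin] <- TRUE
    lin_b <- lin[better]
    bestd2[lin_b] <- d2_sel[better]
    tpar[lin_b] <- cum[i] + tl_sel[better] * seg_len[i]
  }
  list(mask = mask, bestd2 = bestd2, tpar = tpar)
}

# voxelized centerline of one path (26-connected chain)
rasterize_centerline <- function(d, verts) {
  pts <- NULL
  for (i in seq_len(nrow(verts) - 1)) {
    p <- verts[i, ]; q <- verts[i + 1, ]
    n <- max(2, ceiling(2 * sqrt(sum((q - p)^2))))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, round(outer(1 - t, p) + outer(t, q)))
  }
  pts <- pts[!duplicated(pts), , drop = FALSE]
  pts <- pts[pts[, 1] >= 1 & pts[, 1] <= d[1] &
             pts[, 2] >= 1 & pts[, 2] <= d[2] &
             pts[, 3] >= 1 & pts[, 3] <= d[3], , drop = FALSE]
  pts
}

# truth counts from the abstract centerline graph: vertices are unique path
# endpoints, one edge per path; degree-2 non-loop vertices are contracted so
# that segments match the junction/end-point bounded definition
centerline_truth <- function(spec) {
  key <- function(v) paste(round(v, 6), collapse = ",")
  ends <- lapply(spec$paths, function(p) c(key(p[1, ]), key(p[nrow(p), ])))
  verts <- unique(unlist(ends))
  vid <- setNames(seq_along(verts), verts)
  vs <- spec$voxel_size
  path_len <- vapply(spec$paths, function(p) {
    steps <- diff(p)
    sum(sqrt((steps[, 1] * vs[1])^2 + (steps[, 2] * vs[2])^2 +
               (steps[, 3] * vs[3])^2))
  }, 1.0)
  edges <- lapply(seq_along(spec$paths), function(i) {
    list(v = c(vid[[ends[[i]][1]]], vid[[ends[[i]][2]]]), len = path_len[i])
  })

  deg <- integer(length(verts))
  for (e in edges) { deg[e$v[1]] <- deg[e$v[1]] + 1L; deg[e$v[2]] <- deg[e$v[2]] + 1L }

  # components via union-find on vertices
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in edges) {
    a <- find(e$v[1]); b <- find(e$v[2])
    if (a != b) parent[a] <- b
  }
  n_skeletons <- length(unique(vapply(seq_along(verts), find, 1L)))

  # contract plain degree-2 vertices (not junctions, not loop vertices)
  repeat {
    degs <- integer(length(verts))
    selfloop <- logical(length(verts))
    for (e in edges) {
      degs[e$v[1]] <- degs[e$v[1]] + 1L
      degs[e$v[2]] <- degs[e$v[2]] + 1L
      if (e$v[1] == e$v[2]) selfloop[e$v[1]] <- TRUE
    }
    cand <- which(degs == 2L & !selfloop)
    done <- TRUE
    for (v in cand) {
      inc <- which(vapply(edges, function(e) v %in% e$v, logical(1)))
      if (length(inc) != 2) next  # single edge visiting v twice -> loop
      e1 <- edges[[inc[1]]]; e2 <- edges[[inc[2]]]
      o1 <- if (e1$v[1] == v) e1$v[2] else e1$v[1]
      o2 <- if (e2$v[1] == v) e2$v[2] else e2$v[1]
      edges[[inc[1]]] <- list(v = c(o1, o2), len = e1$len + e2$len)
      edges[[inc[2]]] <- NULL
      done <- FALSE
      break
    }
    if (done) break
  }

  list(
    n_skeletons = n_skeletons,
    n_segments = length(edges),
    n_junctions = sum(deg >= 3L),
    n_endpoints = sum(deg == 1L),
    segment_lengths = vapply(edges, function(e) e$len, 1.0)
  )
}

#' Render a phantom to an image volume and its ground truth
#'
#' Tubes are all voxels within the path radius of the centerline
#' (Euclidean distance with the calibrated axis aspect, radius in units of
#' the x voxel pitch). Vessel voxels get the foreground mean modulated by
#' a smooth seeded heterogeneity field, background voxels the background
#' mean; Gaussian noise is added and fragmentation gaps erase tube voxels
#' along the stated arc spans. Rendering is deterministic for a fixed
#' spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a [vn_volume()]) and `truth` (list:
#'   `mask`, `skeleton_gt` as [vn_binary()], exact counts, and
#'   `segment_lengths` in micrometres).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "vn_phantom_spec"))
  d <- spec$canvas_shape
  vs <- spec$voxel_size
  aspect <- vs / vs[3]
  set.seed(spec$seed)

  tubes <- lapply(seq_along(spec$paths), function(i) {
    render_tube_path(d, spec$paths[[i]], spec$radii[i], aspect)
  })
  truth_mask <- array(FALSE, d)
  for (tb in tubes) truth_mask <- truth_mask | tb$mask

  # corrupted (rendered) mask: apply fragmentation gaps per path
  rendered <- lapply(tubes, function(tb) tb$mask)
  for (gap in spec$gaps) {
    i <- gap[1]
    span <- c(gap[2], gap[2] + gap[3])
    tb <- tubes[[i]]
    cut <- tb$mask & !is.na(tb$tpar) & tb$tpar >= span[1] & tb$tpar <= span[2]
    rendered[[i]] <- rendered[[i]] & !cut
  }
  img_mask <- array(FALSE, d)
  for (m in rendered) img_mask <- img_mask | m

  field <- if (spec$heterogeneity > 0) heterogeneity_field(d, spec$heterogeneity)
           else array(1, d)
  img <- array(spec$background, d)
  img[img_mask] <- spec$foreground * field[img_mask]
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  maxval <- 2^spec$bit_depth - 1
  img <- round(pmin(maxval, pmax(0, img)))
  dim(img) <- d

  gt <- array(FALSE, d)
  for (p in spec$paths) {
    pts <- rasterize_centerline(d, p)
    gt[pts] <- TRUE
  }

  truth <- c(
    list(mask = vn_binary(truth_mask, vs),
         skeleton_gt = vn_binary(gt, vs)),
    centerline_truth(spec)
  )
  list(
    image = vn_volume(img, bit_depth = spec$bit_depth, voxel_size = vs),
    truth = truth,
    spec = spec
  )
}

# smooth multiplicative modulation field in [1 - a, 1 + a]
heterogeneity_field <- function(d, amplitude) {
  coarse <- c(4L, 4L, 4L)
  g <- array(runif(prod(coarse), -1, 1), coarse)
  up <- array(0, d)
  iz <- pmin(coarse[1], ceiling(seq_len(d[1]) / d[1] * coarse[1]))
  iy <- pmin(coarse[2], ceiling(seq_len(d[2]) / d[2] * coarse[2]))
  ix <- pmin(coarse[3], ceiling(seq_len(d[3]) / d[3] * coarse[3]))
  up[] <- g[cbind(rep(iz, times = d[2] * d[3]),
                  rep(rep(iy, each = d[1]), times = d[3]),
                  rep(ix, each = d[1] * d[2]))]
  k <- gaussian_kernel(max(2, min(d) / 8))
  for (axis in 1:3) up <- .cpp_conv1d(up, as.integer(d), k, axis - 1L)
  dim(up) <- d
  m <- max(abs(up))
  if (m > 0) up <- up / m
  1 + amplitude * up
}

#' Built-in phantom battery
#'
#' A fixed suite of seven noise-free phantoms covering the topologies the
#' pipeline must recover: straight tube, Y-bifurcation (1 junction),
#' H-network (2 junctions), two disjoint networks (2 skeletons), a closed
#' loop (cycle rank 1), a fragmented tube (two 3-voxel gaps) and a
#' low-contrast tube emulating weakly fluorescing vessels. Canvas 96^3,
#' isotropic 1 um voxels, tube radius 3.
#'
#' @param seed Integer seed propagated to each phantom's renderer.
#' @param noise_sd,heterogeneity Optional corruption applied to every
#'   phantom (defaults 0: the noise-free battery).
#' @return Named list of rendered phantoms (see [render_phantom()]).
#' @export
make_test_suite <- function(seed = 1L, noise_sd = 0, heterogeneity = 0) {
  n <- 96L
  p <- function(...) {
    matrix(c(...), ncol = 3, byrow = TRUE)
  }
  base <- function(paths, radii = 3, foreground = 200, gaps = list()) {
    phantom_spec(
      canvas_shape = c(n, n, n), voxel_size = c(1, 1, 1),
      paths = paths, radii = radii, foreground = foreground,
      background = 10, heterogeneity = heterogeneity, noise_sd = noise_sd,
      gaps = gaps, seed = seed
    )
  }
  circle <- function(z, cy, cx, r, nv = 48) {
    th <- seq(0, 2 * pi, length.out = nv + 1)
    cbind(z, cy + r * sin(th), cx + r * cos(th))
  }
  specs <- list(
    straight = base(list(p(48, 48, 8, 48, 48, 88))),
    ybranch = base(list(
      p(48, 48, 10, 48, 48, 48),
      p(48, 48, 48, 48, 28, 84),
      p(48, 48, 48, 48, 68, 84)
    )),
    hnet = base(list(
      p(48, 30, 10, 48, 30, 48),
      p(48, 30, 48, 48, 30, 86),
      p(48, 66, 10, 48, 66, 48),
      p(48, 66, 48, 48, 66, 86),
      p(48, 30, 48, 48, 66, 48)
    )),
    disjoint = base(list(
      p(48, 20, 10, 48, 20, 86),
      p(48, 70, 10, 48, 70, 45),
      p(48, 70, 45, 48, 52, 82),
      p(48, 70, 45, 48, 88, 82)
    )),
    loop = base(list(circle(48, 48, 48, 26))),
    fragmented = base(list(p(48, 48, 8, 48, 48, 88)),
                      gaps = list(c(1, 30, 3), c(1, 55, 3))),
    lowcontrast = base(list(p(48, 48, 8, 48, 48, 88)), foreground = 40)
  )
  lapply(specs, render_phantom)
}

#' Write a rendered phantom to disk
#'
#' Writes the raw image TIFF, the ground-truth centerline skeleton TIFF
#' and a one-row truth CSV (counts named like the measurement columns),
#' consumable by [run_batch()] and [evaluate_overlap()].
#'
#' @param pair A rendered phantom from [render_phantom()].
#' @param directory Output directory (must exist).
#' @param stem Filename stem.
#' @return Named character vector of the three paths written.
#' @export
write_phantom <- function(pair, directory, stem = "phantom") {
  if (!dir.exists(directory)) {
    stop(sprintf("directory not found: %s", directory), call. = FALSE)
  }
  raw_path <- file.path(directory, paste0(stem, ".tif"))
  gt_path <- file.path(directory, paste0(stem, "_gt.tif"))
  csv_path <- file.path(directory, paste0(stem, "_truth.csv"))
  write_volume(pair$image, raw_path)
  write_volume(pair$truth$skeleton_gt, gt_path)
  readr::write_csv(
    tibble::tibble(
      image_id = stem,
      n_skeletons = pair$truth$n_skeletons,
      n_segments = pair$truth$n_segments,
      n_junctions = pair$truth$n_junctions,
      n_endpoints = pair$truth$n_endpoints,
      total_segment_length_um = sum(pair$truth$segment_lengths)
    ),
    csv_path
  )
  c(raw = raw_path, gt = gt_path, truth = csv_path)
}
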