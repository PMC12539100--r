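#' Connected components of a binary volume
#'
#' Union-find style labelling of foreground voxels under 6- or
#' 26-connectivity.
#'
#' @param mask Logical 3D array (or [vn_binary()] / `vn_skeleton`).
#' @param connectivity 6 or 26.
#' @return Integer array of labels (0 = background); the number of
#'   components is `max(labels)`.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26", call. = FALSE)
  labels <- .cpp_label(mask, as.integer(dim(mask)), as.integer(connectivity))
  dim(labels) <- dim(mask)
  labels
}

#' @rdname label_components
#' @export
count_components <- function(mask, connectivity = 26) {
  max(0L, max(label_components(mask, connectivity)))
}

as_mask <- function(x) {
  if (inherits(x, c("vn_binary", "vn_skeleton"))) x <- x$mask
  x <- as_array3d(x)
  storage.mode(x) <- "logical"
  x
}

#' Euler characteristic of the cubical complex of a voxel set
#'
#' Counts the distinct vertices, edges, faces and cubes of the union of
#' unit cubes centred on foreground voxels: `chi = V - E + F - C`. This is
#' a direct combinatorial computation, independent of any labelling or
#' thinning code, and satisfies `chi = b0 - b1 + b2` (Euler-Poincare).
#'
#' @param mask Logical 3D array or [vn_binary()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  # presence grids: a cell of the complex is present if any incident voxel is
  present <- function(offsets, outdim) {
    g <- array(FALSE, outdim)
    for (o in offsets) {
      idx_out <- lapply(1:3, function(a) seq_len(d[a]) + o[a])
      g[idx_out[[1]], idx_out[[2]], idx_out[[3]]] <-
        g[idx_out[[1]], idx_out[[2]], idx_out[[3]]] | m
    }
    sum(g)
  }
  shifts <- function(axes) {
    # all 0/1 offsets over the given axes, 0 elsewhere
    grid <- expand.grid(rep(list(0:1), length(axes)))
    lapply(seq_len(nrow(grid)), function(i) {
      o <- c(0L, 0L, 0L)
      o[axes] <- as.integer(grid[i, ])
      o
    })
  }
  V <- present(shifts(1:3), d + 1L)
  E <- present(shifts(2:3), d + c(0L, 1L, 1L)) +  # edges along z
       present(shifts(c(1, 3)), d + c(1L, 0L, 1L)) +
       present(shifts(1:2), d + c(1L, 1L, 0L))
  F <- present(shifts(3), d + c(0L, 0L, 1L)) +    # faces normal to x
       present(shifts(2), d + c(0L, 1L, 0L)) +
       present(shifts(1), d + c(1L, 0L, 0L))
  C <- sum(m)
  V - E + F - C
}

#' Enclosed cavities of a voxel set
#'
#' Number of 6-connected background components that do not touch the
#' volume border (the second Betti number for well-composed masks).
#'
#' @inheritParams euler_characteristic
#' @return Integer count.
#' @export
count_cavities <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  labels <- .cpp_label(!m, as.integer(d), 6L)
  dim(labels) <- d
  border <- unique(c(
    labels[c(1, d[1]), , ], labels[, c(1, d[2]), ], labels[, , c(1, d[3])]
  ))
  length(setdiff(labels[labels > 0], border))
}

#' Homological cycle rank (first Betti number) of a voxel set
#'
#' `b1 = b0 + b2 - chi`, with `b0` the number of 26-connected foreground
#' components, `b2` the number of enclosed cavities and `chi` the Euler
#' characteristic of the cubical complex. Applicable to both solid masks
#' and thinned skeletons; a topology-preserving thinning leaves it
#' unchanged.
#'
#' @inheritParams euler_characteristic
#' @return Integer number of independent loops.
#' @export
cycle_rank <- function(mask) {
  m <- as_mask(mask)
  count_components(m, 26) + count_cavities(m) - euler_characteristic(m)
}

#' Graph cycle rank of a skeleton voxel set
#'
#' Treats foreground voxels as graph nodes with 26-adjacency edges and
#' returns `E - V + C`. For one-voxel-thick curve skeletons this equals
#' the number of independent loops; for thick masks it also counts local
#' adjacency triangles, which is exactly what makes residual shell
#' artifacts (e.g. around unfilled cavities) visible.
#'
#' @inheritParams euler_characteristic
#' @return Integer cycle rank of the adjacency graph.
#' @export
graph_cycle_rank <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  V <- sum(m)
  if (V == 0) return(0L)
  E <- 0L
  # count each 26-adjacent pair once via positive offsets
  offsets <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      offsets[[length(offsets) + 1]] <- c(dz, dy, dx)
    }
  }
  for (o in offsets) {
    lo <- pmax(1, 1 + o)
    hi <- pmin(d, d + o)
    if (any(hi < lo)) next
    z1 <- lo[1]:hi[1]; y1 <- lo[2]:hi[2]; x1 <- lo[3]:hi[3]
    E <- E + sum(m[z1, y1, x1, drop = FALSE] &
                 m[z1 - o[1], y1 - o[2], x1 - o[3], drop = FALSE])
  }
  C <- count_components(m, 26)
  as.integer(E - V + C)
}
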