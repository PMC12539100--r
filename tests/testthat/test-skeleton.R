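test_that("thinning leaves a one-voxel line unchanged", {
  d <- c(5, 5, 14)
  m <- line_mask(d, 3, 3, 3:12)
  sk <- thin_3d(vn_binary(m))
  expect_identical(sk$mask, m)
})

test_that("thinning a solid cube preserves one component with no loops", {
  m <- empty_mask(c(11, 11, 11)); m[3:9, 3:9, 3:9] <- TRUE
  sk <- thin_3d(vn_binary(m))
  expect_true(all(m[sk$mask]))  # skeleton is a subset of the input
  expect_equal(count_components(sk$mask), 1)
  expect_equal(cycle_rank(sk$mask), 0)
  expect_lt(sum(sk$mask), 10)
})

test_that("thinning preserves components and cycle rank (independent Euler oracle)", {
  cases <- list(
    torus = solid_torus_mask(),
    rod = { m <- empty_mask(c(9, 9, 24)); m[4:6, 4:6, 3:22] <- TRUE; m },
    two_blobs = { m <- empty_mask(c(12, 12, 24)); m[4:8, 4:8, 3:8] <- TRUE
                  m[4:8, 4:8, 15:20] <- TRUE; m }
  )
  for (nm in names(cases)) {
    m <- cases[[nm]]
    sk <- thin_3d(vn_binary(m))
    expect_equal(count_components(sk$mask), count_components(m), info = nm)
    expect_equal(cycle_rank(sk$mask), cycle_rank(m), info = nm)
    expect_equal(count_cavities(sk$mask), count_cavities(m), info = nm)
  }
  expect_equal(cycle_rank(solid_torus_mask()), 1)
})

test_that("voxel classification counts 26-neighbours", {
  d <- c(5, 5, 9)
  line <- line_mask(d, 3, 3, 3:7)
  cls <- classify_skeleton_voxels(line)
  expect_equal(sum(cls == 1L), 2)  # ends
  expect_equal(sum(cls == 2L), 3)  # slabs
  expect_equal(sum(cls == 3L), 0)
  y <- y_skeleton_mask(4, 4, 4)
  cls_y <- classify_skeleton_voxels(y)
  expect_equal(sum(cls_y == 3L), 1)
  expect_equal(sum(cls_y == 1L), 3)
  single <- empty_mask(d); single[2, 2, 2] <- TRUE
  expect_equal(classify_skeleton_voxels(single)[2, 2, 2], 1L)
})

test_that("extract_graph enumerates segments, junctions and skeletons", {
  d <- c(5, 5, 9)
  line_sk <- vesselnet:::new_skeleton(line_mask(d, 3, 3, 3:7), c(1, 1, 1))
  g <- extract_graph(line_sk)
  expect_equal(unname(g$counts), c(1, 1, 0, 2))
  expect_equal(g$segments[[1]]$length_um, 4)

  y_sk <- vesselnet:::new_skeleton(y_skeleton_mask(4, 4, 4), c(1, 1, 1))
  gy <- extract_graph(y_sk)
  expect_equal(unname(gy$counts), c(1, 3, 1, 3))

  # two disjoint structures in one volume are two skeletons
  m <- y_skeleton_mask(4, 4, 4)
  m[1, 3, 3:10] <- TRUE
  g2 <- extract_graph(vesselnet:::new_skeleton(m, c(1, 1, 1)))
  expect_equal(unname(g2$counts["skeletons"]), 2)
  expect_equal(unname(g2$counts["segments"]), 4)

  td <- tidy(gy)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_setequal(td$end_kind_2[td$end_kind_1 == "junction"], "end")
})

test_that("a closed voxel ring is one loop segment with no endpoints", {
  # diamond ring: |y-7| + |x-7| = 4 is a 26-connected cycle of degree-2 voxels
  d <- c(3, 14, 14)
  m <- empty_mask(d)
  for (y in 1:14) for (x in 1:14) {
    if (abs(y - 7) + abs(x - 7) == 4) m[2, y, x] <- TRUE
  }
  g <- extract_graph(vesselnet:::new_skeleton(m, c(1, 1, 1)))
  expect_equal(unname(g$counts), c(1, 1, 0, 0))
  expect_equal(graph_cycle_rank(m), 1L)
})

test_that("segment_length sums calibrated Euclidean steps", {
  expect_equal(segment_length(cbind(3, 3, 1:5), c(1, 1, 1)), 4)
  path_diag <- cbind(1, 1:3, 1:3)
  expect_equal(segment_length(path_diag, c(1, 1, 1)), 2 * sqrt(2))
  # anisotropic: steps along z cost dz
  path_z <- cbind(1:3, 2, 2)
  expect_equal(segment_length(path_z, c(2, 1, 1)), 4)
  path_mix <- rbind(c(1, 1, 1), c(2, 2, 1), c(3, 2, 2))
  expect_equal(segment_length(path_mix, c(2, 0.5, 0.5)),
               sqrt(4 + 0.25) + sqrt(4 + 0.25))
  expect_equal(segment_length(cbind(1, 1, 1), c(1, 1, 1)), 0)
  expect_error(segment_length(rbind(c(1, 1, 1), c(1, 1, 4)), c(1, 1, 1)),
               "adjacent")
})

test_that("pruning removes short junction-attached arms and re-extracts", {
  m <- y_skeleton_mask(5, 5, 2)
  sk <- vesselnet:::new_skeleton(m, c(1, 1, 1))
  g <- extract_graph(sk)
  expect_equal(unname(g$counts), c(1, 3, 1, 3))
  pr <- prune_short_end_segments(g, sk, 3)
  expect_equal(unname(pr$graph$counts), c(1, 1, 0, 2))
  # prune_length 0 is the identity
  pr0 <- prune_short_end_segments(g, sk, 0)
  expect_identical(pr0$skeleton$mask, sk$mask)
  expect_equal(unname(pr0$graph$counts), unname(g$counts))
})

test_that("free-floating short segments are never pruned", {
  d <- c(5, 9, 9)
  m <- empty_mask(d); m[3, 4, 4:5] <- TRUE  # 2-voxel END-END segment
  sk <- vesselnet:::new_skeleton(m, c(1, 1, 1))
  g <- extract_graph(sk)
  pr <- prune_short_end_segments(g, sk, 5)
  expect_identical(pr$skeleton$mask, m)
  expect_equal(unname(pr$graph$counts["segments"]), 1)
})

test_that("pruning is idempotent and never increases segment counts", {
  m <- y_skeleton_mask(6, 5, 2)
  sk <- vesselnet:::new_skeleton(m, c(1, 1, 1))
  g <- extract_graph(sk)
  p1 <- prune_short_end_segments(g, sk, 4)
  p2 <- prune_short_end_segments(p1$graph, p1$skeleton, 4)
  expect_identical(p1$skeleton$mask, p2$skeleton$mask)
  expect_equal(unname(p1$graph$counts), unname(p2$graph$counts))
  expect_lte(p1$graph$counts["segments"], g$counts["segments"])
  expect_lte(p1$graph$counts["junctions"], g$counts["junctions"])
})

test_that("segment terminal bookkeeping is consistent", {
  # every END voxel belongs to exactly one segment terminus; each segment
  # carries exactly two terminal attachments
  for (builder in list(function() y_skeleton_mask(5, 4, 6),
                       function() { m <- y_skeleton_mask(4, 4, 4)
                                    m[1, 3, 3:10] <- TRUE; m })) {
    m <- builder()
    g <- extract_graph(vesselnet:::new_skeleton(m, c(1, 1, 1)))
    kinds <- unlist(lapply(g$segments, function(s) s$end_kinds))
    expect_equal(length(kinds), 2 * length(g$segments))
    n_end_termini <- sum(kinds == "end")
    expect_equal(n_end_termini, unname(g$counts["endpoints"]))
  }
})
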