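measure_from_mask <- function(mask, voxel_size = c(1, 1, 1), id = "m") {
  b <- vn_binary(mask, voxel_size)
  sk <- thin_3d(b)
  g <- extract_graph(sk)
  measure_network(b, g, sk, image_id = id)
}

test_that("an empty skeleton yields zero counts but a valid row", {
  d <- c(6, 6, 6)
  m <- measure_from_mask(empty_mask(d))
  expect_equal(m$n_skeletons, 0)
  expect_equal(m$n_segments, 0)
  expect_equal(m$n_junctions, 0)
  expect_equal(m$n_endpoints, 0)
  expect_equal(m$network_length_voxels, 0)
  expect_equal(m$volume_fraction, 0)
  expect_length(m$segment_lengths[[1]], 0)
})

test_that("network length density follows the closed-form imaged volume", {
  d <- c(100, 100, 100)
  mask <- line_mask(d, 50, 50, 1:100)
  m <- measure_from_mask(mask)
  expect_equal(m$network_length_voxels, 100)
  # 100 voxels in (100 um)^3 = 1e-3 mm^3 -> 1e5 voxels per mm^3
  expect_equal(m$network_length_per_mm3, 1e5)
  expect_equal(m$image_volume_mm3, 1e-3)
  expect_equal(m$network_length_um, 99)
})

test_that("measurements match generator truth on a phantom", {
  spec <- phantom_spec(
    canvas_shape = c(28, 48, 48),
    paths = list(
      matrix(c(14, 24, 6, 14, 24, 24), ncol = 3, byrow = TRUE),
      matrix(c(14, 24, 24, 14, 10, 42), ncol = 3, byrow = TRUE),
      matrix(c(14, 24, 24, 14, 38, 42), ncol = 3, byrow = TRUE)
    ),
    radii = 2.5, seed = 2
  )
  ph <- render_phantom(spec)
  params <- vn_params(gaussian_sigma = 1, prune_length = 4)
  pre <- preprocess_volume(ph$image, params)
  bin <- binarize_volume(pre, params)
  sk <- skeletonize_volume(bin, params)
  m <- measure_network(bin, sk$graph, sk$skeleton)
  expect_equal(m$n_skeletons, ph$truth$n_skeletons)
  expect_equal(m$n_segments, ph$truth$n_segments)
  expect_equal(m$n_junctions, ph$truth$n_junctions)
  expect_equal(m$n_endpoints, ph$truth$n_endpoints)
})

test_that("normalize_counts divides counts by the imaged volume", {
  d <- c(10, 10, 10)
  mask <- empty_mask(d)
  mask[5, 5, 2:5] <- TRUE; mask[2, 2, 2:5] <- TRUE  # 2 separate lines
  m <- measure_from_mask(mask, voxel_size = c(100, 100, 50))  # 0.5 mm^3
  expect_equal(m$image_volume_mm3, 0.5)
  norm <- normalize_counts(m)
  expect_equal(norm$n_skeletons_per_mm3, 2 / 0.5)
  # zero counts stay zero
  z <- normalize_counts(measure_from_mask(empty_mask(d)))
  expect_equal(z$n_junctions_per_mm3, 0)
  expect_error(normalize_counts(m, image_volume_mm3 = 0), "positive")
})

test_that("doubling empty padding halves densities, raw counts unchanged", {
  small <- c(12, 20, 20); big <- c(12, 20, 40)
  mask_s <- line_mask(small, 6, 10, 4:16)
  mask_b <- line_mask(big, 6, 10, 4:16)
  m_s <- normalize_counts(measure_from_mask(mask_s, c(10, 10, 10)))
  m_b <- normalize_counts(measure_from_mask(mask_b, c(10, 10, 10)))
  expect_equal(m_s$n_skeletons, m_b$n_skeletons)
  expect_equal(m_s$network_length_voxels, m_b$network_length_voxels)
  expect_equal(m_b$n_skeletons_per_mm3, m_s$n_skeletons_per_mm3 / 2)
  expect_equal(m_b$network_length_per_mm3, m_s$network_length_per_mm3 / 2)
})

test_that("raw measurements are translation invariant on a fixed canvas", {
  d <- c(10, 30, 30)
  base <- y_skeleton_mask(4, 4, 4, d = c(10, 30, 30))
  shifted <- array(FALSE, d)
  shifted[, 4:30, ] <- base[, 1:27, ]
  m1 <- measure_from_mask(base)
  m2 <- measure_from_mask(shifted)
  for (col in c("volume_fraction", "network_length_voxels", "n_skeletons",
                "n_segments", "n_junctions", "n_endpoints")) {
    expect_equal(m1[[col]], m2[[col]], info = col)
  }
  expect_equal(sort(m1$segment_lengths[[1]]), sort(m2$segment_lengths[[1]]))
})

test_that("summed segment lengths bound the voxel count from below", {
  for (mask in list(y_skeleton_mask(5, 6, 3),
                    line_mask(c(5, 5, 20), 3, 3, 2:18))) {
    vs <- c(2, 1, 1)
    m <- measure_from_mask(mask, voxel_size = vs)
    lhs <- sum(m$segment_lengths[[1]])
    rhs <- (m$network_length_voxels - m$n_segments) * min(vs)
    expect_gte(lhs, rhs)
  }
})

test_that("measure_network validates shape and calibration consistency", {
  b <- vn_binary(empty_mask(c(4, 4, 4)))
  sk <- thin_3d(vn_binary(empty_mask(c(4, 4, 5))))
  g <- extract_graph(sk)
  expect_error(measure_network(b, g, sk), "shapes")
  sk2 <- thin_3d(vn_binary(empty_mask(c(4, 4, 4)), voxel_size = c(2, 1, 1)))
  g2 <- extract_graph(sk2)
  expect_error(measure_network(b, g2, sk2), "calibration")
})

test_that("segment_length_table unrolls the list-column", {
  m <- measure_from_mask(y_skeleton_mask(4, 4, 4), id = "img1")
  tab <- segment_length_table(m)
  expect_equal(nrow(tab), m$n_segments)
  expect_named(tab, c("image_id", "segment_id", "length_um"))
  expect_true(all(tab$image_id == "img1"))
})
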