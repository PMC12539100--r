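test_that("yen threshold separates a two-valued image exactly", {
  set.seed(2)
  vox <- array(sample(c(10, 200), 6^3, TRUE, prob = c(0.7, 0.3)), c(6, 6, 6))
  v <- vn_volume(vox)
  t <- yen_threshold(v)
  expect_gte(t, 10); expect_lt(t, 200)
  fg <- v$voxels > t
  expect_identical(fg, vox == 200)
})

test_that("yen threshold equals brute-force criterion maximization on random histograms", {
  set.seed(7)
  n_ok <- 0; n_run <- 0
  for (i in 1:100) {
    h <- stats::rpois(256, lambda = runif(1, 0.5, 50))
    if (sum(h) == 0 || sum(h > 0) < 2) h[c(10, 200)] <- h[c(10, 200)] + 1
    n_run <- n_run + 1
    impl <- vesselnet:::yen_cut_from_histogram(h)
    if (identical(as.integer(impl), as.integer(yen_brute_force(h)))) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, n_run)
  expect_equal(n_run, 100)
})

test_that("yen threshold rejects constant images", {
  expect_error(yen_threshold(vn_volume(array(5, c(3, 3, 3)))), "constant")
})

test_that("particle removal uses slice-wise 2D 8-connectivity", {
  d <- c(3, 20, 20)
  m <- empty_mask(d)
  m[2, 2:11, 2:11] <- TRUE       # 100-px blob in slice 2
  m[2, 15:16, 15] <- TRUE        # 2-px blob, diagonal co-slice
  m[2, 17, 16] <- TRUE           # diagonal touch: 8-connected -> one 3-px blob
  b <- vn_binary(m)
  out <- remove_small_particles(b, 10)
  expect_equal(sum(out$mask), 100)
  expect_identical(remove_small_particles(b, 0)$mask, b$mask)
  expect_error(remove_small_particles(b, -1), "non-negative")
})

test_that("a z-axis rod of 1 px per slice is removed by slice-wise semantics", {
  d <- c(10, 9, 9)
  m <- empty_mask(d)
  m[1:10, 5, 5] <- TRUE
  out2d <- remove_small_particles(vn_binary(m), 2)
  expect_equal(sum(out2d$mask), 0)
  # volumetric mode sees one 10-voxel component and keeps it
  out3d <- remove_small_particles(vn_binary(m), 2, particles_3d = TRUE)
  expect_equal(sum(out3d$mask), 10)
})

test_that("particle removal only ever deletes foreground", {
  set.seed(12)
  m <- array(runif(6^3) < 0.3, c(6, 6, 6))
  out <- remove_small_particles(vn_binary(m), 3)
  expect_true(all(m[!out$mask] | !m[!out$mask]))  # background untouched
  expect_true(all(!out$mask[!m]))                  # nothing added
  expect_true(all(m | !out$mask))                  # subset of input
})

test_that("close_3d bridges a one-voxel axial gap and is idempotent", {
  d <- c(7, 7, 11)
  m <- empty_mask(d)
  m[4, 4, 4] <- TRUE; m[4, 4, 6] <- TRUE
  b <- vn_binary(m)
  out <- close_3d(b, c(0, 0, 1), c(0, 0, 1))
  expect_identical(which(out$mask), which(line_mask(d, 4, 4, 4:6)))
  # empty in, empty out; isolated voxel unchanged by equal-radius closing
  expect_equal(sum(close_3d(vn_binary(empty_mask(d)), 1, 1)$mask), 0)
  single <- empty_mask(d); single[4, 4, 6] <- TRUE
  expect_identical(close_3d(vn_binary(single), 1, 1)$mask, single)
  # idempotence of closing with equal radii
  set.seed(5)
  rnd <- vn_binary(array(runif(9^3) < 0.2, c(9, 9, 9)))
  once <- close_3d(rnd, 1, 1)
  twice <- close_3d(once, 1, 1)
  expect_identical(once$mask, twice$mask)
  expect_error(close_3d(b, -1), "non-negative")
})

test_that("fill_holes_3d fills enclosed cavities and only adds voxels", {
  shell <- shell_mask()
  filled <- fill_holes_3d(vn_binary(shell))
  solid <- empty_mask(c(9, 9, 9)); solid[3:7, 3:7, 3:7] <- TRUE
  expect_identical(filled$mask, solid)
  # U-shaped channel open to the border stays open
  d <- c(7, 7, 7)
  u <- empty_mask(d); u[2:6, 2:6, 2:6] <- TRUE
  u[4, 4, 1:4] <- FALSE  # bore reaching the x = 1 border face
  out <- fill_holes_3d(vn_binary(u))
  expect_identical(out$mask, u)
  # empty volume unchanged; only additions ever happen
  expect_equal(sum(fill_holes_3d(vn_binary(empty_mask(d)))$mask), 0)
  expect_true(all(fill_holes_3d(vn_binary(shell))$mask[shell]))
})

test_that("volume_fraction is a plain voxel ratio, invariant under rotations", {
  d <- c(4, 4, 4)
  m <- empty_mask(d); m[1:2, 1:2, 1:2] <- TRUE
  expect_equal(volume_fraction(vn_binary(m)), 8 / 64)
  expect_equal(volume_fraction(vn_binary(array(TRUE, d))), 1)
  expect_equal(volume_fraction(vn_binary(empty_mask(d))), 0)
  set.seed(8)
  r <- array(runif(prod(d)) < 0.4, d)
  vf <- volume_fraction(vn_binary(r))
  for (perm in list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    rot <- aperm(r, perm)
    expect_equal(volume_fraction(vn_binary(rot)), vf)
    flipped <- rot[dim(rot)[1]:1, , , drop = FALSE]
    dim(flipped) <- dim(rot)
    expect_equal(volume_fraction(vn_binary(flipped)), vf)
  }
})

test_that("binarize_volume recovers a noise-free rendered tube exactly", {
  spec <- phantom_spec(
    canvas_shape = c(24, 40, 40),
    paths = list(matrix(c(12, 20, 6, 12, 20, 34), ncol = 3, byrow = TRUE)),
    radii = 2.5, seed = 3
  )
  ph <- render_phantom(spec)
  # no preprocessing: the two intensity levels must split exactly, nothing
  # gets removed, closing is idempotent on the solid tube, no holes exist
  params <- vn_params(particle_min_size = 3, closing_max_radius = 0,
                      closing_min_radius = 0)
  b <- binarize_volume(ph$image, params)
  expect_identical(b$mask, ph$truth$mask$mask)
  expect_error(binarize_volume(vn_volume(array(1, c(3, 3, 3))), params),
               "constant")
})
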