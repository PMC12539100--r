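test_that("ground-truth dilation grows by the structuring element", {
  d <- c(9, 9, 9)
  single <- empty_mask(d); single[5, 5, 5] <- TRUE
  gt <- vn_binary(single)
  r0 <- dilate_ground_truth(gt, 0)
  expect_identical(r0$gt$mask, single)
  expect_equal(r0$gt_area_increase_percent, 0)
  r1 <- dilate_ground_truth(gt, 1)
  expect_equal(sum(r1$gt$mask), 27)          # full 3x3x3 cube
  expect_equal(r1$gt_area_increase_percent, 2600)
  r1c <- dilate_ground_truth(gt, 1, connectivity = 6)
  expect_equal(sum(r1c$gt$mask), 7)          # face-neighbour cross
  # extensivity: each round contains the previous
  set.seed(21)
  rnd <- vn_binary(array(runif(10^3) < 0.05, c(10, 10, 10)))
  m1 <- dilate_ground_truth(rnd, 1)$gt$mask
  m2 <- dilate_ground_truth(rnd, 2)$gt$mask
  expect_true(all(m2[m1]))
  expect_error(dilate_ground_truth(gt, -1), "non-negative")
})

test_that("skeleton overlap is the foreground-voxel containment percentage", {
  d <- c(4, 6, 10)
  sk <- line_mask(d, 2, 3, 1:10)
  expect_equal(skeleton_overlap(vn_binary(sk), vn_binary(sk)), 100)
  disjoint <- line_mask(d, 4, 5, 1:10)
  expect_equal(skeleton_overlap(vn_binary(sk), vn_binary(disjoint)), 0)
  partial <- line_mask(d, 2, 3, 1:4)    # 4 of the 10 skeleton voxels
  expect_equal(skeleton_overlap(vn_binary(sk), vn_binary(partial)), 40)
  expect_error(skeleton_overlap(vn_binary(empty_mask(d)), vn_binary(sk)),
               "empty")
  expect_error(
    skeleton_overlap(vn_binary(sk), vn_binary(empty_mask(c(4, 6, 9)))),
    "shapes"
  )
})

test_that("overlap is monotone non-decreasing in dilation rounds", {
  set.seed(33)
  d <- c(12, 24, 24)
  gt <- vn_binary(line_mask(d, 6, 12, 3:21))
  # a skeleton displaced by one voxel from the ground truth
  sk <- vn_binary(line_mask(d, 7, 13, 3:21))
  tab <- evaluate_overlap(sk, gt, 0:2)
  expect_equal(tab$dilation_rounds, 0:2)
  expect_true(all(diff(tab$overlap_percent) >= 0))
  expect_true(all(diff(tab$gt_area_increase_percent) >= 0))
  expect_equal(tab$overlap_percent[2], 100)  # one-voxel tolerance captures it
})

test_that("glass_delta reproduces hand-computed values exactly", {
  # group mean 3, control {0, 2}: sd = sqrt(2), delta = 2/sqrt(2) = sqrt(2)
  es <- glass_delta(c(3, 3), c(0, 2))
  expect_equal(es$delta, sqrt(2), tolerance = 1e-12)
  expect_equal(es$category, "high")
  expect_equal(glass_delta(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  expect_equal(glass_delta(c(1, 2, 3), c(1, 2, 3))$category, "low")
})

test_that("glass_delta category boundaries are inclusive at 0.2 and 0.5", {
  # control sd 1, mean 0 -> delta equals |group mean|
  ctrl <- c(-1, 0, 1) / sqrt(sum(c(-1, 0, 1)^2) / 2)  # sd exactly 1
  expect_equal(sd(ctrl), 1)
  expect_equal(glass_delta(c(0.2, 0.2), ctrl)$category, "low")
  expect_equal(glass_delta(c(0.2000001, 0.2000001), ctrl)$category, "medium")
  expect_equal(glass_delta(c(0.5, 0.5), ctrl)$category, "medium")
  expect_equal(glass_delta(c(0.5000001, 0.5000001), ctrl)$category, "high")
})

test_that("glass_delta is shift invariant and scale equivariant in delta", {
  set.seed(14)
  g <- rnorm(6, 4, 2); c0 <- rnorm(8, 2, 1.5)
  d0 <- glass_delta(g, c0)$delta
  expect_equal(glass_delta(g + 7, c0 + 7)$delta, d0)
  expect_equal(glass_delta(3 * g, 3 * c0)$delta, d0)
  expect_error(glass_delta(g, c(5)), "at least two")
  expect_error(glass_delta(g, c(5, 5, 5)), "zero")
})

test_that("exact Mann-Whitney p matches full enumeration for all small pairs", {
  set.seed(11)
  for (na in 2:6) for (nb in 2:6) {
    a <- sample(0:8, na, replace = TRUE)
    b <- sample(0:8, nb, replace = TRUE)
    res <- mann_whitney_bonferroni(a, b)
    expect_identical(res$method, "exact")
    expect_equal(res$u_statistic, u_pair_count(a, b))
    expect_equal(res$p_value, mw_brute_force_p(a, b), tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("identical samples give p = 1 and exact mode agrees with wilcox.test", {
  expect_equal(mann_whitney_bonferroni(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # tie-free case: exact p must equal the classical exact distribution
  set.seed(19)
  a <- sample(1:100, 5); b <- sample(101:200, 6) - 50.5
  res <- mann_whitney_bonferroni(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(23)
  a <- sample(0:20, 30, replace = TRUE)
  b <- sample(3:23, 28, replace = TRUE)
  res <- mann_whitney_bonferroni(a, b)
  expect_identical(res$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("Bonferroni correction sets the per-test level", {
  res <- mann_whitney_bonferroni(c(1, 2), c(3, 4), m_tests = 1,
                                 alpha_star = 0.05)
  expect_equal(res$alpha_corrected, 0.050)
  res14 <- mann_whitney_bonferroni(c(1, 2), c(3, 4), m_tests = 14,
                                   alpha_star = 0.05)
  expect_equal(res14$alpha_corrected, 0.05 / 14)
  expect_identical(res14$significant, res14$p_value < res14$alpha_corrected)
  gl <- glance(res14)
  expect_equal(gl$m_tests, 14L)
  expect_error(mann_whitney_bonferroni(numeric(0), c(1)), "nonempty")
})

test_that("the p-value is invariant under strictly monotone transforms", {
  set.seed(29)
  a <- rnorm(5); b <- rnorm(7, 1)
  p0 <- mann_whitney_bonferroni(a, b)$p_value
  expect_equal(mann_whitney_bonferroni(exp(a), exp(b))$p_value, p0)
  expect_equal(mann_whitney_bonferroni(a^3, b^3)$p_value, p0)
  expect_equal(mann_whitney_bonferroni(5 * a - 2, 5 * b - 2)$p_value, p0)
})
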