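#' Dilate a ground-truth skeleton
#'
#' Applies `rounds` successive 3D binary dilations. The default
#' structuring element is the full 3x3x3 cube (26-neighbourhood);
#' `connectivity = 6` uses the face-neighbour cross instead. Also reports
#' the growth of the foreground voxel count relative to the original, the
#' companion number quoted alongside overlap tables.
#'
#' @param gt A [vn_binary()] ground-truth skeleton volume.
#' @param rounds Non-negative integer number of dilations.
#' @param connectivity 26 (cube) or 6 (cross).
#' @return A list: `gt` (dilated [vn_binary()]) and
#'   `gt_area_increase_percent`.
#' @export
dilate_ground_truth <- function(gt, rounds, connectivity = 26) {
  stopifnot(inherits(gt, "vn_binary"))
  if (!is.numeric(rounds) || length(rounds) != 1 || rounds < 0 ||
      rounds != round(rounds)) {
    stop("`rounds` must be a non-negative integer", call. = FALSE)
  }
  if (!connectivity %in% c(6, 26)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  n0 <- sum(gt$mask)
  m <- gt$mask
  d <- as.integer(dim(m))
  shape <- if (connectivity == 26) 1L else 0L
  for (i in seq_len(rounds)) {
    m <- .cpp_minmax(m, d, c(1L, 1L, 1L), TRUE, shape)
  }
  dim(m) <- d
  increase <- if (n0 > 0) 100 * (sum(m) - n0) / n0 else 0
  list(gt = vn_binary(m, gt$voxel_size), gt_area_increase_percent = increase)
}

#' Skeleton overlap with a ground truth
#'
#' Percentage of produced-skeleton voxels that fall inside the (possibly
#' dilated) ground-truth mask: `100 * |skeleton & gt| / |skeleton|`.
#'
#' @param skeleton A `vn_skeleton` or [vn_binary()] produced skeleton.
#' @param gt A [vn_binary()] ground truth of the same shape.
#' @return Overlap percentage in \[0, 100\].
#' @export
skeleton_overlap <- function(skeleton, gt) {
  sk <- as_mask(skeleton)
  g <- as_mask(gt)
  if (!identical(dim(sk), dim(g))) {
    stop("skeleton and ground truth shapes differ", call. = FALSE)
  }
  n <- sum(sk)
  if (n == 0) stop("empty skeleton: overlap undefined", call. = FALSE)
  100 * sum(sk & g) / n
}

#' Overlap evaluation over successive ground-truth dilations
#'
#' Reproduces the shape of a skeleton-overlap validation table: one row
#' per dilation round with the ground-truth growth and the skeleton
#' overlap percentage. Overlap is non-decreasing in the number of rounds
#' because dilation is extensive.
#'
#' @inheritParams skeleton_overlap
#' @param rounds Integer vector of dilation rounds, e.g. `0:2`.
#' @param connectivity Structuring element, see [dilate_ground_truth()].
#' @return A tibble with columns `dilation_rounds`,
#'   `gt_area_increase_percent`, `overlap_percent`.
#' @export
evaluate_overlap <- function(skeleton, gt, rounds = 0:2, connectivity = 26) {
  stopifnot(inherits(gt, "vn_binary"))
  purrr::map_dfr(sort(unique(as.integer(rounds))), function(r) {
    dil <- dilate_ground_truth(gt, r, connectivity)
    tibble::tibble(
      dilation_rounds = r,
      gt_area_increase_percent = dil$gt_area_increase_percent,
      overlap_percent = skeleton_overlap(skeleton, dil$gt)
    )
  })
}

#' Glass's delta effect size
#'
#' `delta = |mean(group) - mean(control)| / sd(control)`, with the control
#' standard deviation estimated with the n-1 denominator. Categories
#' follow the conventional cuts: `delta <= 0.2` low, `0.2 < delta <= 0.5`
#' medium, `delta > 0.5` high.
#'
#' @param group Numeric vector of the comparison group.
#' @param control Numeric vector of the control group; at least two values
#'   with nonzero standard deviation.
#' @return A `vn_effect_size` list: `delta`, `category`, `mean_group`,
#'   `mean_control`, `sd_control`; [tidy()] gives a one-row tibble.
#' @examples
#' glass_delta(c(3, 3), c(0, 2))  # delta = sqrt(2), high
#' @export
glass_delta <- function(group, control) {
  group <- as.numeric(group)
  control <- as.numeric(control)
  if (length(control) < 2) {
    stop("control group needs at least two values", call. = FALSE)
  }
  s2 <- sd(control)
  if (!is.finite(s2) || s2 == 0) {
    stop("control group standard deviation is zero", call. = FALSE)
  }
  delta <- abs(mean(group) - mean(control)) / s2
  category <- if (delta <= 0.2) "low" else if (delta <= 0.5) "medium" else "high"
  structure(
    list(delta = delta, category = category,
         mean_group = mean(group), mean_control = mean(control),
         sd_control = s2),
    class = "vn_effect_size"
  )
}

#' @export
print.vn_effect_size <- function(x, ...) {
  cat(sprintf("Glass's delta = %.4g (%s effect)\n", x$delta, x$category))
  invisible(x)
}

#' @describeIn glass_delta One-row tibble of the effect size.
#' @param x A `vn_effect_size`.
#' @param ... Unused.
#' @export
tidy.vn_effect_size <- function(x, ...) {
  tibble::tibble(
    delta = x$delta, category = x$category,
    mean_group = x$mean_group, mean_control = x$mean_control,
    sd_control = x$sd_control
  )
}

#' Two-sided Mann-Whitney U test with Bonferroni correction
#'
#' The U statistic is computed from midranks. For small samples
#' (`min(n) <= 8` and a feasible enumeration) the two-sided p-value is
#' exact: all `choose(na+nb, na)` relabellings of the pooled sample are
#' enumerated and p is the fraction whose U is at least as far from the
#' null mean `na*nb/2` as observed (ties handled exactly). Larger samples
#' use the tie-corrected normal approximation with continuity correction.
#' The per-test level is `alpha_star / m_tests` and the significance flag
#' compares p against it.
#'
#' @param samples_a,samples_b Numeric vectors, both nonempty.
#' @param m_tests Number of comparisons in the family (>= 1).
#' @param alpha_star Family significance level (default 0.05).
#' @return A `vn_test` list: `u_statistic` (U of `samples_a`), `p_value`,
#'   `method` ("exact" or "normal"), `alpha_star`, `alpha_corrected`,
#'   `m_tests`, `significant`; [tidy()]/[glance()] give one-row tibbles.
#' @export
mann_whitney_bonferroni <- function(samples_a, samples_b, m_tests = 1,
                                    alpha_star = 0.05) {
  a <- as.numeric(samples_a)
  b <- as.numeric(samples_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (m_tests < 1) stop("`m_tests` must be >= 1", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  exact_ok <- min(na, nb) <= 8 && choose(n, na) <= 2e5
  if (exact_ok) {
    combos <- utils::combn(n, na)
    rsums <- colSums(matrix(r[combos], nrow = na))
    u_all <- rsums - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_a - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u_a - mu) - 0.5) / sigma
      p <- min(1, 2 * pnorm(-max(0, z)))
    }
    method <- "normal"
  }
  alpha_corrected <- alpha_star / m_tests
  structure(
    list(u_statistic = u_a, p_value = p, method = method,
         alpha_star = alpha_star, alpha_corrected = alpha_corrected,
         m_tests = as.integer(m_tests),
         n_a = na, n_b = nb,
         significant = p < alpha_corrected),
    class = "vn_test"
  )
}

#' @export
print.vn_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %g, p = %.4g (%s), alpha = %.4g/%d = %.4g -> %s\n",
    x$u_statistic, x$p_value, x$method, x$alpha_star, x$m_tests,
    x$alpha_corrected, if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}

#' @describeIn mann_whitney_bonferroni One-row tibble of statistic and p.
#' @param x A `vn_test`.
#' @param ... Unused.
#' @export
tidy.vn_test <- function(x, ...) {
  tibble::tibble(
    u_statistic = x$u_statistic, p_value = x$p_value, method = x$method,
    n_a = x$n_a, n_b = x$n_b
  )
}

#' @describeIn mann_whitney_bonferroni One-row tibble of the decision.
#' @export
glance.vn_test <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, alpha_star = x$alpha_star, m_tests = x$m_tests,
    alpha_corrected = x$alpha_corrected, significant = x$significant
  )
}
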