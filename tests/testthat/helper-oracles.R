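# Independent oracles and small fixture builders shared across tests.

# Yen's criterion maximized by explicit summation over every cut point,
# independent of the vectorized implementation.
yen_brute_force <- function(h) {
  p <- h / sum(h)
  best <- -Inf
  best_k <- NA_integer_
  for (k in 1:255) {
    P1 <- sum(p[1:k]); P2 <- 1 - P1
    if (P1 <= 0 || P2 <= 0) next
    G1 <- sum(p[1:k]^2); G2 <- sum(p[(k + 1):256]^2)
    if (G1 <= 0 || G2 <= 0) next
    tc <- -log(G1 * G2) + 2 * log(P1 * P2)
    if (tc > best + 1e-12) { best <- tc; best_k <- k }
  }
  best_k
}

# Mann-Whitney U by direct pair counting, and the exact two-sided p by full
# enumeration of all C(n, na) group labellings.
u_pair_count <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

mw_brute_force_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  mu <- na * length(b) / 2
  u_obs <- u_pair_count(a, b)
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(ix) u_pair_count(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# mask builders ---------------------------------------------------------------

empty_mask <- function(d) array(FALSE, d)

# straight voxel line along x at (z0, y0)
line_mask <- function(d, z0, y0, x_range) {
  m <- empty_mask(d)
  m[z0, y0, x_range] <- TRUE
  m
}

# Y-shaped skeleton in one z-plane: stem along x plus two diagonal arms;
# arm voxel counts exclude the junction voxel
y_skeleton_mask <- function(stem = 5, arm1 = 5, arm2 = 5, d = c(5, 41, 41)) {
  m <- empty_mask(d)
  z <- 3; jy <- 21; jx <- 21
  m[z, jy, (jx - stem):jx] <- TRUE
  for (i in seq_len(arm1)) m[z, jy - i, jx + i] <- TRUE
  for (i in seq_len(arm2)) m[z, jy + i, jx + i] <- TRUE
  m
}

# hollow cube shell with one enclosed cavity
shell_mask <- function() {
  m <- empty_mask(c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- TRUE
  m[4:6, 4:6, 4:6] <- FALSE
  m
}

solid_torus_mask <- function() {
  d <- c(20, 48, 48)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  rad <- sqrt((g$y - 24)^2 + (g$x - 24)^2)
  array((rad - 14)^2 + (g$z - 10)^2 <= 4^2, d)
}
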