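# Independent oracles used to cross-check the package's geometry.

# Brute-force convex hull of a planar set by extreme-edge enumeration:
# a directed edge (i, j) lies on the hull iff every other point is on its
# left. O(N^3); intended for <= 60-point instances in general position.
brute_hull_metrics <- function(xy) {
  n <- nrow(xy)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- xy[j, ] - xy[i, ]
      rel <- sweep(xy[-c(i, j), , drop = FALSE], 2L, xy[i, ])
      cr <- d[1L] * rel[, 2L] - d[2L] * rel[, 1L]
      if (all(cr >= 0)) {
        on_hull[i] <- on_hull[j] <- TRUE
      }
    }
  }
  v <- xy[on_hull, , drop = FALSE]
  ctr <- colMeans(v)
  ord <- order(atan2(v[, 2L] - ctr[2L], v[, 1L] - ctr[1L]))
  v <- v[ord, , drop = FALSE]
  m <- nrow(v)
  nxt <- c(2:m, 1L)
  area <- abs(sum(v[, 1L] * v[nxt, 2L] - v[nxt, 1L] * v[, 2L])) / 2
  per <- sum(sqrt(rowSums((v[nxt, , drop = FALSE] - v) ^ 2)))
  list(area = area, perimeter = per, n_vertices = m)
}

# Closed-form hexcone RGB -> HSV (h in degrees [0, 360), s, v in [0, 1]).
hexcone_hsv <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  idx <- d > 0 & mx == r
  h[idx] <- 60 * (((g - b) / d)[idx] %% 6)
  idx <- d > 0 & mx == g & mx != r
  h[idx] <- 60 * (((b - r) / d)[idx] + 2)
  idx <- d > 0 & mx == b & mx != r & mx != g
  h[idx] <- 60 * (((r - g) / d)[idx] + 4)
  s <- ifelse(mx == 0, 0, d / mx)
  cbind(h = h %% 360, s = s, v = mx)
}

# Numerical arc-length / chord of a lateral-offset axis x(z) over [zlo, zhi].
arc_chord_quadrature <- function(fx, zlo, zhi, n = 20000L) {
  z <- seq(zlo, zhi, length.out = n)
  x <- fx(z)
  sum(sqrt(diff(x) ^ 2 + diff(z) ^ 2)) /
    sqrt((x[n] - x[1]) ^ 2 + (zhi - zlo) ^ 2)
}

# Uniformly random rotation matrix (from a random unit quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q ^ 2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x*y - w*z), 2 * (x*z + w*y),
           2 * (x*y + w*z), 1 - 2 * (x^2 + z^2), 2 * (y*z - w*x),
           2 * (x*z - w*y), 2 * (y*z + w*x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
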