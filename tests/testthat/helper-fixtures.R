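# Programmatic fixtures shared across test files.

# Wrap a raw coordinate matrix as a standardised BodyCloud (centred, unit
# scale), bypassing the preprocessing chain for direct metric tests.
make_body <- function(P, rgb = NULL) {
  P <- as.matrix(P)
  P <- sweep(P, 2L, colMeans(P))
  dimnames(P) <- list(NULL, c("x", "y", "z"))
  if (is.null(rgb)) rgb <- matrix(200L, nrow(P), 3L)
  new("BodyCloud", coords = P, rgb = rgb,
      bodyHeightMm = diff(range(P[, 3L])),
      scaleFactor = 1, rotation = diag(3))
}

# Uniform samples of the lateral surface of an elliptic cylinder
# (a = b gives a circular cylinder), axis along z, z in [0, h].
sample_elliptic_cylinder <- function(n, a, b, h, seed = 1) {
  set.seed(seed)
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, 0, h)
  cbind(a * cos(th), b * sin(th), z)
}

# Area-uniform samples of a sphere of radius R centred at the origin.
sample_sphere <- function(n, R, seed = 1) {
  set.seed(seed)
  u <- stats::runif(n, -1, 1)
  th <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - u ^ 2)
  R * cbind(r * cos(th), r * sin(th), u)
}

# Small coloured cloud with exactly known hues: n_red points of pure red
# (h = 0), n_green of pure green (h = 120), n_blue of pure blue (h = 240).
make_hue_cloud <- function(n_red, n_green = 0, n_blue = 0, seed = 1) {
  set.seed(seed)
  n <- n_red + n_green + n_blue
  P <- matrix(stats::runif(3 * n), ncol = 3L)
  rgb <- rbind(
    matrix(rep(c(255L, 0L, 0L), each = n_red), ncol = 3L),
    matrix(rep(c(0L, 255L, 0L), each = n_green), ncol = 3L),
    matrix(rep(c(0L, 0L, 255L), each = n_blue), ncol = 3L)
  )
  rgbToHSV(newPointCloud(P, rgb, sourceId = "hue-fixture"))
}

# A permissive config for small fixtures.
small_cfg <- function(...) {
  args <- list(...)
  if (!"minSegmentPoints" %in% names(args)) args$minSegmentPoints <- 10
  do.call(berryConfig, args)
}

# SliceStack whose centroids trace a semicircular arc of radius R with the
# chord along z, sampled uniformly along the arc (n slices).
semicircle_stack <- function(R = 10, n = 80) {
  phi <- seq(0, pi, length.out = n)
  zl <- (seq_len(n) - 0.5) * (2 * R / n)   # nominal even slice levels
  new("SliceStack", zLevels = zl, halfwidthMm = R / n,
      points = rep(list(cbind(0, 0)), n), areas = rep(1, n),
      perimeters = rep(1, n),
      centroids = cbind(R * sin(phi), 0, R * (1 - cos(phi))),
      valid = rep(TRUE, n), largestIndex = 1L)
}
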