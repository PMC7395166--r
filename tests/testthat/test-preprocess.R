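test_that("hue denoising partitions exactly on known hues", {
  cl <- make_hue_cloud(n_red = 100, n_green = 50)
  cfg <- small_cfg(noiseHueKeep = list(c(350, 30)))
  kept <- denoiseByHue(cl, cfg, quiet = TRUE)
  expect_equal(nPoints(kept), 100L)
  expect_true(all(hsvColours(kept)[, 1L] == 0))
  # keeping the whole hue circle is the identity
  all_cfg <- small_cfg(noiseHueKeep = list(c(0, 360)))
  expect_equal(coords(denoiseByHue(cl, all_cfg, quiet = TRUE)), coords(cl))
  # too few survivors is a hard error
  tight <- small_cfg(noiseHueKeep = list(c(350, 30)), minSegmentPoints = 500)
  expect_error(denoiseByHue(cl, tight, quiet = TRUE), "empty after denoising")
})

test_that("denoising a generator scene recovers the noise-free labels", {
  gen <- generateBerry(berrySpec(nPoints = 8000, noiseFrac = 0.10, seed = 5))
  cl <- rgbToHSV(gen$cloud)
  kept <- denoiseByHue(cl, berryConfig(), quiet = TRUE)
  expect_equal(nPoints(kept), sum(gen$truth$label != "noise"))
})

test_that("centering moves the moment to the origin and is idempotent", {
  one <- newPointCloud(matrix(c(5, 5, 5), 1L), matrix(0L, 1L, 3L))
  expect_equal(unname(coords(centerToOrigin(one))), matrix(0, 1L, 3L))
  two <- newPointCloud(rbind(c(0, 0, 0), c(2, 0, 0)), matrix(0L, 2L, 3L))
  expect_equal(unname(coords(centerToOrigin(two))),
               rbind(c(-1, 0, 0), c(1, 0, 0)))
  gen <- generateBerry(berrySpec(nPoints = 2000, seed = 2))$cloud
  once <- centerToOrigin(gen)
  expect_equal(coords(centerToOrigin(once)), coords(once))
  expect_lt(max(abs(colMeans(coords(once)))), 1e-9 * diff(range(coords(gen))))
})

test_that("principal-axis alignment maps the main orientation to z", {
  # points on the main diagonal align onto the z axis
  t <- seq(-1, 1, length.out = 51)
  seg <- centerToOrigin(newPointCloud(cbind(t, t, t), matrix(0L, 51L, 3L)))
  al <- alignPrincipalAxis(seg)
  expect_false(al$degenerate)
  expect_lt(max(abs(coords(al$cloud)[, 1:2])), 1e-9)
  expect_lt(max(abs(crossprod(al$rotation) - diag(3))), 1e-12)

  # an already z-aligned prolate cloud gets (close to) the identity
  set.seed(4)
  P <- cbind(rnorm(500, sd = 0.5), rnorm(500, sd = 0.4), rnorm(500, sd = 5))
  al2 <- alignPrincipalAxis(centerToOrigin(newPointCloud(P, matrix(0L, 500L, 3L))))
  expect_equal(abs(al2$rotation[3L, 3L]), 1, tolerance = 1e-3)

  # an exactly isotropic cloud is degenerate: identity + warning
  octa <- rbind(diag(3), -diag(3))
  expect_warning(
    al3 <- alignPrincipalAxis(newPointCloud(octa, matrix(0L, 6L, 3L))),
    "near-spherical")
  expect_true(al3$degenerate)
  expect_identical(al3$rotation, diag(3))
})

test_that("a known pre-rotation is recovered by alignment", {
  gen <- generateBerry(berrySpec(nPoints = 20000, seed = 7))
  cl <- rgbToHSV(gen$cloud)
  cfg <- berryConfig()
  base <- alignPrincipalAxis(centerToOrigin(denoiseByHue(cl, cfg, quiet = TRUE)),
                             holderHueRange = cfg$holderHueRange)
  axis0 <- base$rotation[3L, ]          # estimated axis in the raw frame
  set.seed(7)
  R0 <- random_rotation()
  rot <- cl
  rot@coords <- cl@coords %*% t(R0)
  al <- alignPrincipalAxis(centerToOrigin(denoiseByHue(rot, cfg, quiet = TRUE)),
                           holderHueRange = cfg$holderHueRange)
  axis1 <- al$rotation[3L, ]            # estimated axis in the rotated frame
  ang <- acos(min(1, abs(sum(axis1 * (R0 %*% axis0))))) * 180 / pi
  expect_lt(ang, 0.1)
})

test_that("segmentation splits berry and holder exactly by hue", {
  cl <- make_hue_cloud(n_red = 10000, n_blue = 2000)
  seg <- segmentBodyHolder(cl, berryConfig())
  expect_equal(nPoints(seg$holder), 2000L)
  expect_equal(nPoints(seg$body), 10000L)
  expect_true(all(hsvColours(seg$holder)[, 1L] == 240))

  gen <- generateBerry(berrySpec(nPoints = 8000, seed = 6))
  seg2 <- segmentBodyHolder(rgbToHSV(gen$cloud), berryConfig())
  expect_equal(nPoints(seg2$body), sum(gen$truth$label == "berry"))
  expect_equal(nPoints(seg2$holder), sum(gen$truth$label == "holder"))

  allred <- make_hue_cloud(n_red = 5000)
  expect_error(segmentBodyHolder(allred, berryConfig()),
               "holder segment empty")
})

test_that("holder height standardisation recovers metric scale", {
  # holder spanning z in [-2, 0] with height 38 mm gives scale factor 19
  set.seed(1)
  body <- newPointCloud(cbind(runif(50), runif(50), runif(50)),
                        matrix(0L, 50L, 3L))
  holder <- newPointCloud(cbind(runif(50), runif(50), runif(50, -2, 0)),
                          matrix(0L, 50L, 3L))
  holder@coords[1L, 3L] <- -2  # pin the exact extent
  holder@coords[2L, 3L] <- 0
  bc <- standardizeScale(body, holder, berryConfig())
  expect_equal(bc@scaleFactor, 19)

  flat <- holder
  flat@coords[, 3L] <- 0
  expect_error(standardizeScale(body, flat, berryConfig()), "z extent")
})

test_that("pre-scaling the raw cloud does not change the standardised body", {
  gen <- generateBerry(berrySpec(nPoints = 8000, seed = 9))
  b1 <- preprocessCloud(gen$cloud, quiet = TRUE)
  scaled <- gen$cloud
  scaled@coords <- scaled@coords * 37.2
  b2 <- preprocessCloud(scaled, quiet = TRUE)
  expect_equal(coords(b2), coords(b1), tolerance = 1e-9)
  expect_equal(b2@bodyHeightMm, b1@bodyHeightMm, tolerance = 1e-12)
})

test_that("body height is recovered in millimetres at reconstruction scale", {
  gen <- generateBerry(berrySpec(profile = "berry", heightMm = 31,
                                 globalScale = 0.013, nPoints = 30000,
                                 seed = 10))
  body <- preprocessCloud(gen$cloud, quiet = TRUE)
  expect_equal(body@bodyHeightMm, 31, tolerance = 0.2 / 31)
  expect_lt(max(abs(crossprod(body@rotation) - diag(3))), 1e-9)
  # alignment postcondition: top eigenvector of the body is near +/- z
  S <- crossprod(sweep(coords(body), 2L, colMeans(coords(body))))
  e1 <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  expect_lt(max(abs(e1[1:2])), 0.05)
})
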