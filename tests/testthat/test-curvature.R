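test_that("curvature estimates match closed forms on canonical surfaces", {
  # sphere R = 15: k1 = k2 = 1/15
  gen <- generateBerry(berrySpec(profile = "sphere", heightMm = 30,
                                 nPoints = 20000, seed = 2))
  b <- make_body(coords(gen$cloud)[gen$truth$label == "berry", ])
  f <- principalCurvatures(b, 30)
  ok <- !f@flagged
  expect_equal(median(f@kAvg[ok]), 1 / 15, tolerance = 0.05)
  expect_equal(median(f@k1[ok]), 1 / 15, tolerance = 0.07)
  expect_equal(median(f@k2[ok]), 1 / 15, tolerance = 0.07)

  # cylinder r = 10: k1 = 1/10, k2 = 0
  gen2 <- generateBerry(berrySpec(profile = "cylinder", radiusMm = 10,
                                  heightMm = 30, nPoints = 20000, seed = 2))
  b2 <- make_body(coords(gen2$cloud)[gen2$truth$label == "berry", ])
  f2 <- principalCurvatures(b2, 30)
  ok2 <- !f2@flagged
  expect_equal(median(f2@k1[ok2]), 0.1, tolerance = 0.10)
  expect_lt(abs(median(f2@k2[ok2])), 0.01)
  expect_equal(median(f2@kAvg[ok2]), 0.05, tolerance = 0.10)

  # noise-free plane: flat limit
  set.seed(3)
  Pp <- cbind(runif(4000, -10, 10), runif(4000, -10, 10),
              c(1e-9, numeric(3999)))
  fp <- principalCurvatures(make_body(Pp), 30)
  expect_lt(median(fp@kAvg[!fp@flagged]), 1e-3)

  # normals are unit and k1 >= k2 everywhere
  expect_equal(max(abs(sqrt(rowSums(f@normals^2)) - 1)), 0, tolerance = 1e-6)
  expect_true(all(f@k1[ok] >= f@k2[ok]))
})

test_that("MLS smoothing is nearly bias-free and reduces noise", {
  gen <- generateBerry(berrySpec(profile = "sphere", heightMm = 30,
                                 nPoints = 20000, seed = 4))
  clean <- make_body(coords(gen$cloud)[gen$truth$label == "berry", ])
  sm <- mlsSmooth(clean, radiusMm = 2, quiet = TRUE)
  # quadratic-fit bias bound on a sphere: radius^2 / (2 R) = 0.133 mm
  disp <- sqrt(rowSums((coords(sm) - coords(clean)) ^ 2))
  expect_lt(max(disp), 2 ^ 2 / (2 * 15))
  expect_equal(nPoints(sm), nPoints(clean))

  # radial noise sigma = 0.2 mm shrinks after smoothing
  noisy <- generateBerry(berrySpec(profile = "sphere", heightMm = 30,
                                   nPoints = 20000, noiseSigmaMm = 0.2,
                                   seed = 4))
  nb <- make_body(coords(noisy$cloud)[noisy$truth$label == "berry", ])
  resid <- function(body) {
    ctr <- colMeans(coords(body))
    sqrt(mean((sqrt(rowSums(sweep(coords(body), 2, ctr) ^ 2)) - 15) ^ 2))
  }
  before <- resid(nb)
  after <- resid(mlsSmooth(nb, radiusMm = 2, quiet = TRUE))
  expect_gt(before, 0.15)
  expect_lt(after, 0.2)          # below the injected noise level
  expect_lt(after, 0.8 * before) # and a clear variance reduction

  # sparse neighbourhoods: points are copied, counted and warned about
  set.seed(5)
  sparse <- make_body(matrix(runif(60, -50, 50), ncol = 3))
  w <- capture_warnings(sm2 <- mlsSmooth(sparse, radiusMm = 1, quiet = TRUE))
  expect_true(any(grepl("unsmoothed", w)))
  expect_equal(coords(sm2), coords(sparse))
})

test_that("patch aggregation averages the upper half of curvatures", {
  expect_equal(berry3d:::.upper_half_mean(c(1, 2, 3, 4)), 3.5)
  expect_equal(berry3d:::.upper_half_mean(c(3, 1, 2)), 2.5)  # median on top
  expect_equal(berry3d:::.upper_half_mean(5), 5)
})

test_that("curvature summary follows its defining arithmetic", {
  mk <- function(k) new("PatchSet", seeds = matrix(0, length(k), 3),
                        seedAnglesDeg = seq(0, 360, length.out = length(k) + 1)[-(length(k) + 1)],
                        members = rep(list(1L), length(k)),
                        patchCurvature = k)
  eq <- curvatureSummary(mk(rep(0.07, 16)))
  expect_identical(eq$cv_c, 0)
  expect_identical(eq$max_min_c, 1)
  two <- curvatureSummary(mk(rep(c(2, 4), 8)))
  expect_equal(two$cv_c, 1 / 3)
  expect_equal(two$max_min_c, 2)
  flat <- curvatureSummary(mk(c(rep(0.1, 15), 0)))
  expect_true(flat$maxMinMissing)
  expect_true(is.na(flat$max_min_c))
  expect_false(is.na(flat$cv_c))
})

test_that("sphere patches are uniform within estimator noise", {
  gen <- generateBerry(berrySpec(profile = "sphere", heightMm = 30,
                                 nPoints = 30000, seed = 6))
  body <- preprocessCloud(gen$cloud, quiet = TRUE)
  sm <- mlsSmooth(body, quiet = TRUE)
  field <- principalCurvatures(sm, 30)
  stack <- buildSlices(sm)
  patches <- buildPatches(sm, field, stack)
  k <- patchCurvatures(patches)
  expect_length(k, 16L)
  expect_true(all(abs(k - 1 / 15) / (1 / 15) < 0.05))
  cs <- curvatureSummary(patches)
  expect_lt(cs$cv_c, 0.05)
  expect_lt(cs$max_min_c, 1.15)
})

test_that("curvature scales as 1/c under uniform scaling; summaries are invariant", {
  gen <- generateBerry(berrySpec(profile = "berry", lobeAmplitude = 0.1,
                                 lobeCount = 4, nPoints = 10000, seed = 7))
  body <- preprocessCloud(gen$cloud, quiet = TRUE)
  f1 <- principalCurvatures(body, 20)
  scaled <- body
  scaled@coords <- body@coords * 2
  scaled@bodyHeightMm <- body@bodyHeightMm * 2
  f2 <- principalCurvatures(scaled, 20)
  ok <- !f1@flagged & !f2@flagged
  expect_equal(f2@kAvg[ok], f1@kAvg[ok] / 2, tolerance = 1e-9)
})

test_that("patch curvatures rotate with the fruit", {
  gen <- generateBerry(berrySpec(profile = "berry", lobeAmplitude = 0.15,
                                 lobeCount = 2, nPoints = 20000, seed = 8))
  body <- preprocessCloud(gen$cloud, quiet = TRUE)
  getk <- function(b) {
    sm <- mlsSmooth(b, quiet = TRUE)
    field <- principalCurvatures(sm, 30)
    patchCurvatures(buildPatches(sm, field, buildSlices(sm)))
  }
  k0 <- getk(body)
  th <- 22.5 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- body
  rot@coords <- body@coords %*% t(Rz)
  k1 <- getk(rot)
  # rotating by one patch step permutes the patch values cyclically
  expect_equal(k1[c(2:16, 1)], k0, tolerance = 0.05)
})
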