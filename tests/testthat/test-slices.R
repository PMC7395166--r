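test_that("cylinder slices recover the circular cross-section", {
  P <- sample_elliptic_cylinder(50000, 10, 10, 30, seed = 1)
  stack <- buildSlices(make_body(P), nSlices = 100)
  a <- sliceAreas(stack)
  ok <- stack@valid
  expect_true(all(ok))
  expect_equal(mean(a), pi * 100, tolerance = 0.02)
  cen <- sliceCentroids(stack)
  expect_lt(max(abs(cen[, 1:2])), 0.1)
})

test_that("degenerate slices are excluded from the largest-slice search", {
  # a cylinder with a lone point floating above: the top slices hold < 3
  # points and must be invalid without poisoning the search
  P <- rbind(sample_elliptic_cylinder(5000, 10, 10, 20, seed = 2),
             c(0, 0, 40))
  stack <- buildSlices(make_body(P), nSlices = 50)
  expect_true(any(!stack@valid))
  expect_true(stack@valid[stack@largestIndex])
  expect_lt(stack@zLevels[stack@largestIndex], 11)  # within the cylinder part
})

test_that("the largest slice sits where the profile is widest", {
  gen_cone <- generateBerry(berrySpec(profile = "cone", nPoints = 15000,
                                      seed = 3))
  body <- preprocessCloud(gen_cone$cloud, quiet = TRUE)
  st <- buildSlices(body)
  valid_idx <- which(st@valid)
  expect_equal(st@largestIndex, min(valid_idx))  # cone widens downward

  S <- sample_sphere(30000, 15, seed = 4)
  st2 <- buildSlices(make_body(S), nSlices = 100)
  expect_lte(abs(st2@largestIndex - 50.5), 1.5)  # equator of the sphere

  # berry profile: argmax of hull area within one slice of argmax r(z)^2
  gen <- generateBerry(berrySpec(profile = "berry", nPoints = 30000,
                                 seed = 5))
  truth <- gen$truth
  bodyb <- preprocessCloud(gen$cloud, quiet = TRUE)
  stb <- buildSlices(bodyb)
  zg <- seq(0, truth$spec$heightMm, length.out = 2000)
  rmax_z <- zg[which.max(truth$profileFn(zg, 0))]
  frac_true <- rmax_z / truth$spec$heightMm
  frac_got <- (stb@largestIndex - 0.5) / length(stb@zLevels)
  expect_lt(abs(frac_got - frac_true), 2 / length(stb@zLevels) + 1e-9)
})

test_that("bounding-box aspect follows the principal axes of the slice", {
  # axis-aligned 4 x 2 grid of points: exactly 2
  g <- as.matrix(expand.grid(x = seq(0, 4, 0.5), y = seq(0, 2, 0.5)))
  expect_equal(bboxAspect(list(points = g)), 2)
  # ellipse a = 20, b = 10 sampled densely: 2 within 2%
  th <- seq(0, 2 * pi, length.out = 4000)
  E <- cbind(20 * cos(th), 10 * sin(th)) + matrix(rnorm(8000, 0, 0.05), ncol = 2)
  expect_equal(bboxAspect(list(points = E)), 2, tolerance = 0.02)
  # circle: 1 within 2%
  C <- cbind(10 * cos(th), 10 * sin(th))
  expect_equal(bboxAspect(list(points = C)), 1, tolerance = 0.02)
  # collinear points have no width
  expect_error(bboxAspect(list(points = cbind(1:10, 2 * (1:10)))),
               "collinear")
})

test_that("circularity hits the closed forms for polygons and circles", {
  slice_of <- function(xy) {
    h <- hullMetrics2D(xy)
    list(points = xy, area = h$area, perimeter = h$perimeter)
  }
  sq <- slice_of(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-12)
  hexa <- slice_of(cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6)))
  expect_equal(circularity(hexa), pi * sqrt(3) / 6, tolerance = 1e-12)
  th <- seq(0, 2 * pi, length.out = 2000)
  circ <- slice_of(cbind(cos(th), sin(th)))
  expect_equal(circularity(circ), 1, tolerance = 0.005)
})

test_that("straightness is 1 for a coaxial cylinder and pi/2 for a semicircle", {
  P <- sample_elliptic_cylinder(40000, 8, 8, 30, seed = 6)
  st <- buildSlices(make_body(P))
  expect_equal(straightness(st), 1, tolerance = 1e-3)

  # synthetic stack whose centroids lie on a semicircular arc (chord 2R)
  arc <- semicircle_stack(R = 10, n = 80)
  expect_equal(straightness(arc, 0, 1), pi / 2, tolerance = 0.01)

  # invalid slices inside the window are bridged, not fatal
  holes <- arc
  holes@valid[seq(5, 75, by = 7)] <- FALSE
  expect_equal(straightness(holes, 0, 1), pi / 2, tolerance = 0.01)
})

test_that("hull area and perimeter match the brute-force oracle exactly", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    xy <- matrix(rnorm(2 * n), ncol = 2)
    got <- hullMetrics2D(xy)
    ref <- brute_hull_metrics(xy)
    expect_equal(got$area, ref$area, tolerance = 1e-12)
    expect_equal(got$perimeter, ref$perimeter, tolerance = 1e-12)
  }
})

test_that("slice metrics respect their hard bounds on random berries", {
  set.seed(42)
  for (s in 1:5) {
    sp <- berrySpec(profile = "berry", lobeAmplitude = runif(1, 0, 0.2),
                    lobeCount = sample(2:5, 1),
                    axisAmplitudeMm = runif(1, 0, 1.5),
                    axisShape = "sine", nPoints = 8000, seed = 100 + s)
    body <- preprocessCloud(generateBerry(sp)$cloud, quiet = TRUE)
    st <- buildSlices(body)
    sl <- largestSlice(st)
    expect_lte(circularity(sl), 1 + 1e-9)
    expect_gte(bboxAspect(sl), 1)
    expect_gte(straightness(st), 1 - 1e-9)
  }
})
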