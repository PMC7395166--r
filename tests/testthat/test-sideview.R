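test_that("silhouette areas of solids of revolution match closed forms", {
  # circular cylinder radius 10, band height 15: every view area = 300
  P <- sample_elliptic_cylinder(50000, 10, 10, 15, seed = 1)
  views <- projectSideViews(make_body(P), nViews = 100)
  expect_equal(mean(viewAreas(views)), 300, tolerance = 0.02)
  expect_lt(diff(range(viewAreas(views))) / mean(viewAreas(views)), 0.02)

  # elliptic cylinder: areas oscillate between 2bh and 2ah
  E <- sample_elliptic_cylinder(50000, 20, 10, 15, seed = 2)
  v2 <- projectSideViews(make_body(E), nViews = 100)
  expect_equal(max(viewAreas(v2)), 2 * 20 * 15, tolerance = 0.02)
  expect_equal(min(viewAreas(v2)), 2 * 10 * 15, tolerance = 0.02)
  expect_equal(areaMetrics(v2)$max_min_a, 2, tolerance = 0.02)
})

test_that("views half a turn apart have identical areas", {
  gen <- generateBerry(berrySpec(profile = "berry", lobeAmplitude = 0.15,
                                 lobeCount = 3, nPoints = 12000, seed = 3))
  body <- preprocessCloud(gen$cloud, quiet = TRUE)
  views <- projectSideViews(equatorialBand(body), nViews = 100)
  a <- viewAreas(views)
  expect_equal(a[1:50], a[51:100], tolerance = 1e-12)
})

test_that("area metrics follow their defining arithmetic", {
  mk <- function(a) new("SideViewSet", nViews = length(a),
                        stepDeg = 360 / length(a), areas = a,
                        anglesDeg = rep(0, length(a)))
  eq <- areaMetrics(mk(rep(7, 10)))
  expect_identical(eq$cv_a, 0)
  expect_identical(eq$max_min_a, 1)
  two <- areaMetrics(mk(rep(c(2, 4), 5)))
  expect_equal(two$cv_a, 1 / 3)
  expect_equal(two$max_min_a, 2)
})

test_that("orientation CV uses deviation from the mean axis plus 90", {
  mk <- function(ang) new("SideViewSet", nViews = length(ang),
                          stepDeg = 360 / length(ang),
                          areas = rep(1, length(ang)), anglesDeg = ang)
  # axes at 80 and 100 degrees about a 90-degree mean: SD/mean = 10/90
  expect_equal(orientationCV(mk(c(80, 100))), 10 / 90)
  # identical axes: zero dispersion, wherever the mean axis points
  expect_equal(orientationCV(mk(rep(0, 8))), 0)
  expect_equal(orientationCV(mk(rep(90, 8))), 0)
  # wrap-around: 179 and 1 degree are 2 degrees apart axially
  expect_equal(orientationCV(mk(c(179, 1))), 1 / 90)
})

test_that("an upright solid of revolution has near-zero orientation CV", {
  P <- sample_elliptic_cylinder(30000, 5, 5, 25, seed = 4)
  views <- projectSideViews(make_body(P), nViews = 100)
  expect_lt(orientationCV(views), 0.01)
})

test_that("bending the axis raises the orientation CV", {
  straight <- berrySpec(profile = "cylinder", radiusMm = 8, nPoints = 15000,
                        seed = 12)
  bent <- berrySpec(profile = "cylinder", radiusMm = 8, axisShape = "sine",
                    axisAmplitudeMm = 2, nPoints = 15000, seed = 12)
  cv <- vapply(list(straight, bent), function(sp) {
    body <- preprocessCloud(generateBerry(sp)$cloud, quiet = TRUE)
    orientationCV(projectSideViews(equatorialBand(body)))
  }, 0)
  expect_gt(cv[2L], cv[1L])
})

test_that("side-view metrics are invariant to uniform scaling", {
  P <- sample_elliptic_cylinder(5000, 12, 9, 20, seed = 5)
  v1 <- projectSideViews(make_body(P), nViews = 50)
  v2 <- projectSideViews(make_body(P * 3), nViews = 50)
  expect_equal(viewAreas(v2), 9 * viewAreas(v1), tolerance = 1e-12)
  expect_equal(areaMetrics(v2)$cv_a, areaMetrics(v1)$cv_a, tolerance = 1e-12)
  expect_equal(areaMetrics(v2)$max_min_a, areaMetrics(v1)$max_min_a,
               tolerance = 1e-12)
  expect_equal(orientationCV(v2), orientationCV(v1), tolerance = 1e-12)
})

test_that("the equatorial band keeps exactly the middle height window", {
  set.seed(6)
  z <- runif(20000, 0, 100)
  P <- cbind(runif(20000), runif(20000), z)
  body <- make_body(P)
  band <- equatorialBand(body, 0.25, 0.75)
  expect_equal(nPoints(band), sum(z >= 25 & z <= 75))
  flat <- make_body(cbind(runif(100), runif(100), 1))
  expect_error(equatorialBand(flat), "zero height")
})
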