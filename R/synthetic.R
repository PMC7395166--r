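# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic berry scene
#'
#' Parametrises a coloured berry-plus-holder point cloud with controllable
#' deformations and exact ground truth, emulating a structure-from-motion
#' reconstruction of a fruit on its reference holder. The berry is a
#' surface of revolution `r(z)` (one of four named profile families)
#' optionally modulated by angular lobes
#' `r(z, theta) = r(z) * (1 + a * cos(m * theta))`, a lateral axis offset
#' (sinusoidal or circular-arc bend), a rigid tilt and an arbitrary global
#' scale. Surface points are area-weighted samples; the holder is a
#' 38 x 19 x 19 mm foam block under the berry base; optional stray points
#' with off-palette hues emulate reconstruction noise.
#'
#' @param profile `"berry"` (smooth conic-berry spline), `"cylinder"`,
#'   `"cone"` or `"sphere"`.
#' @param heightMm berry body height (for `"sphere"` the diameter).
#' @param radiusMm maximum profile radius.
#' @param lobeAmplitude,lobeCount angular radius modulation `a` and `m`.
#' @param axisShape `"none"`, `"sine"` (lateral offset
#'   `A * sin(2 * pi * p * z/H)`) or `"arc"` (offset
#'   `A * sqrt(1 - (2 z/H - 1)^2)`; with `A = H/2` the axis is an exact
#'   semicircle of chord H).
#' @param axisAmplitudeMm lateral offset amplitude `A` in mm.
#' @param axisPeriods sine periods `p` over the height.
#' @param tiltDeg rigid rotation about the x axis applied to the whole
#'   scene (recorded in the ground truth).
#' @param globalScale arbitrary reconstruction scale applied last.
#' @param nPoints total points in the scene (berry + holder + noise),
#'   >= 1000.
#' @param noiseSigmaMm Gaussian displacement of berry points along the
#'   local surface normal.
#' @param noiseFrac fraction of stray random-hue points.
#' @param seed RNG seed; the same spec and seed reproduce the cloud
#'   exactly.
#' @return A list of class `"BerrySpec"`.
#' @seealso [generateBerry()], [makeFixtureSuite()]
#' @export
berrySpec <- function(profile = c("berry", "cylinder", "cone", "sphere"),
                      heightMm = 30, radiusMm = 12,
                      lobeAmplitude = 0, lobeCount = 0,
                      axisShape = c("none", "sine", "arc"),
                      axisAmplitudeMm = 0, axisPeriods = 1,
                      tiltDeg = 0, globalScale = 1,
                      nPoints = 50000,
                      noiseSigmaMm = 0, noiseFrac = 0,
                      seed = 1) {
  profile <- match.arg(profile)
  axisShape <- match.arg(axisShape)
  stopifnot(heightMm > 0, radiusMm > 0, nPoints >= 1000,
            lobeAmplitude >= 0, lobeAmplitude < 1,
            noiseFrac >= 0, noiseFrac < 1, noiseSigmaMm >= 0,
            globalScale > 0)
  spec <- list(profile = profile, heightMm = heightMm, radiusMm = radiusMm,
               lobeAmplitude = lobeAmplitude, lobeCount = as.integer(lobeCount),
               axisShape = axisShape, axisAmplitudeMm = axisAmplitudeMm,
               axisPeriods = axisPeriods, tiltDeg = tiltDeg,
               globalScale = globalScale, nPoints = as.integer(nPoints),
               noiseSigmaMm = noiseSigmaMm, noiseFrac = noiseFrac,
               seed = as.integer(seed))
  class(spec) <- c("BerrySpec", "list")
  spec
}

# profile radius r(z) on z in [0, H], before lobe modulation
.profile_fun <- function(spec) {
  H <- spec$heightMm
  r0 <- spec$radiusMm
  switch(spec$profile,
    cylinder = function(z) rep(r0, length(z)),
    cone = function(z) r0 * (1 - 0.98 * z / H),   # apex kept slightly open
    sphere = function(z) {
      R <- H / 2
      sqrt(pmax(R ^ 2 - (z - R) ^ 2, 0))
    },
    berry = {
      f <- stats::splinefun(c(0, 0.15, 0.40, 0.70, 1) * H,
                            c(0.35, 0.85, 1.00, 0.72, 0.06) * r0,
                            method = "natural")
      function(z) pmax(f(z), 0.02 * r0)
    }
  )
}

# lateral axis offset (x displacement) as a function of z
.axis_fun <- function(spec) {
  H <- spec$heightMm
  A <- spec$axisAmplitudeMm
  switch(spec$axisShape,
    none = function(z) numeric(length(z)) + 0,
    sine = function(z) A * sin(2 * pi * spec$axisPeriods * z / H),
    arc = function(z) A * sqrt(pmax(1 - (2 * z / H - 1) ^ 2, 0))
  )
}

.hsv_to_rgb255 <- function(h, s, v) {
  hex <- grDevices::hsv(pmin(pmax(h %% 360, 0), 359.999) / 360, s, v)
  t(grDevices::col2rgb(hex))
}

#' Generate a synthetic berry scene with ground truth
#'
#' Realises a \code{\link{berrySpec}}: area-weighted surface samples of
#' the deformed berry surface, holder-block samples below the base, and
#' optional stray noise points; colours are disjoint hue bands (berry red,
#' holder blue, noise green-cyan) so that hue segmentation has an exact
#' ground truth. The tilt and global scale are applied last and recorded.
#'
#' @param spec a `"BerrySpec"`.
#' @return A list with `cloud` (a
#'   \code{\linkS4class{ColouredPointCloud}}) and `truth`, a list holding
#'   the per-point part `label` (factor berry/holder/noise), the axis
#'   offset function `axisFn`, the profile function `profileFn(z, theta)`,
#'   closed-form principal curvatures `k1`/`k2` where the family admits
#'   them (sphere, cylinder; otherwise `NA`), the applied `rotation` and
#'   `scale`, and the generating `spec`.
#' @examples
#' gen <- generateBerry(berrySpec(profile = "cylinder", nPoints = 5000))
#' table(gen$truth$label)
#' @export
generateBerry <- function(spec) {
  stopifnot(inherits(spec, "BerrySpec"))
  .with_seed(spec$seed, {
    H <- spec$heightMm
    rfun <- .profile_fun(spec)
    afun <- .axis_fun(spec)
    a <- spec$lobeAmplitude
    m <- spec$lobeCount
    rmod <- function(z, th) rfun(z) * (1 + a * cos(m * th))
    surf <- function(z, th) {
      r <- rmod(z, th)
      cbind(afun(z) + r * cos(th), r * sin(th), z)
    }

    # area weights on a fine (z, theta) grid via numerical cross product
    nzg <- 400L
    ntg <- 256L
    dz <- H / nzg
    dth <- 2 * pi / ntg
    zg <- (seq_len(nzg) - 0.5) * dz
    tg <- (seq_len(ntg) - 0.5) * dth
    G <- expand.grid(z = zg, th = tg)
    eps <- 1e-4
    dpz <- (surf(G$z + eps, G$th) - surf(G$z - eps, G$th)) / (2 * eps)
    dpt <- (surf(G$z, G$th + eps) - surf(G$z, G$th - eps)) / (2 * eps)
    crossp <- cbind(dpz[, 2] * dpt[, 3] - dpz[, 3] * dpt[, 2],
                    dpz[, 3] * dpt[, 1] - dpz[, 1] * dpt[, 3],
                    dpz[, 1] * dpt[, 2] - dpz[, 2] * dpt[, 1])
    w <- sqrt(rowSums(crossp ^ 2))
    berry_area <- sum(w) * dz * dth
    holder_faces <- cbind(
      area = c(19 * 38, 19 * 38, 19 * 38, 19 * 38, 19 * 19))
    holder_area <- sum(holder_faces)

    n <- spec$nPoints
    n_noise <- round(spec$noiseFrac * n)
    n_rest <- n - n_noise
    n_berry <- round(n_rest * berry_area / (berry_area + holder_area))
    n_holder <- n_rest - n_berry

    # berry: multinomial over grid cells, jittered within the cell
    cell <- sample.int(nrow(G), n_berry, replace = TRUE, prob = w)
    zb <- G$z[cell] + (stats::runif(n_berry) - 0.5) * dz
    thb <- G$th[cell] + (stats::runif(n_berry) - 0.5) * dth
    zb <- pmin(pmax(zb, 0), H)
    Pb <- surf(zb, thb)
    if (spec$noiseSigmaMm > 0) {
      nrm <- cbind(dpz[cell, 2] * dpt[cell, 3] - dpz[cell, 3] * dpt[cell, 2],
                   dpz[cell, 3] * dpt[cell, 1] - dpz[cell, 1] * dpt[cell, 3],
                   dpz[cell, 1] * dpt[cell, 2] - dpz[cell, 2] * dpt[cell, 1])
      nrm <- nrm / sqrt(rowSums(nrm ^ 2))
      Pb <- Pb + nrm * stats::rnorm(n_berry, 0, spec$noiseSigmaMm)
    }

    # holder: 38 x 19 x 19 mm block below the base, sides plus bottom
    face <- sample.int(5L, n_holder, replace = TRUE,
                       prob = holder_faces[, 1])
    u <- stats::runif(n_holder, -9.5, 9.5)
    v <- stats::runif(n_holder)
    Ph <- matrix(0, n_holder, 3L)
    zh <- -38 * v
    Ph[face == 1L, ] <- cbind(u[face == 1L], 9.5, zh[face == 1L])
    Ph[face == 2L, ] <- cbind(u[face == 2L], -9.5, zh[face == 2L])
    Ph[face == 3L, ] <- cbind(9.5, u[face == 3L], zh[face == 3L])
    Ph[face == 4L, ] <- cbind(-9.5, u[face == 4L], zh[face == 4L])
    bt <- face == 5L
    Ph[bt, ] <- cbind(u[bt], stats::runif(sum(bt), -9.5, 9.5), -38)

    # stray noise points: uniform in the padded scene box, off-palette hue
    lo <- c(-spec$radiusMm - abs(spec$axisAmplitudeMm) - 10, -15, -45)
    hi <- c(spec$radiusMm + abs(spec$axisAmplitudeMm) + 10, 15, H + 8)
    Pn <- cbind(stats::runif(n_noise, lo[1], hi[1]),
                stats::runif(n_noise, lo[2], hi[2]),
                stats::runif(n_noise, lo[3], hi[3]))

    P <- rbind(Pb, Ph, Pn)
    label <- factor(rep(c("berry", "holder", "noise"),
                        c(n_berry, n_holder, n_noise)),
                    levels = c("berry", "holder", "noise"))

    rgb <- rbind(
      .hsv_to_rgb255(stats::runif(n_berry, -12, 12), stats::runif(n_berry, 0.80, 0.98),
                     stats::runif(n_berry, 0.60, 0.90)),
      .hsv_to_rgb255(stats::runif(n_holder, 218, 242), stats::runif(n_holder, 0.70, 0.90),
                     stats::runif(n_holder, 0.35, 0.55)),
      .hsv_to_rgb255(stats::runif(n_noise, 65, 175), stats::runif(n_noise, 0.50, 0.95),
                     stats::runif(n_noise, 0.40, 0.90))
    )

    # rigid tilt about x, then arbitrary global scale, applied last
    phi <- spec$tiltDeg * pi / 180
    R <- rbind(c(1, 0, 0),
               c(0, cos(phi), -sin(phi)),
               c(0, sin(phi), cos(phi)))
    P <- (P %*% t(R)) * spec$globalScale

    cf <- switch(spec$profile,
      sphere = list(k1 = 2 / H, k2 = 2 / H),
      cylinder = list(k1 = 1 / spec$radiusMm, k2 = 0),
      list(k1 = NA_real_, k2 = NA_real_))

    cloud <- newPointCloud(P, rgb,
                           sourceId = sprintf("synthetic-%s-seed%d",
                                              spec$profile, spec$seed))
    list(cloud = cloud,
         truth = list(label = label, axisFn = afun,
                      profileFn = rmod, k1 = cf$k1, k2 = cf$k2,
                      rotation = R, scale = spec$globalScale,
                      berryAreaMm2 = berry_area, spec = spec))
  })
}

# numerical arc-length / chord ratio of the berry axis over [zlo, zhi]
.axis_arc_chord <- function(axisFn, zlo, zhi, n = 4000L) {
  z <- seq(zlo, zhi, length.out = n)
  x <- axisFn(z)
  arc <- sum(sqrt(diff(x) ^ 2 + diff(z) ^ 2))
  chord <- sqrt((x[n] - x[1]) ^ 2 + (zhi - zlo) ^ 2)
  arc / chord
}

#' Write the standard synthetic fixture suite
#'
#' Generates six named berry scenes (ideal cone, sphere, lobed, bent
#' axis, tilted and rescaled, noisy), writes each as a binary PLY, and
#' writes a JSON manifest recording every spec, its hash and the expected
#' metric behaviour (exact ideal values where the solid is a surface of
#' revolution; a quadrature arc/chord prediction for the bent axis).
#'
#' @param outDir output directory (created if missing).
#' @param nPoints points per fixture scene.
#' @param seed base RNG seed; fixture i uses `seed + i - 1`.
#' @return Invisibly, the manifest as a list; also written to
#'   `manifest.json` in `outDir`.
#' @export
makeFixtureSuite <- function(outDir, nPoints = 50000, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    `ideal-cone` = berrySpec(profile = "cone", heightMm = 30, radiusMm = 12,
                             nPoints = nPoints),
    sphere = berrySpec(profile = "sphere", heightMm = 30, nPoints = nPoints),
    lobed = berrySpec(profile = "berry", lobeAmplitude = 0.2, lobeCount = 2,
                      nPoints = nPoints),
    `bent-axis` = berrySpec(profile = "cylinder", radiusMm = 8,
                            axisShape = "sine", axisAmplitudeMm = 2,
                            nPoints = nPoints),
    `tilted-rescaled` = berrySpec(profile = "berry", lobeAmplitude = 0.2,
                                  lobeCount = 2, tiltDeg = 25,
                                  globalScale = 0.013, nPoints = nPoints),
    noisy = berrySpec(profile = "berry", noiseSigmaMm = 0.2,
                      noiseFrac = 0.05, nPoints = nPoints)
  )
  manifest <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    sp <- specs[[i]]
    sp$seed <- as.integer(seed + i - 1)
    gen <- generateBerry(sp)
    file <- file.path(outDir, paste0(nm, ".ply"))
    writePLY(gen$cloud, file, encoding = "binary_le")
    expected <- if (sp$lobeAmplitude == 0 && sp$axisAmplitudeMm == 0 &&
                    sp$noiseSigmaMm == 0) {
      list(cv_a = c(0, 0.02), max_min_a = c(1, 1.03),
           cv_d = c(0, 0.02), l_w = c(1, 1.03), str = c(1, 1.01))
    } else if (sp$axisAmplitudeMm > 0) {
      qac <- .axis_arc_chord(.axis_fun(sp), 0.105 * sp$heightMm,
                             0.895 * sp$heightMm)
      list(str = c(0.98 * qac, 1.02 * qac))
    } else {
      list(max_min_a = c(1.2, 1.8))
    }
    manifest[[nm]] <- list(file = basename(file),
                           spec = unclass(sp),
                           specHash = configHash(sp),
                           expected = expected)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
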