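#' Remove reconstruction noise by hue thresholding
#'
#' Keeps only points whose hue falls inside the configured berry/holder
#' intervals; stray points introduced by the multi-view reconstruction
#' (background, turntable, speckle) fall outside those bands and are
#' discarded. The retained fraction is reported via `message()`.
#'
#' @param cloud a \code{\linkS4class{ColouredPointCloud}} with HSV
#'   populated (see [rgbToHSV()]).
#' @param cfg a configuration from [berryConfig()]; uses `noiseHueKeep`
#'   and `minSegmentPoints`.
#' @param quiet suppress the retained-fraction message.
#' @return The filtered cloud.
#' @export
denoiseByHue <- function(cloud, cfg = berryConfig(), quiet = FALSE) {
  h <- hsvColours(cloud)[, 1L]
  keep <- .hue_in_ranges(h, cfg$noiseHueKeep)
  if (sum(keep) < cfg$minSegmentPoints) {
    stop("cloud empty after denoising: ", sum(keep),
         " points retained (minimum ", cfg$minSegmentPoints, ")",
         call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("denoise: retained %d/%d points (%.1f%%)",
                    sum(keep), length(keep), 100 * mean(keep)))
  }
  .subset_cloud(cloud, keep)
}

.subset_cloud <- function(cloud, idx) {
  cloud@coords <- cloud@coords[idx, , drop = FALSE]
  cloud@rgb <- cloud@rgb[idx, , drop = FALSE]
  if (nrow(cloud@hsv) > 0L) cloud@hsv <- cloud@hsv[idx, , drop = FALSE]
  if (nrow(cloud@extra) > 0L) cloud@extra <- cloud@extra[idx, , drop = FALSE]
  validObject(cloud)
  cloud
}

#' Translate a cloud so its moment sits at the origin
#'
#' Subtracts the arithmetic mean (the cloud's moment) from every
#' coordinate. Idempotent.
#'
#' @param cloud a \code{\linkS4class{ColouredPointCloud}}.
#' @return The centred cloud.
#' @export
centerToOrigin <- function(cloud) {
  ctr <- colMeans(cloud@coords)
  cloud@coords <- sweep(cloud@coords, 2L, ctr)
  cloud
}

#' Rotate a cloud so its main orientation lies along z
#'
#' The main orientation is the eigenvector of the largest eigenvalue of
#' the point covariance (1/N normalisation). The returned rotation maps it
#' onto the z axis. The axial sign is chosen so that holder-coloured
#' points end up at negative z (holder down); without holder information
#' the hemisphere containing more points goes down. When the covariance is
#' near-spherical (largest/second eigenvalue < 1 + 1e-6) the orientation
#' is undefined: a warning is raised and the identity rotation applied.
#'
#' @param cloud a centred \code{\linkS4class{ColouredPointCloud}}.
#' @param holderHueRange optional hue interval locating the holder, used
#'   only for the sign choice; requires HSV populated.
#' @return A list with `cloud` (rotated), `rotation` (the 3 x 3 matrix
#'   applied, so `aligned = raw %*% t(rotation)`) and `degenerate`.
#' @export
alignPrincipalAxis <- function(cloud, holderHueRange = NULL) {
  P <- cloud@coords
  ctr <- colMeans(P)
  C <- sweep(P, 2L, ctr)
  S <- crossprod(C) / nrow(C)
  eg <- eigen(S, symmetric = TRUE)
  degenerate <- eg$values[1L] < (1 + 1e-6) * eg$values[2L]
  if (degenerate) {
    warning("near-spherical covariance: principal axis undefined, ",
            "identity rotation applied", call. = FALSE)
    return(list(cloud = cloud, rotation = diag(3), degenerate = TRUE))
  }
  v1 <- eg$vectors[, 1L]
  v2 <- eg$vectors[, 2L]
  v3 <- eg$vectors[, 3L]
  R <- rbind(v2, v3, v1)            # rows: new x, y, z axes
  if (det(R) < 0) R[2L, ] <- -R[2L, ]  # proper rotation
  rotated <- P %*% t(R)
  # axial sign: holder (or the point-heavier hemisphere) goes to negative z
  zc <- rotated[, 3L] - mean(rotated[, 3L])
  flip <- if (!is.null(holderHueRange) && nrow(cloud@hsv) > 0L) {
    hsel <- .hue_in_ranges(cloud@hsv[, 1L], list(holderHueRange))
    any(hsel) && mean(zc[hsel]) > 0
  } else {
    mean(zc > 0) > 0.5
  }
  if (flip) {
    F180 <- diag(c(1, -1, -1))      # 180 deg about x
    R <- F180 %*% R
    rotated <- P %*% t(R)
  }
  cloud@coords <- rotated
  dimnames(cloud@coords) <- list(NULL, c("x", "y", "z"))
  list(cloud = cloud, rotation = R, degenerate = FALSE)
}

#' Segment the berry body from the holder
#'
#' Splits an aligned, denoised cloud into holder (hue inside
#' `holderHueRange`) and body (the complement).
#'
#' @param cloud a \code{\linkS4class{ColouredPointCloud}} with HSV
#'   populated.
#' @param cfg a configuration from [berryConfig()].
#' @return A list with `body` and `holder` clouds.
#' @export
segmentBodyHolder <- function(cloud, cfg = berryConfig()) {
  h <- hsvColours(cloud)[, 1L]
  is_holder <- .hue_in_ranges(h, list(cfg$holderHueRange))
  n_holder <- sum(is_holder)
  n_body <- sum(!is_holder)
  if (n_holder < cfg$minSegmentPoints) {
    stop(if (n_holder == 0L) "holder segment empty" else
         paste0("holder segment too small: ", n_holder, " points (minimum ",
                cfg$minSegmentPoints, ")"), call. = FALSE)
  }
  if (n_body < cfg$minSegmentPoints) {
    stop(if (n_body == 0L) "body segment empty" else
         paste0("body segment too small: ", n_body, " points (minimum ",
                cfg$minSegmentPoints, ")"), call. = FALSE)
  }
  list(body = .subset_cloud(cloud, !is_holder),
       holder = .subset_cloud(cloud, is_holder))
}

#' Standardise a body cloud to millimetres using the holder height
#'
#' Multi-view reconstruction fixes geometry only up to a global scale; the
#' holder's known physical height recovers it. The scale factor is
#' `holderHeightMm / (max z - min z)` of the holder segment; body
#' coordinates are multiplied by it and re-centred at the origin (the
#' centroid drift caused by removing the holder is recorded, in mm).
#'
#' @param body,holder aligned clouds from [segmentBodyHolder()].
#' @param cfg a configuration from [berryConfig()].
#' @param rotation the rotation applied during alignment (recorded).
#' @param degenerate whether the alignment was degenerate (recorded).
#' @return A \code{\linkS4class{BodyCloud}} in millimetres.
#' @export
standardizeScale <- function(body, holder, cfg = berryConfig(),
                             rotation = diag(3), degenerate = FALSE) {
  zext <- diff(range(holder@coords[, 3L]))
  if (zext <= 1e-12) {
    stop("holder has no z extent; cannot standardise scale", call. = FALSE)
  }
  s <- cfg$holderHeightMm / zext
  P <- body@coords * s
  ctr <- colMeans(P)
  drift <- sqrt(sum(ctr ^ 2))
  P <- sweep(P, 2L, ctr)
  out <- new("BodyCloud",
             coords = P, rgb = body@rgb, hsv = body@hsv,
             extra = body@extra, extraTypes = body@extraTypes,
             sourceId = body@sourceId, nDropped = body@nDropped,
             scaleFactor = s, rotation = rotation,
             bodyHeightMm = diff(range(P[, 3L])),
             centroidDriftMm = drift, degenerateAxis = degenerate)
  validObject(out)
  out
}

#' Run the full pre-processing chain
#'
#' Composes the stages in order: HSV conversion (if needed), hue
#' denoising, translation to the origin, principal-axis alignment,
#' body/holder segmentation and metric scale standardisation. After
#' alignment the postcondition is asserted: the top covariance eigenvector
#' of the aligned cloud lies within 1e-6 of (0, 0, +/-1).
#'
#' @param cloud a raw \code{\linkS4class{ColouredPointCloud}}.
#' @param cfg a configuration from [berryConfig()].
#' @param quiet suppress progress messages.
#' @return A \code{\linkS4class{BodyCloud}} ready for the metric stages.
#' @examples
#' gen <- generateBerry(berrySpec(nPoints = 8000, seed = 1))
#' body <- preprocessCloud(gen$cloud, quiet = TRUE)
#' body
#' @export
preprocessCloud <- function(cloud, cfg = berryConfig(), quiet = FALSE) {
  if (nrow(cloud@hsv) == 0L) cloud <- rgbToHSV(cloud)
  cloud <- denoiseByHue(cloud, cfg, quiet = quiet)
  cloud <- centerToOrigin(cloud)
  al <- alignPrincipalAxis(cloud, holderHueRange = cfg$holderHueRange)
  if (!al$degenerate) {
    S <- crossprod(sweep(al$cloud@coords, 2L, colMeans(al$cloud@coords)))
    e1 <- eigen(S, symmetric = TRUE)$vectors[, 1L]
    stopifnot(max(abs(e1[1:2])) <= 1e-6)
  }
  seg <- segmentBodyHolder(al$cloud, cfg)
  standardizeScale(seg$body, seg$holder, cfg,
                   rotation = al$rotation, degenerate = al$degenerate)
}
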