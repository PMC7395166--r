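# population CV: sd is 1/N-normalised for consistency across all metrics
.pop_sd <- function(x) sqrt(mean((x - mean(x)) ^ 2))
.pop_cv <- function(x) .pop_sd(x) / mean(x)

#' Extract the equatorial band of a body cloud
#'
#' Retains the points in the middle band of the body height (middle 50%
#' by default), removing the calyx end and the nose so that side-view
#' metrics measure the berry's equatorial symmetry. The band is re-centred
#' at its own moment (all downstream side-view quantities are translation
#' invariant).
#'
#' @param body a \code{\linkS4class{BodyCloud}}.
#' @param lowerFrac,upperFrac height fractions bounding the band.
#' @return A \code{\linkS4class{BodyCloud}} containing the band.
#' @export
equatorialBand <- function(body, lowerFrac = 0.25, upperFrac = 0.75) {
  stopifnot(is(body, "BodyCloud"), lowerFrac < upperFrac)
  z <- body@coords[, 3L]
  H <- diff(range(z))
  if (!(H > 0)) stop("body has zero height; no equatorial band", call. = FALSE)
  zlo <- min(z) + lowerFrac * H
  zhi <- min(z) + upperFrac * H
  keep <- z >= zlo & z <= zhi
  if (!any(keep)) stop("equatorial band is empty", call. = FALSE)
  band <- body
  band@coords <- body@coords[keep, , drop = FALSE]
  band@rgb <- body@rgb[keep, , drop = FALSE]
  if (nrow(body@hsv) > 0L) band@hsv <- body@hsv[keep, , drop = FALSE]
  if (nrow(body@extra) > 0L) band@extra <- body@extra[keep, , drop = FALSE]
  band@coords <- sweep(band@coords, 2L, colMeans(band@coords))
  band@bodyHeightMm <- diff(range(band@coords[, 3L]))
  validObject(band)
  band
}

#' Project rotational side views and measure their silhouettes
#'
#' Rotates the band about the z axis in `360/nViews`-degree steps
#' (equivalently, walks a camera around the fruit) and projects each pose
#' onto the x-z plane. Per view it records the convex-hull area of the
#' projected points and the major-axis angle of the projection (first
#' principal direction of the 2D covariance), as an axial angle from the
#' z axis in [0, 180) degrees.
#'
#' @param band a \code{\linkS4class{BodyCloud}} from [equatorialBand()].
#' @param nViews number of views; the default 100 gives a 3.6-degree step.
#' @return A \code{\linkS4class{SideViewSet}}.
#' @export
projectSideViews <- function(band, nViews = 100) {
  stopifnot(is(band, "BodyCloud"), nViews >= 3)
  P <- band@coords
  step <- 360 / nViews
  areas <- numeric(nViews)
  angles <- numeric(nViews)
  for (i in seq_len(nViews)) {
    th <- (i - 1L) * step * pi / 180
    px <- P[, 1L] * cos(th) + P[, 2L] * sin(th)
    proj <- cbind(px, P[, 3L])
    h <- hullMetrics2D(proj)
    if (!h$valid) {
      stop("side view ", i, " has fewer than 3 non-collinear points",
           call. = FALSE)
    }
    areas[i] <- h$area
    ctr <- colMeans(proj)
    S <- crossprod(sweep(proj, 2L, ctr)) / nrow(proj)
    e <- eigen(S, symmetric = TRUE)$vectors[, 1L]
    angles[i] <- (atan2(e[1L], e[2L]) * 180 / pi) %% 180
  }
  new("SideViewSet", nViews = as.integer(nViews), stepDeg = step,
      areas = areas, anglesDeg = angles)
}

#' Side-view area uniformity metrics
#'
#' The coefficient of variation of the per-view silhouette areas (CV_A)
#' and the ratio of the maximum to the minimum area (Max_A/Min_A). A
#' perfect solid of revolution has CV_A = 0 and Max_A/Min_A = 1.
#'
#' @param views a \code{\linkS4class{SideViewSet}}.
#' @return A list with `cv_a` and `max_min_a`.
#' @export
areaMetrics <- function(views) {
  stopifnot(is(views, "SideViewSet"))
  a <- views@areas
  list(cv_a = .pop_cv(a), max_min_a = max(a) / min(a))
}

#' Dispersion of side-view principal orientations (CV_D)
#'
#' Quantifies how much the major axis of the projected silhouette swings
#' as the fruit rotates. The per-view axial angles (mod 180 degrees,
#' eigenvector sign-free) are expressed as signed deviations from their
#' axial circular-mean direction and shifted by +90 degrees, so a perfect
#' solid of revolution scores 90 in every view; CV_D is the population
#' CV of those values and is 0 for a perfectly uniform fruit. The +90
#' offset keeps the mean far from zero, where a plain CV of wrapped
#' angles would be unstable.
#'
#' @param views a \code{\linkS4class{SideViewSet}}.
#' @return The dimensionless CV_D.
#' @export
orientationCV <- function(views) {
  stopifnot(is(views, "SideViewSet"))
  th <- views@anglesDeg * pi / 180
  mu <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2 * 180 / pi
  dev <- (views@anglesDeg - mu) %% 180
  dev[dev > 90] <- dev[dev > 90] - 180      # signed deviation in (-90, 90]
  a <- 90 + dev
  .pop_sd(a) / mean(a)
}
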