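#' Mean nearest-neighbour spacing of a point set
#'
#' Average distance from each point to its nearest neighbour; the natural
#' length scale for smoothing radii on a sampled surface.
#'
#' @param pts numeric N x 3 coordinate matrix (or a cloud object).
#' @return Mean spacing in the units of `pts`.
#' @export
meanNNSpacing <- function(pts) {
  if (is(pts, "ColouredPointCloud")) pts <- coords(pts)
  mean(.cpp_knn(pts, 1L)$distance)
}

#' Smooth a body surface by moving least squares
#'
#' Each point is projected onto a degree-2 polynomial surface fitted by
#' weighted least squares (Gaussian weights, scale radius/2) over its
#' radius neighbourhood, in the frame of the local tangent plane (normal
#' from the local covariance). The point count is unchanged; points with
#' fewer than 6 neighbours are copied unsmoothed and counted.
#'
#' @param body a standardised \code{\linkS4class{BodyCloud}}.
#' @param radiusMm support radius in mm; `NA` (default) uses
#'   `radiusFactor` times the effective point spacing. The effective
#'   spacing is twice the mean nearest-neighbour distance: for
#'   Poisson-like surface samples of density `lambda` the mean
#'   nearest-neighbour distance is `0.5 / sqrt(lambda)`, so doubling it
#'   recovers the lattice-equivalent spacing `1 / sqrt(lambda)` and the
#'   default factor 2.5 holds about 20 points.
#' @param radiusFactor multiplier for the automatic radius.
#' @param quiet suppress the mean-displacement message.
#' @return The smoothed \code{\linkS4class{BodyCloud}}; the fraction of
#'   unsmoothed points is attached as attribute `"unsmoothedFrac"`.
#' @export
mlsSmooth <- function(body, radiusMm = NA_real_, radiusFactor = 2.5,
                      quiet = FALSE) {
  stopifnot(is(body, "BodyCloud"))
  spacing <- 2 * meanNNSpacing(body@coords)
  if (is.na(radiusMm)) radiusMm <- radiusFactor * spacing
  if (radiusMm <= 0) stop("radiusMm must be positive", call. = FALSE)
  if (radiusMm < 2 * spacing) {
    warning("MLS radius ", signif(radiusMm, 3), " mm is below twice the ",
            "mean point spacing (", signif(spacing, 3),
            " mm); smoothing will be ineffective", call. = FALSE)
  }
  sm <- .cpp_mls_smooth(body@coords, radiusMm)
  frac_un <- sm$n_unsmoothed / nPoints(body)
  if (frac_un > 0.10) {
    warning(sprintf("%.1f%% of points had fewer than 6 neighbours and were %s",
                    100 * frac_un, "left unsmoothed"), call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("MLS: radius %.3g mm, mean displacement %.4g mm, %d unsmoothed",
                    radiusMm, sm$mean_displacement, sm$n_unsmoothed))
  }
  out <- body
  out@coords <- sm$points
  dimnames(out@coords) <- list(NULL, c("x", "y", "z"))
  attr(out, "unsmoothedFrac") <- frac_un
  out
}

#' Per-point principal curvatures by local quadric fitting
#'
#' For each point, a quadric height field `z = a x^2 + b xy + c y^2` is
#' fitted over the k-nearest-neighbour patch in the local tangent frame
#' (normal from the neighbourhood covariance, oriented away from the body
#' centroid). The principal curvatures k1 >= k2 are the eigenvalues of
#' the second-fundamental-form matrix `[[2a, b], [b, 2c]]`, signed so
#' that locally convex surface (bulging along the outward normal) is
#' positive: a sphere of radius R scores k1 = k2 = 1/R and a cylinder of
#' radius r scores k1 = 1/r, k2 = 0. The average curvature is
#' `(|k1| + |k2|) / 2`. Points whose fit is rank-deficient are flagged
#' and excluded from patch aggregation.
#'
#' @param body a (smoothed) \code{\linkS4class{BodyCloud}}.
#' @param kNeighbours neighbourhood size, >= 8 (default 30).
#' @return A \code{\linkS4class{CurvatureField}}.
#' @export
principalCurvatures <- function(body, kNeighbours = 30) {
  stopifnot(is(body, "BodyCloud"), kNeighbours >= 8)
  res <- .cpp_quadric_curvatures(body@coords, as.integer(kNeighbours),
                                 matrix(colMeans(body@coords), nrow = 1L))
  # height field along the outward normal makes convex curvature negative;
  # negate so that convex is positive, and restore the k1 >= k2 order
  k1 <- as.numeric(-res$k2)
  k2 <- as.numeric(-res$k1)
  kAvg <- (abs(k1) + abs(k2)) / 2
  new("CurvatureField", normals = res$normal,
      k1 = k1, k2 = k2, kAvg = kAvg,
      flagged = res$flagged, kNeighbours = as.integer(kNeighbours))
}

#' Build the equatorial curvature patches
#'
#' Seeds `nPatches` directions at equal angular spacing (22.5 degrees for
#' 16 patches) around the centroid of the largest slice; each seed is the
#' slice point nearest that direction, and its patch is the `patchK`
#' nearest body points. The patch curvature is the mean of the upper half
#' of the members' average curvatures (midpoint included on the upper
#' side for odd counts), which emphasises local creases and bumps.
#'
#' @param body the (smoothed) \code{\linkS4class{BodyCloud}} whose points
#'   carry the curvature field.
#' @param field the \code{\linkS4class{CurvatureField}} of `body`.
#' @param stack the \code{\linkS4class{SliceStack}} locating the largest
#'   slice.
#' @param nPatches number of patches (default 16).
#' @param patchK points per patch.
#' @return A \code{\linkS4class{PatchSet}}.
#' @export
buildPatches <- function(body, field, stack, nPatches = 16, patchK = 200) {
  stopifnot(is(body, "BodyCloud"), is(field, "CurvatureField"),
            is(stack, "SliceStack"))
  sl <- largestSlice(stack)
  if (nrow(sl$points) < 1L) stop("largest slice has no points", call. = FALSE)
  ctr <- sl$centroid[1:2]
  pt_ang <- atan2(sl$points[, 2L] - ctr[2L], sl$points[, 1L] - ctr[1L])
  seed_ang <- (seq_len(nPatches) - 1L) * 2 * pi / nPatches
  P <- body@coords
  seeds <- matrix(NA_real_, nPatches, 3L)
  members <- vector("list", nPatches)
  pcurv <- numeric(nPatches)
  usable <- !field@flagged
  for (j in seq_len(nPatches)) {
    dang <- (pt_ang - seed_ang[j] + pi) %% (2 * pi) - pi
    s <- which.min(abs(dang))
    seed <- c(sl$points[s, ], sl$zLevel)
    seeds[j, ] <- seed
    d2 <- (P[, 1L] - seed[1L]) ^ 2 + (P[, 2L] - seed[2L]) ^ 2 +
      (P[, 3L] - seed[3L]) ^ 2
    mem <- order(d2)[seq_len(min(patchK, nrow(P)))]
    mem <- mem[usable[mem]]
    if (length(mem) == 0L) {
      stop("patch ", j, " is empty (all member curvatures flagged)",
           call. = FALSE)
    }
    members[[j]] <- mem
    pcurv[j] <- .upper_half_mean(field@kAvg[mem])
  }
  new("PatchSet", seeds = seeds, seedAnglesDeg = seed_ang * 180 / pi,
      members = members, patchCurvature = pcurv)
}

# mean of the upper half of the values; the median element joins the upper
# side when the count is odd
.upper_half_mean <- function(x) {
  v <- sort(x, decreasing = TRUE)
  mean(v[seq_len(ceiling(length(v) / 2))])
}

#' Curvature uniformity metrics (CV_C and Max_C/Min_C)
#'
#' Population CV and max/min ratio of the per-patch curvatures. When the
#' smallest patch curvature is not positive (a flat or saddle patch) the
#' ratio is undefined and reported as `NA` with `maxMinMissing = TRUE`;
#' the CV is still computed.
#'
#' @param patches a \code{\linkS4class{PatchSet}}.
#' @return A list with `cv_c`, `max_min_c` and `maxMinMissing`.
#' @export
curvatureSummary <- function(patches) {
  stopifnot(is(patches, "PatchSet"))
  k <- patches@patchCurvature
  cv <- .pop_cv(k)
  if (min(k) <= 0) {
    list(cv_c = cv, max_min_c = NA_real_, maxMinMissing = TRUE)
  } else {
    list(cv_c = cv, max_min_c = max(k) / min(k), maxMinMissing = FALSE)
  }
}
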