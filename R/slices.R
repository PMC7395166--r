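#' Build the stack of horizontal cross-section slices
#'
#' Places `nSlices` evenly spaced slice planes across the body height (at
#' the centres of `nSlices` equal height cells) and collects, per plane,
#' the points within `halfwidthMm` of it. Each slice is projected to
#' (x, y) and summarised by its convex hull: area, perimeter and polygon
#' centroid (the geometric analogue of the image-moment centroid of a
#' contour, and independent of sampling density). Slices with fewer than
#' 3 non-collinear points are marked invalid.
#'
#' @param body a standardised \code{\linkS4class{BodyCloud}}.
#' @param nSlices number of slices (default 100).
#' @param halfwidthMm slab half-thickness; `NA` (default) uses
#'   body height / (2 * nSlices) so adjacent slabs tile the height.
#' @return A \code{\linkS4class{SliceStack}}.
#' @export
buildSlices <- function(body, nSlices = 100, halfwidthMm = NA_real_) {
  stopifnot(is(body, "BodyCloud"), nSlices >= 2)
  z <- body@coords[, 3L]
  zmin <- min(z)
  H <- diff(range(z))
  if (!(H > 0)) stop("body has zero height; cannot slice", call. = FALSE)
  if (is.na(halfwidthMm)) halfwidthMm <- H / (2 * nSlices)
  zl <- zmin + (seq_len(nSlices) - 0.5) * H / nSlices
  pts <- vector("list", nSlices)
  areas <- perims <- rep(NA_real_, nSlices)
  cents <- matrix(NA_real_, nSlices, 3L)
  valid <- logical(nSlices)
  for (i in seq_len(nSlices)) {
    sel <- abs(z - zl[i]) <= halfwidthMm
    xy <- body@coords[sel, c(1L, 2L), drop = FALSE]
    pts[[i]] <- xy
    h <- hullMetrics2D(xy)
    if (h$valid) {
      areas[i] <- h$area
      perims[i] <- h$perimeter
      cents[i, ] <- c(h$centroid, zl[i])
      valid[i] <- TRUE
    }
  }
  if (!any(valid)) stop("all slices are degenerate", call. = FALSE)
  largest <- which(valid)[which.max(areas[valid])]  # ties: lower index
  new("SliceStack", zLevels = zl, halfwidthMm = halfwidthMm,
      points = pts, areas = areas, perimeters = perims,
      centroids = cents, valid = valid, largestIndex = as.integer(largest))
}

#' Extract the slice with the largest contour
#'
#' Returns the valid slice whose convex hull has maximal area (the
#' maximum circumference of the fruit); ties go to the lower index, i.e.
#' the slice nearer the holder.
#'
#' @param stack a \code{\linkS4class{SliceStack}}.
#' @return A list with `index`, `zLevel`, `points` (M x 2), `area`,
#'   `perimeter` and `centroid` (length-3).
#' @export
largestSlice <- function(stack) {
  stopifnot(is(stack, "SliceStack"))
  i <- stack@largestIndex
  list(index = i, zLevel = stack@zLevels[i], points = stack@points[[i]],
       area = stack@areas[i], perimeter = stack@perimeters[i],
       centroid = stack@centroids[i, ])
}

#' Bounding-box aspect ratio of a slice (L/W)
#'
#' Fits the minimum bounding box aligned with the slice's principal
#' orientation (the two eigenvectors of the 2D point covariance) and
#' returns the length-to-width ratio, >= 1. A perfectly uniform fruit has
#' a circular largest slice and L/W = 1.
#'
#' @param slice a slice as returned by [largestSlice()].
#' @return The aspect ratio `l_w`.
#' @export
bboxAspect <- function(slice) {
  xy <- slice$points
  stopifnot(is.matrix(xy), nrow(xy) >= 3L)
  ctr <- colMeans(xy)
  C <- sweep(xy, 2L, ctr)
  V <- eigen(crossprod(C) / nrow(C), symmetric = TRUE)$vectors
  ext <- apply(C %*% V, 2L, function(p) diff(range(p)))
  if (min(ext) <= 1e-12 * max(ext)) {
    stop("slice is collinear; bounding box has zero width", call. = FALSE)
  }
  max(ext) / min(ext)
}

#' Circularity of a slice contour (CIR)
#'
#' The isoperimetric quotient `4 * pi * A / p^2` of the slice's convex
#' hull, where `A` is the hull area and `p` its perimeter: 1 for a circle
#' and < 1 for any other shape. Reported for the largest slice.
#'
#' @param slice a slice as returned by [largestSlice()].
#' @return The circularity in (0, 1].
#' @export
circularity <- function(slice) {
  stopifnot(is.finite(slice$area), is.finite(slice$perimeter),
            slice$perimeter > 0)
  4 * pi * slice$area / slice$perimeter ^ 2
}

#' Straightness of the centre axis (STR)
#'
#' Connects the centroids of the slices inside the middle band of the
#' body height (middle 80% by default: 80 of 100 slices) and returns the
#' ratio of the polyline length through consecutive centroids to the
#' straight-line distance between the first and last centroid. Collinear
#' centroids give 1; a bent berry axis gives > 1. Distances are 3D;
#' invalid slices inside the window are skipped, with the polyline
#' bridging across them.
#'
#' @param stack a \code{\linkS4class{SliceStack}}.
#' @param lowerFrac,upperFrac height fractions bounding the window.
#' @return The straightness `str` (>= 1 up to numerical error).
#' @export
straightness <- function(stack, lowerFrac = 0.10, upperFrac = 0.90) {
  stopifnot(is(stack, "SliceStack"), lowerFrac < upperFrac)
  zl <- stack@zLevels
  dz <- if (length(zl) > 1L) zl[2L] - zl[1L] else 0
  zmin <- zl[1L] - dz / 2                  # cell-centred levels
  H <- length(zl) * dz
  inwin <- zl >= zmin + lowerFrac * H & zl <= zmin + upperFrac * H
  use <- which(inwin & stack@valid)
  if (length(use) < 2L) {
    stop("fewer than 2 valid slices inside the straightness window",
         call. = FALSE)
  }
  cen <- stack@centroids[use, , drop = FALSE]
  seg <- sqrt(rowSums(diff(cen) ^ 2))
  D <- sqrt(sum((cen[nrow(cen), ] - cen[1L, ]) ^ 2))
  if (D <= 1e-9) stop("end centroids coincide; straightness undefined",
                      call. = FALSE)
  sum(seg) / D
}
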