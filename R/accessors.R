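#' Accessors for berry3d data classes
#'
#' Slot access for the point-cloud and metric containers. \code{nPoints}
#' gives the number of points, \code{coords} the N x 3 coordinate matrix,
#' \code{rgbColours}/\code{hsvColours} the colour matrices,
#' \code{sourceId} the input identifier. \code{viewAreas} and
#' \code{viewAngles} extract the per-view silhouette areas and major-axis
#' angles of a \code{\linkS4class{SideViewSet}}; \code{sliceAreas} and
#' \code{sliceCentroids} the per-slice hull areas and centroids of a
#' \code{\linkS4class{SliceStack}}; \code{patchCurvatures} the 16 per-patch
#' curvature summaries of a \code{\linkS4class{PatchSet}}.
#'
#' @param x an object of the corresponding class.
#' @return The slot value (vector or matrix as documented per slot).
#' @name accessors
#' @aliases nPoints coords rgbColours hsvColours sourceId viewAreas
#'   viewAngles sliceCentroids sliceAreas patchCurvatures
#' @examples
#' cl <- newPointCloud(matrix(rnorm(30), ncol = 3),
#'                     matrix(128L, nrow = 10, ncol = 3))
#' nPoints(cl)
#' head(coords(cl))
NULL

#' @rdname accessors
#' @export
setMethod("nPoints", "ColouredPointCloud", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setMethod("coords", "ColouredPointCloud", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("rgbColours", "ColouredPointCloud", function(x) x@rgb)

#' @rdname accessors
#' @export
setMethod("hsvColours", "ColouredPointCloud", function(x) {
  if (nrow(x@hsv) == 0L) {
    stop("HSV colours not populated; call rgbToHSV() first", call. = FALSE)
  }
  x@hsv
})

#' @rdname accessors
#' @export
setMethod("sourceId", "ColouredPointCloud", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("viewAreas", "SideViewSet", function(x) x@areas)

#' @rdname accessors
#' @export
setMethod("viewAngles", "SideViewSet", function(x) x@anglesDeg)

#' @rdname accessors
#' @export
setMethod("sliceCentroids", "SliceStack", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("sliceAreas", "SliceStack", function(x) x@areas)

#' @rdname accessors
#' @export
setMethod("patchCurvatures", "PatchSet", function(x) x@patchCurvature)

setMethod("show", "ColouredPointCloud", function(object) {
  cat(class(object), "with", nrow(object@coords), "points\n")
  if (!is.na(object@sourceId)) cat("  source:", object@sourceId, "\n")
  cat("  HSV populated:", nrow(object@hsv) > 0L, "\n")
  if (object@nDropped > 0L) {
    cat("  non-finite rows dropped on load:", object@nDropped, "\n")
  }
  invisible(NULL)
})

setMethod("show", "BodyCloud", function(object) {
  cat("BodyCloud with", nrow(object@coords), "points\n")
  cat(sprintf("  body height: %.2f mm, scale factor: %.4g\n",
              object@bodyHeightMm, object@scaleFactor))
  if (object@degenerateAxis) cat("  (degenerate principal axis)\n")
  invisible(NULL)
})

setMethod("show", "SideViewSet", function(object) {
  cat("SideViewSet:", object@nViews, "views at", object@stepDeg, "deg\n")
  cat(sprintf("  area range: [%.2f, %.2f] mm^2\n",
              min(object@areas), max(object@areas)))
  invisible(NULL)
})

setMethod("show", "SliceStack", function(object) {
  cat("SliceStack:", length(object@zLevels), "slices,",
      sum(object@valid), "valid\n")
  cat(sprintf("  z range: [%.2f, %.2f] mm, largest slice at index %d\n",
              min(object@zLevels), max(object@zLevels),
              object@largestIndex))
  invisible(NULL)
})

setMethod("show", "CurvatureField", function(object) {
  ok <- !object@flagged
  cat("CurvatureField over", length(object@k1), "points (",
      sum(!ok), "flagged )\n")
  cat(sprintf("  mean average curvature: %.4f /mm\n",
              mean(object@kAvg[ok])))
  invisible(NULL)
})

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet with", length(object@patchCurvature), "patches\n")
  cat(sprintf("  patch curvature range: [%.4f, %.4f] /mm\n",
              min(object@patchCurvature), max(object@patchCurvature)))
  invisible(NULL)
})
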