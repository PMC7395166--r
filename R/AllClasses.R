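#' @useDynLib berry3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Coloured point cloud
#'
#' The universal carrier of the pipeline: \code{N} points with xyz
#' coordinates and per-point RGB colour, plus the derived HSV channels once
#' \code{\link{rgbToHSV}} has been applied. Coordinates are in the arbitrary
#' units of the reconstruction until \code{\link{standardizeScale}} converts
#' them to millimetres.
#'
#' @slot coords numeric matrix, N x 3 (x, y, z); all values finite.
#' @slot rgb integer matrix, N x 3 in [0, 255].
#' @slot hsv numeric matrix, N x 3 with hue in [0, 360) degrees and
#'   saturation/value in [0, 1]; zero rows until populated.
#' @slot extra data.frame of pass-through vertex properties (e.g. alpha,
#'   normals) preserved verbatim for re-export.
#' @slot extraTypes named character vector of PLY type names for the
#'   pass-through properties.
#' @slot sourceId character identifier (usually the file name).
#' @slot nDropped integer count of non-finite vertex rows dropped on load.
#'
#' @seealso [readPLY()], [writePLY()], [rgbToHSV()]
#' @export
setClass("ColouredPointCloud",
  representation(
    coords = "matrix",
    rgb = "matrix",
    hsv = "matrix",
    extra = "data.frame",
    extraTypes = "character",
    sourceId = "character",
    nDropped = "integer"
  ),
  prototype(
    hsv = matrix(numeric(0), ncol = 3),
    extra = data.frame(),
    extraTypes = character(0),
    sourceId = NA_character_,
    nDropped = 0L
  )
)

setValidity("ColouredPointCloud", function(object) {
  msg <- character(0)
  n <- nrow(object@coords)
  if (n < 1L) msg <- c(msg, "cloud must contain at least one point")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be N x 3")
  if (any(!is.finite(object@coords))) {
    msg <- c(msg, "coords contain non-finite values")
  }
  if (nrow(object@rgb) != n || ncol(object@rgb) != 3L) {
    msg <- c(msg, "rgb must be N x 3")
  } else if (any(object@rgb < 0 | object@rgb > 255)) {
    msg <- c(msg, "rgb values must lie in [0, 255]")
  }
  if (nrow(object@hsv) > 0L) {
    if (nrow(object@hsv) != n) msg <- c(msg, "hsv must have N rows")
    h <- object@hsv[, 1L]
    if (any(h < 0 | h >= 360)) msg <- c(msg, "hue must lie in [0, 360)")
  }
  if (nrow(object@extra) > 0L && nrow(object@extra) != n) {
    msg <- c(msg, "extra properties must have N rows")
  }
  if (length(msg)) msg else TRUE
})

#' Segmented, standardised berry body cloud
#'
#' A \code{\linkS4class{ColouredPointCloud}} that has been denoised,
#' centred at its moment, rotated so the main orientation lies along the z
#' axis, segmented from the holder and rescaled to millimetres using the
#' holder's known physical height. Input to all metric operations.
#'
#' @slot scaleFactor numeric, the units-to-mm multiplier that was applied.
#' @slot rotation 3 x 3 orthonormal rotation matrix that was applied.
#' @slot bodyHeightMm numeric, max z - min z of the body in mm.
#' @slot centroidDriftMm numeric, how far the body centroid had moved from
#'   the origin after segmentation (logged; the cloud is re-centred).
#' @slot degenerateAxis logical, TRUE when the principal-axis alignment was
#'   skipped because the covariance was near-spherical.
#'
#' @seealso [preprocessCloud()], [standardizeScale()]
#' @export
setClass("BodyCloud",
  contains = "ColouredPointCloud",
  representation(
    scaleFactor = "numeric",
    rotation = "matrix",
    bodyHeightMm = "numeric",
    centroidDriftMm = "numeric",
    degenerateAxis = "logical"
  ),
  prototype(
    scaleFactor = 1,
    rotation = diag(3),
    bodyHeightMm = NA_real_,
    centroidDriftMm = 0,
    degenerateAxis = FALSE
  )
)

setValidity("BodyCloud", function(object) {
  msg <- character(0)
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) {
    msg <- c(msg, "rotation must be 3 x 3")
  } else if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-9)")
  }
  if (!is.na(object@bodyHeightMm) && object@bodyHeightMm > 0) {
    ctr <- colMeans(object@coords)
    if (max(abs(ctr)) > 1e-6 * object@bodyHeightMm) {
      msg <- c(msg, "body centroid must sit at the origin")
    }
  }
  if (length(object@scaleFactor) != 1L || object@scaleFactor <= 0) {
    msg <- c(msg, "scaleFactor must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' Set of rotational side-view projections
#'
#' Holds the per-view convex-hull silhouette areas and principal-orientation
#' angles of the equatorial band, projected onto the x-z plane after
#' successive rotations about z.
#'
#' @slot nViews integer number of views (default 100).
#' @slot stepDeg numeric rotation increment in degrees (nViews * stepDeg
#'   must equal 360).
#' @slot areas numeric vector of per-view convex-hull areas (mm^2), all > 0.
#' @slot anglesDeg numeric vector of per-view major-axis angles in
#'   [0, 180) degrees, measured from the z axis (axial, sign-free).
#'
#' @seealso [projectSideViews()], [areaMetrics()], [orientationCV()]
#' @export
setClass("SideViewSet",
  representation(
    nViews = "integer",
    stepDeg = "numeric",
    areas = "numeric",
    anglesDeg = "numeric"
  )
)

setValidity("SideViewSet", function(object) {
  msg <- character(0)
  if (abs(object@nViews * object@stepDeg - 360) > 1e-9) {
    msg <- c(msg, "nViews * stepDeg must equal 360")
  }
  if (length(object@areas) != object@nViews) {
    msg <- c(msg, "areas must have one entry per view")
  } else if (any(object@areas <= 0)) {
    msg <- c(msg, "all view areas must be positive")
  }
  if (length(object@anglesDeg) != object@nViews) {
    msg <- c(msg, "anglesDeg must have one entry per view")
  }
  if (length(msg)) msg else TRUE
})

#' Stack of horizontal cross-section slices
#'
#' Evenly spaced horizontal slabs through the body; each slice carries its
#' member points projected to (x, y), the convex-hull area and perimeter,
#' and the hull-polygon centroid. Source of the bounding-box aspect ratio,
#' circularity and centre-axis straightness metrics.
#'
#' @slot zLevels numeric vector of slice-plane heights (mm), strictly
#'   increasing and evenly spaced across the body height.
#' @slot halfwidthMm numeric slab half-thickness used to collect points.
#' @slot points list of M x 2 matrices, the member points per slice.
#' @slot areas numeric hull areas (mm^2); NA for invalid slices.
#' @slot perimeters numeric hull perimeters (mm); NA for invalid slices.
#' @slot centroids numeric matrix, N x 3 hull-centroid coordinates (mm).
#' @slot valid logical; slices with fewer than 3 non-collinear points are
#'   invalid and excluded from the largest-slice search.
#' @slot largestIndex integer index of the valid slice with maximal hull
#'   area (ties broken toward the holder end).
#'
#' @seealso [buildSlices()], [largestSlice()], [straightness()]
#' @export
setClass("SliceStack",
  representation(
    zLevels = "numeric",
    halfwidthMm = "numeric",
    points = "list",
    areas = "numeric",
    perimeters = "numeric",
    centroids = "matrix",
    valid = "logical",
    largestIndex = "integer"
  )
)

setValidity("SliceStack", function(object) {
  msg <- character(0)
  n <- length(object@zLevels)
  if (n < 2L) msg <- c(msg, "at least two slices are required")
  dz <- diff(object@zLevels)
  if (any(dz <= 0)) msg <- c(msg, "zLevels must be strictly increasing")
  if (n > 2L && diff(range(dz)) > 1e-6 * max(abs(dz))) {
    msg <- c(msg, "zLevels must be evenly spaced")
  }
  lens <- c(length(object@points), length(object@areas),
            length(object@perimeters), nrow(object@centroids),
            length(object@valid))
  if (any(lens != n)) msg <- c(msg, "per-slice fields must align with zLevels")
  if (!any(object@valid)) msg <- c(msg, "no valid slices")
  if (length(msg)) msg else TRUE
})

#' Per-point surface curvature field
#'
#' Principal curvatures estimated per point by fitting a quadric height
#' field over the k-nearest-neighbour patch in the local tangent frame.
#'
#' @slot normals numeric N x 3 matrix of outward unit normals.
#' @slot k1 numeric maximum principal curvature per point (1/mm).
#' @slot k2 numeric minimum principal curvature per point (1/mm), k2 <= k1.
#' @slot kAvg numeric average curvature per point, (|k1| + |k2|)/2 (1/mm).
#' @slot flagged logical, TRUE where the local fit was rank-deficient;
#'   such points are excluded from patch aggregation.
#' @slot kNeighbours integer neighbourhood size used.
#'
#' @seealso [principalCurvatures()], [buildPatches()]
#' @export
setClass("CurvatureField",
  representation(
    normals = "matrix",
    k1 = "numeric",
    k2 = "numeric",
    kAvg = "numeric",
    flagged = "logical",
    kNeighbours = "integer"
  )
)

setValidity("CurvatureField", function(object) {
  msg <- character(0)
  n <- length(object@k1)
  if (length(object@k2) != n || length(object@kAvg) != n ||
      length(object@flagged) != n || nrow(object@normals) != n) {
    msg <- c(msg, "per-point fields must have equal length")
  }
  ok <- !object@flagged
  if (any(object@k1[ok] < object@k2[ok])) msg <- c(msg, "k1 must be >= k2")
  if (any(object@kAvg[ok] < 0)) msg <- c(msg, "kAvg must be non-negative")
  nrm <- sqrt(rowSums(object@normals^2))
  if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "normals must be unit length")
  if (length(msg)) msg else TRUE
})

#' Equatorial curvature patches
#'
#' Sixteen patches of surface points seeded at equal angular spacing around
#' the largest-slice contour; each patch summarises local curvature as the
#' mean of the upper half of its members' average curvatures.
#'
#' @slot seeds numeric nPatches x 3 matrix of seed-point coordinates.
#' @slot seedAnglesDeg numeric seed directions in degrees (0, 22.5, ...).
#' @slot members list of integer index vectors into the body cloud.
#' @slot patchCurvature numeric per-patch curvature summary (1/mm).
#'
#' @seealso [buildPatches()], [curvatureSummary()]
#' @export
setClass("PatchSet",
  representation(
    seeds = "matrix",
    seedAnglesDeg = "numeric",
    members = "list",
    patchCurvature = "numeric"
  )
)

setValidity("PatchSet", function(object) {
  msg <- character(0)
  np <- length(object@patchCurvature)
  if (nrow(object@seeds) != np || length(object@members) != np ||
      length(object@seedAnglesDeg) != np) {
    msg <- c(msg, "per-patch fields must align")
  }
  if (any(vapply(object@members, length, 1L) == 0L)) {
    msg <- c(msg, "patches must be non-empty")
  }
  if (length(msg)) msg else TRUE
})
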