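#' Convex-hull metrics of a planar point set
#'
#' Computes the 2D convex hull of a point set together with its area
#' (shoelace formula), perimeter and polygon (area-weighted) centroid.
#' These quantities feed every silhouette and cross-section metric in the
#' package, so they are exposed for direct use and cross-checking.
#'
#' @param xy numeric M x 2 matrix of planar points.
#' @return A list with `valid` (FALSE when the set is empty, has fewer than
#'   3 points or is collinear), `hull` (hull vertices in counter-clockwise
#'   order), `area`, `perimeter` and `centroid` (polygon centroid; for
#'   degenerate sets the point mean).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' h <- hullMetrics2D(sq)
#' 4 * pi * h$area / h$perimeter^2   # circularity of a square: pi/4
#' @export
hullMetrics2D <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) == 0L) {
    return(list(valid = FALSE, hull = xy, area = NA_real_,
                perimeter = NA_real_, centroid = c(NA_real_, NA_real_)))
  }
  mean_pt <- colMeans(xy)
  if (nrow(xy) < 3L) {
    return(list(valid = FALSE, hull = xy, area = 0,
                perimeter = NA_real_, centroid = mean_pt))
  }
  idx <- grDevices::chull(xy[, 1L], xy[, 2L])
  hull <- xy[rev(idx), , drop = FALSE]  # chull is clockwise; reverse to CCW
  m <- nrow(hull)
  if (m < 3L) {
    return(list(valid = FALSE, hull = hull, area = 0,
                perimeter = NA_real_, centroid = mean_pt))
  }
  nxt <- c(2:m, 1L)
  cross <- hull[, 1L] * hull[nxt, 2L] - hull[nxt, 1L] * hull[, 2L]
  area <- sum(cross) / 2
  if (abs(area) <= .Machine$double.eps * max(abs(hull)) ^ 2 * m) {
    return(list(valid = FALSE, hull = hull, area = 0,
                perimeter = NA_real_, centroid = mean_pt))
  }
  perimeter <- sum(sqrt(rowSums((hull[nxt, , drop = FALSE] - hull) ^ 2)))
  cx <- sum((hull[, 1L] + hull[nxt, 1L]) * cross) / (6 * area)
  cy <- sum((hull[, 2L] + hull[nxt, 2L]) * cross) / (6 * area)
  list(valid = TRUE, hull = hull, area = abs(area), perimeter = perimeter,
       centroid = c(cx, cy))
}
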