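#' Cutting path: n+1 ordered points in the access plane
#'
#' The optimization variable. A path of n+1 (x, y) points (2(n+1) scalars)
#' defines n segments whose vertical extrusion is the cutting surface.
#' Points are stored sorted by polar angle about the tumor centroid
#' projection (the origin of the canonical frame).
#'
#' @param points numeric matrix with 2 columns (mm), already ordered.
#' @return object of class `cutting_path`.
#' @export
cutting_path <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 2L) stop("a cutting path needs at least 2 points")
  structure(list(points = points), class = "cutting_path")
}

#' @export
print.cutting_path <- function(x, ...) {
  cat(sprintf("cutting_path: %d points (%d segments)\n",
              nrow(x$points), nrow(x$points) - 1L))
  invisible(x)
}

#' Order points by polar angle about a center
#'
#' Sorts by ascending polar angle about `center`; ties are broken by
#' radius (nearer first), then x, then y, giving a deterministic total
#' order. The open chain is cut at the largest circular angular gap, so
#' the widest empty sector separates the first and last point. This makes
#' the ordering equivariant under rotations of the scene (a fixed `atan2`
#' branch cut would scramble chains whose angular span crosses it) and
#' places the chain's open side where no cutting is happening. This runs
#' inside every objective evaluation, so the optimizer's raw coordinates
#' may arrive in any order.
#'
#' @param points n x 2 matrix of (x, y) (mm).
#' @param center length-2 center, default the origin (canonical tumor
#'   centroid projection).
#' @return a [cutting_path()] with the sorted points.
#' @export
order_points_polar <- function(points, center = c(0, 0)) {
  points <- matrix(as.numeric(points), ncol = 2)
  center <- as.numeric(center)
  dx <- points[, 1] - center[1]; dy <- points[, 2] - center[2]
  r2 <- dx^2 + dy^2
  if (any(r2 < 1e-24))
    stop("a path point coincides with the centroid; polar order undefined")
  ang <- atan2(dy, dx)
  ord <- order(ang, sqrt(r2), points[, 1], points[, 2])
  k <- length(ord)
  if (k > 2L) {
    a <- ang[ord]
    gaps <- c(a[-1] - a[-k], a[1] + 2 * pi - a[k])  # gap i: point i -> i+1
    cut <- which.max(gaps)
    if (cut < k) ord <- ord[c((cut + 1L):k, 1L:cut)]
  }
  cutting_path(points[ord, , drop = FALSE])
}

# Collapse consecutive (near-)duplicate points. The surface of a path with
# duplicated points has redundant coincident planes; dropping them changes
# nothing geometrically but keeps segment-based code well-defined.
collapse_duplicates <- function(points, tol = 1e-6) {
  keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > tol^2)
  points[keep, , drop = FALSE]
}

#' Transverse self-intersections of an open polygonal chain
#'
#' All crossings between non-adjacent segments, found by direct segment-pair
#' intersection. Touching contacts (an endpoint on another segment) count as
#' crossings, which is conservative toward penalization. Overlapping
#' collinear segments cannot be summarized by a point and are flagged
#' degenerate instead.
#'
#' @param path a [cutting_path()] (or 2-column matrix) of at least 3 points.
#' @return list with `points` (k x 2 matrix of crossing coordinates) and
#'   `degenerate` (TRUE when collinear overlap was found).
#' @export
find_self_intersections <- function(path) {
  pts <- if (inherits(path, "cutting_path")) path$points else
    matrix(as.numeric(path), ncol = 2)
  ns <- nrow(pts) - 1L
  out <- list(); k <- 0L; degenerate <- FALSE
  if (ns >= 3L) {
    for (i in 1:(ns - 2L)) {
      for (j in (i + 2L):ns) {
        hit <- segment_intersection(pts[i, ], pts[i + 1L, ], pts[j, ], pts[j + 1L, ])
        if (isTRUE(hit$degenerate)) degenerate <- TRUE
        else if (!is.null(hit$point)) { k <- k + 1L; out[[k]] <- hit$point }
      }
    }
  }
  pts_out <- if (k > 0) do.call(rbind, out) else matrix(numeric(0), ncol = 2)
  list(points = pts_out, degenerate = degenerate)
}

# Intersection of closed segments p1-p2 and p3-p4. Returns list(point=) for a
# transverse or touching intersection, list(degenerate=TRUE) for overlapping
# collinear segments, empty list otherwise.
segment_intersection <- function(p1, p2, p3, p4, tol = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  qp <- p3 - p1
  if (abs(denom) < tol * max(1, sum(d1^2), sum(d2^2))) {
    cross_qp <- qp[1] * d1[2] - qp[2] * d1[1]
    if (abs(cross_qp) > 1e-9 * max(1, sqrt(sum(d1^2))))
      return(list())  # parallel, not collinear
    # collinear: check 1D overlap along d1
    l2 <- sum(d1^2)
    if (l2 < tol) return(list())
    t3 <- sum((p3 - p1) * d1) / l2
    t4 <- sum((p4 - p1) * d1) / l2
    if (max(min(t3, t4), 0) <= min(max(t3, t4), 1) - 1e-12)
      return(list(degenerate = TRUE))
    return(list())
  }
  t <- (qp[1] * d2[2] - qp[2] * d2[1]) / denom
  u <- (qp[1] * d1[2] - qp[2] * d1[1]) / denom
  eps <- 1e-12
  if (t >= -eps && t <= 1 + eps && u >= -eps && u <= 1 + eps)
    return(list(point = p1 + t * d1))
  list()
}

#' Does any chain self-intersection project onto bone or tumor?
#'
#' A self-intersecting cutting surface is clinically acceptable when the
#' intersection line stays clear of the anatomy; when the vertical line
#' through a crossing point intersects the bone or the tumor mesh, the
#' split would be ill-defined and the configuration must be penalized.
#' The test uses the full vertical line (both z directions) because the
#' extruded surface spans the full z-extent.
#'
#' @param crossings k x 2 matrix of crossing points from
#'   [find_self_intersections()].
#' @param bone,tumor [triangle_mesh()] objects in the canonical frame.
#' @return `TRUE` iff any crossing's vertical line hits either mesh.
#' @export
self_intersection_hits_mesh <- function(crossings, bone, tumor) {
  if (is.null(crossings) || nrow(crossings) == 0L) return(FALSE)
  any(vertical_line_intersects(bone, crossings)) ||
    any(vertical_line_intersects(tumor, crossings))
}
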