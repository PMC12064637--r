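#' Approximated-convex-hull (ACH) warm start
#'
#' Builds a plausible initial cutting path from the tumor's silhouette so
#' the swarm starts near the global minimum:
#'
#' 1. project the tumor mesh onto the xy plane;
#' 2. take the 2D convex hull of the projection, polar-ordered about the
#'    tumor centroid;
#' 3. mark hull points whose vertical line intersects the bone as "true",
#'    the others "false";
#' 4. preserve the true run plus its two flanking false points (only these
#'    generate facets that cut bone) as an open polyline, false points
#'    first and last;
#' 5. simplify the polyline to exactly n+1 points (Ramer-Douglas-Peucker);
#' 6. offset the points radially outward until the path clears the
#'    expanded tumor completely.
#'
#' The hull is taken on the margin-expanded tumor by default, since the
#' final path must clear the margin, but the raw tumor is selectable.
#'
#' @param case a [canonicalize_case()] result.
#' @param obj_config an [objective_config()]; used to verify feasibility of
#'   the offset path.
#' @param use_expanded project the expanded (default) or raw tumor.
#' @param offset_step,offset_max radial offset grid (mm).
#' @return object of class `ach_result`: `hull_points`, `truth_mask`,
#'   `preserved_polyline`, `simplified_points`, `offset_points`, `delta`,
#'   `feasible`, `reason`, `objective` (evaluation of the offset path).
#' @export
ach_initialize <- function(case, obj_config = objective_config(case),
                           use_expanded = TRUE,
                           offset_step = 0.1, offset_max = 10) {
  tumor <- if (use_expanded) case$tumor_expanded else case$tumor_raw
  hull <- project_and_hull(tumor, center = case$tumor_centroid[1:2])
  mask <- classify_hull_points(hull, case$bone)
  out <- list(hull_points = hull, truth_mask = mask,
              preserved_polyline = NULL, simplified_points = NULL,
              offset_points = NULL, delta = NA_real_,
              feasible = FALSE, reason = NULL, objective = NULL)
  class(out) <- "ach_result"
  pres <- preserve_and_order(hull, mask)
  if (!pres$ok) { out$reason <- pres$reason; return(out) }
  out$preserved_polyline <- pres$polyline
  simp <- simplify_to_n(pres$polyline, case$n_planes)
  out$simplified_points <- simp
  off <- offset_outward(simp, case, obj_config,
                        offset_step = offset_step, offset_max = offset_max)
  out$offset_points <- off$points
  out$delta <- off$delta
  out$objective <- off$objective
  out$feasible <- off$ok
  if (!off$ok) out$reason <- "no feasible radial offset within offset_max"
  out
}

#' @export
print.ach_result <- function(x, ...) {
  cat(sprintf("ach_result: %s (%d hull points, %d true)\n",
              if (x$feasible) sprintf("feasible, delta = %.1f mm, f = %.5f",
                                      x$delta, x$objective$f)
              else paste("infeasible:", x$reason),
              nrow(x$hull_points), sum(x$truth_mask)))
  invisible(x)
}

#' @rdname ach_initialize
#' @param mesh tumor mesh to project.
#' @param center polar-ordering center (tumor centroid projection).
#' @export
project_and_hull <- function(mesh, center = c(0, 0)) {
  xy <- mesh$vertices[, 1:2, drop = FALSE]
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) stop("degenerate (collinear) tumor projection")
  order_points_polar(xy[h, , drop = FALSE], center)$points
}

#' @rdname ach_initialize
#' @param hull k x 2 hull points.
#' @param bone bone [triangle_mesh()].
#' @export
classify_hull_points <- function(hull, bone) {
  vertical_line_intersects(bone, hull)
}

#' @rdname ach_initialize
#' @param mask logical truth mask over the hull points (circular).
#' @export
preserve_and_order <- function(hull, mask) {
  k <- length(mask)
  nt <- sum(mask)
  if (nt == 0L) return(list(ok = FALSE, reason = "no true hull points"))
  if (nt > k - 2L) return(list(ok = FALSE, reason = "fewer than two false hull points"))
  # circular runs of TRUE: count transitions FALSE->TRUE
  starts <- which(mask & !mask[c(k, seq_len(k - 1L))])
  if (length(starts) > 1L)
    return(list(ok = FALSE, reason = "multiple true runs"))
  st <- starts[1]
  idx <- ((st - 1L + seq_len(nt) - 1L) %% k) + 1L     # the true run, in order
  before <- ((st - 2L) %% k) + 1L
  after <- ((idx[nt]) %% k) + 1L
  list(ok = TRUE, polyline = hull[c(before, idx, after), , drop = FALSE])
}

#' @rdname ach_initialize
#' @param polyline open polyline (m x 2) to simplify, endpoints fixed.
#' @param n number of cutting planes; output has n+1 points.
#' @export
simplify_to_n <- function(polyline, n) {
  polyline <- matrix(as.numeric(polyline), ncol = 2)
  target <- n + 1L
  m <- nrow(polyline)
  if (m < 2L) stop("polyline needs at least 2 points")
  if (m <= target) return(densify_to(polyline, target))
  # smallest epsilon (bisection, 1e-4 mm resolution) whose RDP output has
  # at most n+1 points; RDP point count is non-increasing in epsilon
  lo <- 0
  hi <- max(polyline_deviations(polyline)) + 1e-3
  if (nrow(rdp_simplify(polyline, 0)) <= target) {
    pts <- rdp_simplify(polyline, 0)
    return(densify_to(pts, target))
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (nrow(rdp_simplify(polyline, mid)) <= target) hi <- mid else lo <- mid
  }
  pts <- rdp_simplify(polyline, hi)
  densify_to(pts, target)
}

# Perpendicular deviation of every interior vertex from the chord of the
# whole polyline (upper bound for the useful RDP epsilon range).
polyline_deviations <- function(polyline) {
  a <- polyline[1, ]; b <- polyline[nrow(polyline), ]
  d <- b - a; l2 <- sum(d^2)
  if (l2 < 1e-300) return(sqrt(rowSums(sweep(polyline, 2, a)^2)))
  t <- pmin(pmax(((polyline[, 1] - a[1]) * d[1] +
                    (polyline[, 2] - a[2]) * d[2]) / l2, 0), 1)
  sqrt((polyline[, 1] - a[1] - t * d[1])^2 + (polyline[, 2] - a[2] - t * d[2])^2)
}

# Classic recursive Ramer-Douglas-Peucker with fixed endpoints.
rdp_simplify <- function(polyline, eps) {
  m <- nrow(polyline)
  if (m <= 2L) return(polyline)
  keep <- logical(m)
  keep[c(1L, m)] <- TRUE
  stack <- list(c(1L, m))
  while (length(stack) > 0L) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    a <- polyline[i, ]; b <- polyline[j, ]
    d <- b - a; l2 <- sum(d^2)
    seg <- (i + 1L):(j - 1L)
    if (l2 < 1e-300) {
      dev <- sqrt(rowSums(sweep(polyline[seg, , drop = FALSE], 2, a)^2))
    } else {
      t <- pmin(pmax(((polyline[seg, 1] - a[1]) * d[1] +
                        (polyline[seg, 2] - a[2]) * d[2]) / l2, 0), 1)
      dev <- sqrt((polyline[seg, 1] - a[1] - t * d[1])^2 +
                    (polyline[seg, 2] - a[2] - t * d[2])^2)
    }
    w <- which.max(dev)
    if (dev[w] > eps) {
      k <- seg[w]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  polyline[keep, , drop = FALSE]
}

# Pad a polyline to exactly `target` points by splitting its longest
# segments at their midpoints (RDP can undershoot the requested count).
densify_to <- function(pts, target) {
  while (nrow(pts) < target) {
    lens <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    k <- which.max(lens)
    mid <- (pts[k, ] + pts[k + 1L, ]) / 2
    pts <- rbind(pts[seq_len(k), , drop = FALSE], mid,
                 pts[(k + 1L):nrow(pts), , drop = FALSE])
  }
  dimnames(pts) <- NULL
  pts
}

#' @rdname ach_initialize
#' @param points n+1 path points to offset.
#' @export
offset_outward <- function(points, case, obj_config = objective_config(case),
                           offset_step = 0.1, offset_max = 10) {
  points <- matrix(as.numeric(points), ncol = 2)
  r <- sqrt(rowSums(points^2))
  dir <- points / pmax(r, 1e-12)
  tol <- 1e-6 * case$vol_T_tot
  for (delta in seq(offset_step, offset_max, by = offset_step)) {
    cand <- points + delta * dir
    res <- evaluate_objective(cand, case, obj_config)
    if (!res$penalized && res$vol_T_left <= tol)
      return(list(ok = TRUE, points = cand, delta = delta, objective = res))
  }
  list(ok = FALSE, points = points, delta = NA_real_, objective = NULL)
}
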