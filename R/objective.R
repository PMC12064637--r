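#' Objective configuration
#'
#' The fitness minimized by the swarm is
#' `f = vol_B_cut / vol_B_tot + K * vol_T_left / vol_T_tot`:
#' normalized resected healthy bone plus the weighted unresected tumor
#' fraction. `K` must make any residual tumor dominate achievable bone
#' savings, yet stay finite so the landscape remains navigable; invalid
#' configurations receive the flat `penalty_value`, which strictly
#' dominates every feasible value (`f <= 1 + K`).
#'
#' @param case a [canonicalize_case()] result (supplies total volumes).
#' @param K tumor-term weight (default 100).
#' @param penalty_value value assigned to invalid configurations; default
#'   `10 + K`, "arbitrarily high" with strict dominance over `1 + K` but
#'   bounded to keep swarm velocities sane.
#' @param vol_B_tot,vol_T_tot normalizing volumes (mm^3); default the
#'   case's totals (tumor = margin-expanded volume).
#' @return object of class `objective_config`.
#' @export
objective_config <- function(case = NULL, K = 100, penalty_value = 10 + K,
                             vol_B_tot = NULL, vol_T_tot = NULL) {
  if (is.null(vol_B_tot)) vol_B_tot <- case$vol_B_tot
  if (is.null(vol_T_tot)) vol_T_tot <- case$vol_T_tot
  stopifnot(K > 0, vol_B_tot > 0, vol_T_tot > 0)
  if (penalty_value <= 1 + K)
    stop("penalty_value must strictly dominate the feasible range 1 + K")
  structure(list(K = K, penalty_value = penalty_value,
                 vol_B_tot = vol_B_tot, vol_T_tot = vol_T_tot),
            class = "objective_config")
}

#' Evaluate the objective for raw swarm coordinates
#'
#' The full evaluation pipeline: reshape the `2(n+1)` scalars into points,
#' polar-order them about the tumor centroid, drop duplicate consecutive
#' points (coincident redundant planes are allowed, not penalized), build
#' and orient the extruded surface, run the validity checks, split bone and
#' expanded tumor, and assemble the fitness. No failure mode escapes as an
#' error: every invalid configuration maps to `penalized = TRUE` with a
#' reason code (`facet-miss`, `self-intersection-hit`, `null-split`,
#' `degenerate-chain`, `multi-reflex-gap`).
#'
#' @param raw numeric vector of length `2(n+1)` (xy pairs, any order), or a
#'   2-column matrix of points.
#' @param case a [canonicalize_case()] result.
#' @param config an [objective_config()].
#' @param keep_meshes keep the split meshes in the result (off in the
#'   optimizer loop).
#' @return object of class `objective_result`: `f`, `vol_B_cut`,
#'   `vol_T_left`, `penalized`, `reason`, `validity`, `path`.
#' @export
evaluate_objective <- function(raw, case, config, keep_meshes = FALSE) {
  pts <- if (is.matrix(raw)) raw else matrix(as.numeric(raw), ncol = 2, byrow = TRUE)
  if (!all(is.finite(pts))) return(penalized_result(config, "degenerate-chain"))
  pts0 <- try(order_points_polar(pts, case$tumor_centroid[1:2]), silent = TRUE)
  if (inherits(pts0, "try-error"))
    return(penalized_result(config, "degenerate-chain"))
  pts <- collapse_duplicates(pts0$points)
  if (nrow(pts) < 2L) return(penalized_result(config, "degenerate-chain"))
  surface <- case_surface(case, pts)
  if (surface$multi_reflex)
    return(penalized_result(config, "multi-reflex-gap", path = pts))
  si <- find_self_intersections(pts)
  if (si$degenerate)
    return(penalized_result(config, "degenerate-chain", path = pts))
  if (nrow(si$points) > 0L &&
      self_intersection_hits_mesh(si$points, case$bone, case$tumor_expanded))
    return(penalized_result(config, "self-intersection-hit", path = pts))
  fc <- check_all_facets_cut(case$bone, surface)
  if (!fc$all_cut)
    return(penalized_result(config, "facet-miss", path = pts))
  rv <- resected_volumes(case, pts)
  if (!rv$ok) return(penalized_result(config, rv$reason, path = pts))
  f <- rv$vol_B_cut / config$vol_B_tot + config$K * rv$vol_T_left / config$vol_T_tot
  validity <- structure(list(
    all_facets_cut = TRUE, facet_miss_indices = integer(0),
    self_intersections = si$points, self_intersection_hits_mesh = FALSE,
    degenerate_chain = FALSE, multi_reflex = FALSE, is_valid = TRUE),
    class = "validity_report")
  structure(list(f = f,
                 vol_B_cut = rv$vol_B_cut,
                 vol_T_left = rv$vol_T_left,
                 penalized = FALSE,
                 reason = NULL,
                 validity = validity,
                 path = cutting_path(pts),
                 meshes = if (keep_meshes) rv[c("bone_resected", "bone_remainder",
                                                "tumor_resected", "tumor_remainder")]
                          else NULL),
            class = "objective_result")
}

penalized_result <- function(config, reason, path = NULL) {
  structure(list(f = config$penalty_value,
                 vol_B_cut = NA_real_,
                 vol_T_left = NA_real_,
                 penalized = TRUE,
                 reason = reason,
                 validity = NULL,
                 path = if (!is.null(path)) cutting_path(path) else NULL,
                 meshes = NULL),
            class = "objective_result")
}

#' @export
print.objective_result <- function(x, ...) {
  if (x$penalized)
    cat(sprintf("objective_result: PENALIZED (%s), f = %g\n", x$reason, x$f))
  else
    cat(sprintf("objective_result: f = %.6f (vol_B_cut = %.1f mm^3, vol_T_left = %.3f mm^3)\n",
                x$f, x$vol_B_cut, x$vol_T_left))
  invisible(x)
}
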