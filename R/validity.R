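#' Check that every facet actually cuts the bone
#'
#' During swarm exploration a configuration can place a facet so that its
#' infinite plane still crosses the bone while the facet itself lies beside
#' it; such a "plane count" violation must be penalized. For each facet the
#' bone is sectioned with the facet's infinite (vertical) plane and the
#' section contour is projected onto the facet's own segment axis; the
#' facet misses when the contour's coordinate range is disjoint from the
#' facet endpoints' range (or when there is no contour at all). Using the
#' segment's own axis generalizes the global-x comparison of the original
#' procedure to facets of arbitrary orientation.
#'
#' @param bone a [triangle_mesh()] in the canonical frame.
#' @param surface a `cutting_surface` (orientation not required).
#' @return list with `all_cut` (logical) and `miss_indices`.
#' @export
check_all_facets_cut <- function(bone, surface) {
  pts <- surface$points
  nf <- n_facets(surface)
  v <- bone$vertices
  f <- bone$faces
  miss <- integer(0)
  for (i in seq_len(nf)) {
    A <- pts[i, ]; B <- pts[i + 1L, ]
    dseg <- B - A
    L <- sqrt(sum(dseg^2))
    if (L < 1e-12) { next }  # degenerate facet cuts nothing extra
    dhat <- dseg / L
    nrm <- c(dhat[2], -dhat[1])  # plane normal (sign irrelevant here)
    g <- (v[, 1] - A[1]) * nrm[1] + (v[, 2] - A[2]) * nrm[2]
    g1 <- g[f[, 1]]; g2 <- g[f[, 2]]; g3 <- g[f[, 3]]
    crossed <- !((g1 > 0 & g2 > 0 & g3 > 0) | (g1 < 0 & g2 < 0 & g3 < 0))
    if (!any(crossed)) { miss <- c(miss, i); next }
    # u-range of the bone-plane section, from the crossing edges' endpoints
    # interpolated to the plane, measured along the segment axis
    fc <- f[crossed, , drop = FALSE]
    urange <- c(Inf, -Inf)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      ia <- fc[, e[1]]; ib <- fc[, e[2]]
      ga <- g[ia]; gb <- g[ib]
      sel <- (ga > 0 & gb < 0) | (ga < 0 & gb > 0) | ga == 0
      if (!any(sel)) next
      t <- ifelse(ga[sel] == 0, 0, ga[sel] / (ga[sel] - gb[sel]))
      px <- v[ia[sel], 1] + t * (v[ib[sel], 1] - v[ia[sel], 1])
      py <- v[ia[sel], 2] + t * (v[ib[sel], 2] - v[ia[sel], 2])
      u <- (px - A[1]) * dhat[1] + (py - A[2]) * dhat[2]
      urange[1] <- min(urange[1], min(u))
      urange[2] <- max(urange[2], max(u))
    }
    if (!is.finite(urange[1]) || urange[2] < 0 || urange[1] > L)
      miss <- c(miss, i)
  }
  list(all_cut = length(miss) == 0L, miss_indices = miss)
}

#' Full validity report for a cutting path
#'
#' Combines the two invalid-configuration classes the optimizer must
#' penalize: a facet whose plane crosses the bone without the facet itself
#' cutting it, and a chain self-intersection whose vertical line crosses
#' the bone or tumor. `is_valid` is their conjunction; degenerate
#' (collinear-overlap) chains are invalid outright.
#'
#' @param case a [canonicalize_case()] result.
#' @param path a polar-ordered [cutting_path()] / point matrix.
#' @param surface optional prebuilt oriented surface for `path`.
#' @return object of class `validity_report`.
#' @export
validity_report <- function(case, path, surface = NULL) {
  pts <- if (inherits(path, "cutting_path")) path$points else
    matrix(as.numeric(path), ncol = 2)
  if (is.null(surface)) surface <- case_surface(case, pts)
  si <- find_self_intersections(pts)
  hits <- self_intersection_hits_mesh(si$points, case$bone, case$tumor_expanded)
  fc <- check_all_facets_cut(case$bone, surface)
  structure(list(
    all_facets_cut = fc$all_cut,
    facet_miss_indices = fc$miss_indices,
    self_intersections = si$points,
    self_intersection_hits_mesh = hits,
    degenerate_chain = si$degenerate,
    multi_reflex = surface$multi_reflex,
    is_valid = fc$all_cut && !hits && !si$degenerate && !surface$multi_reflex
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(paste0("validity_report: %s\n",
                     "  all facets cut bone: %s%s\n",
                     "  self-intersections: %d (hits mesh: %s)\n"),
              if (x$is_valid) "valid" else "INVALID",
              x$all_facets_cut,
              if (length(x$facet_miss_indices)) paste0(" (miss: ",
                paste(x$facet_miss_indices, collapse = ","), ")") else "",
              nrow(x$self_intersections), x$self_intersection_hits_mesh))
  invisible(x)
}
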