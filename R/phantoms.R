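#' Synthetic bone/tumor phantom specification
#'
#' Phantoms emulate epiphyseal long-bone tumors whose xy-footprint partly
#' protrudes beyond the bone footprint (which guarantees at least two
#' "false" hull points, so the convex-hull warm start applies). Three kinds:
#'
#' * `corner_column`: cubic bone slab 40 x 40 x 40 mm at `[0, 40]^3` with a
#'   box tumor `[-5, 10] x [-5, 10] x [0, 40]` overlapping one edge column.
#'   The optimal 2-plane cut removes the 10 x 10 x 40 corner column, so the
#'   analytic optimum is `f = 4000 / 64000 = 0.0625` at margin 0, n = 2.
#' * `eccentric_ellipsoid`: capsule bone (hemispherically capped cylinder,
#'   r = 15 mm) with an ellipsoid tumor centered 12 mm off-axis, protruding
#'   laterally.
#' * `concave_bean`: same capsule bone with a tumor formed by the union of
#'   two offset ellipsoids (radial-max construction), giving a genuinely
#'   concave footprint.
#'
#' @param kind phantom kind.
#' @param resolution target mesh edge length in mm (default 1); volume
#'   accuracy of the boxes is exact, curved shapes are within ~1-2%.
#' @param seed reserved for randomized variants (stored, not used by the
#'   deterministic kinds).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("corner_column", "eccentric_ellipsoid",
                                  "concave_bean"),
                         resolution = 1, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, resolution = resolution, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic bone/tumor phantom
#'
#' @param spec a [phantom_spec()] (or a kind string).
#' @param resolution overrides the spec's mesh resolution (mm).
#' @return list with watertight `bone` and `tumor` meshes (shared frame,
#'   mm), the surgical `access` direction, suggested `n_planes` and
#'   `margin_mm`, and, for `corner_column`, `analytic_f` plus the
#'   `optimal_path` (in the canonical frame) that attains it.
#' @export
make_phantom <- function(spec = phantom_spec(), resolution = NULL) {
  if (is.character(spec)) spec <- phantom_spec(spec)
  res <- if (!is.null(resolution)) resolution else spec$resolution
  out <- switch(spec$kind,
    corner_column = {
      bone <- mesh_box(c(0, 0, 0), c(40, 40, 40), resolution = res)
      tumor <- mesh_box(c(-5, -5, 0), c(10, 10, 40), resolution = res)
      # canonical frame: tumor centroid (2.5, 2.5, 20) goes to the origin
      list(bone = bone, tumor = tumor, access = c(0, 0, 1),
           n_planes = 2L, margin_mm = 0,
           analytic_f = 4000 / 64000,
           optimal_path = rbind(c(7.5, -15), c(7.5, 7.5), c(-15, 7.5)))
    },
    eccentric_ellipsoid = {
      sub <- max(2L, min(5L, ceiling(log2(15 / res)) + 1L))
      bone <- capsule_mesh(radius = 15, half_length = 25, resolution = res)
      tumor <- mesh_icosphere(radius = c(12, 9, 15), center = c(12, 0, 10),
                              subdivisions = sub - 1L)
      list(bone = bone, tumor = tumor, access = c(0, 0, 1),
           n_planes = 3L, margin_mm = 2,
           analytic_f = NULL, optimal_path = NULL)
    },
    concave_bean = {
      sub <- max(2L, min(5L, ceiling(log2(15 / res)) + 1L))
      bone <- capsule_mesh(radius = 15, half_length = 25, resolution = res)
      tumor <- bean_mesh(center = c(10, 0, 8), subdivisions = sub)
      list(bone = bone, tumor = tumor, access = c(0, 0, 1),
           n_planes = 4L, margin_mm = 2,
           analytic_f = NULL, optimal_path = NULL)
    })
  # tumor must overlap the bone (it is an independent mesh, not a cavity)
  ct <- mesh_centroid(out$tumor)
  if (!any(vertical_line_intersects(out$bone, matrix(ct[1:2], 1))))
    stop("phantom tumor does not overlap the bone footprint")
  out$spec <- spec
  out
}

# Hemispherically capped cylinder along z, centered at the origin.
capsule_mesh <- function(radius, half_length, resolution = 1) {
  n_arc <- max(6L, ceiling(pi * radius / 2 / resolution))
  n_side <- max(2L, ceiling(2 * half_length / resolution))
  th_top <- seq(0, pi / 2, length.out = n_arc + 1L)
  top <- cbind(radius * sin(th_top), half_length + radius * cos(th_top))
  zs <- seq(half_length, -half_length, length.out = n_side + 1L)[-1]
  side <- cbind(rep(radius, length(zs)), zs)
  th_bot <- seq(pi / 2, pi, length.out = n_arc + 1L)[-1]
  bot <- cbind(radius * sin(th_bot), -half_length + radius * cos(th_bot))
  profile <- rbind(c(0, half_length + radius), top[-1, , drop = FALSE],
                   side, bot[-1, , drop = FALSE])
  profile[nrow(profile), 1] <- 0
  n_phi <- max(8L, ceiling(2 * pi * radius / resolution))
  mesh_revolve(profile, n_phi = n_phi)
}

# Union of two overlapping ellipsoids built as a star-shaped radial-max
# surface about a common interior center (both ellipsoids contain it).
bean_mesh <- function(center = c(0, 0, 0), subdivisions = 4) {
  lobes <- list(
    list(c = c(6, 0, 0), ax = c(10, 8, 12)),
    list(c = c(-5, 5, 0), ax = c(9, 9, 11)))
  unit <- mesh_icosphere(1, c(0, 0, 0), subdivisions)
  dirs <- unit$vertices
  r <- rep(0, nrow(dirs))
  for (lb in lobes) {
    # ray-ellipsoid intersection from the shared center along each direction
    o <- -lb$c / lb$ax
    d <- sweep(dirs, 2, lb$ax, "/")
    aa <- rowSums(d^2)
    bb <- 2 * as.numeric(d %*% o)
    cc <- sum(o^2) - 1
    disc <- bb^2 - 4 * aa * cc
    hit <- disc >= 0
    t <- rep(0, nrow(dirs))
    t[hit] <- (-bb[hit] + sqrt(disc[hit])) / (2 * aa[hit])
    r <- pmax(r, t)
  }
  if (any(r <= 0)) stop("bean construction failed: center outside a lobe")
  v <- dirs * r
  normalize_orientation(triangle_mesh(sweep(v, 2, center, "+"), unit$faces))
}
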