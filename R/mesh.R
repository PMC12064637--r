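#' Triangle surface mesh
#'
#' The common currency for bone, tumor, and resected parts: a tessellated
#' surface given by a vertex table and a face table. Coordinates are in
#' millimetres and stored as double precision. Meshes whose volume is taken
#' must be watertight (every edge shared by exactly two faces) and are
#' orientation-normalized so that the signed enclosed volume is positive.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices,
#'   consistently wound.
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- mesh_box(c(0, 0, 0), c(1, 1, 1))
#' mesh_volume(m)
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Watertightness report
#'
#' An edge is open when it is not shared by exactly two faces (counting the
#' two directions separately: a consistently wound closed surface has every
#' directed edge exactly once).
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `watertight` (logical), `n_open_edges`, and
#'   `consistent_winding`.
#' @export
watertight_report <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L)
    return(list(watertight = FALSE, n_open_edges = 0L, consistent_winding = FALSE))
  nv <- nrow(mesh$vertices)
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  und <- pmin(ea, eb) + as.numeric(nv + 1) * pmax(ea, eb)
  cnt <- table(und)
  open_edges <- sum(cnt != 2L)
  dir_key <- ea + as.numeric(nv + 1) * eb
  consistent <- (open_edges == 0L) && !anyDuplicated(dir_key)
  list(watertight = open_edges == 0L,
       n_open_edges = as.integer(open_edges),
       consistent_winding = isTRUE(consistent))
}

stopifnot_watertight <- function(mesh, what = "mesh") {
  rep <- watertight_report(mesh)
  if (!rep$watertight)
    stop(sprintf("%s is not watertight: %d open edge(s)", what, rep$n_open_edges))
  invisible(mesh)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) volume. The mesh must be
#' watertight; orientation is normalized implicitly by taking the absolute
#' value only in [normalize_orientation()], not here, so a negative result
#' reveals inward winding.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param signed if `TRUE` return the raw signed volume.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  stopifnot_watertight(mesh)
  v <- signed_volume(mesh)
  if (signed) v else abs(v)
}

signed_volume <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(cx * c[, 1] + cy * c[, 2] + cz * c[, 3]) / 6
}

#' Volume centroid of a watertight mesh
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return 3-vector, the centroid of the enclosed solid (mm).
#' @export
mesh_centroid <- function(mesh) {
  stopifnot_watertight(mesh)
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  tv <- (cx * c[, 1] + cy * c[, 2] + cz * c[, 3]) / 6
  V <- sum(tv)
  if (abs(V) < 1e-12) stop("mesh has (near) zero volume; centroid undefined")
  # tetrahedron (0, a, b, c) centroid is (a+b+c)/4
  ctr <- colSums((a + b + c) / 4 * tv) / V
  as.numeric(ctr)
}

#' Normalize face winding so the enclosed volume is positive
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return the mesh, with all faces flipped if the signed volume was negative.
#' @export
normalize_orientation <- function(mesh) {
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_rigid(transform, mesh$vertices)
  mesh
}

#' Axis-aligned bounding box
#'
#' @param mesh a [triangle_mesh()].
#' @return 2 x 3 matrix: row 1 = mins, row 2 = maxs.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

# Intersections of vertical lines through (x, y) query points with the mesh.
# Returns, for each query, the z values where the vertical line crosses a
# triangle (interior or edge; shared-edge duplicates are tolerated by the
# callers, which only need hit/no-hit or parity-paired spans).
vertical_line_hits <- function(mesh, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  out <- vector("list", nrow(xy))
  # 2D barycentric containment per query point, vectorized over triangles
  d1x <- b[, 1] - a[, 1]; d1y <- b[, 2] - a[, 2]
  d2x <- c[, 1] - a[, 1]; d2y <- c[, 2] - a[, 2]
  det <- d1x * d2y - d1y * d2x
  ok <- abs(det) > 1e-14
  for (i in seq_len(nrow(xy))) {
    px <- xy[i, 1] - a[, 1]; py <- xy[i, 2] - a[, 2]
    u <- (px * d2y - py * d2x) / det
    v <- (d1x * py - d1y * px) / det
    hit <- ok & u >= -1e-12 & v >= -1e-12 & (u + v) <= 1 + 1e-12
    if (!any(hit)) { out[[i]] <- numeric(0); next }
    zu <- a[hit, 3] + u[hit] * (b[hit, 3] - a[hit, 3]) + v[hit] * (c[hit, 3] - a[hit, 3])
    out[[i]] <- zu
  }
  out
}

# TRUE for each (x, y) query whose vertical line intersects the mesh, i.e.
# the point lies inside the mesh's xy-silhouette.
vertical_line_intersects <- function(mesh, xy) {
  lengths(vertical_line_hits(mesh, xy)) > 0L
}

# Minimum Euclidean distance from each 3D query point to the mesh surface.
# Used by tests (offset distance contract) and the tumor-expansion sanity
# check; plain point-triangle distance, vectorized over triangles.
point_mesh_distance <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  ab <- b - a; ac <- c - a
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    ap <- sweep(-a, 2, p, "+")
    d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
    aa <- rowSums(ab * ab); bb <- rowSums(ac * ac); abdot <- rowSums(ab * ac)
    det <- pmax(aa * bb - abdot^2, 1e-300)
    u <- (bb * d1 - abdot * d2) / det
    v <- (aa * d2 - abdot * d1) / det
    # clamp barycentric coordinates to the triangle (project to edges)
    w <- 1 - u - v
    inside <- u >= 0 & v >= 0 & w >= 0
    # closest point for inside cases
    cpx <- a + u * ab + v * ac
    # edge projections for outside cases: edges ab, ac, bc
    t1 <- pmin(pmax(d1 / pmax(aa, 1e-300), 0), 1)
    e1 <- a + t1 * ab
    t2 <- pmin(pmax(d2 / pmax(bb, 1e-300), 0), 1)
    e2 <- a + t2 * ac
    bc <- c - b
    bp <- sweep(-b, 2, p, "+")
    t3 <- pmin(pmax(rowSums(bc * bp) / pmax(rowSums(bc * bc), 1e-300), 0), 1)
    e3 <- b + t3 * bc
    d_in <- rowSums(sweep(cpx, 2, p, "-")^2)
    d_e <- pmin(rowSums(sweep(e1, 2, p, "-")^2),
                rowSums(sweep(e2, 2, p, "-")^2),
                rowSums(sweep(e3, 2, p, "-")^2))
    d2all <- ifelse(inside, pmin(d_in, d_e), d_e)
    out[i] <- sqrt(min(d2all))
  }
  out
}

# Drop vertices not referenced by any face and reindex.
compact_mesh <- function(vertices, faces) {
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(vertices[used, , drop = FALSE],
                matrix(remap[as.integer(faces)], ncol = 3))
}

# Area-weighted vertex normals (unnormalized face normals summed per vertex).
vertex_normals <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  e1 <- b - a; e2 <- c - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # length = 2 * area
  nv <- nrow(mesh$vertices)
  vn <- matrix(0, nv, 3)
  idx <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  for (j in 1:3) {
    acc <- rowsum(rep(fn[, j], 3), idx)
    vn[as.integer(rownames(acc)), j] <- acc
  }
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-300] <- 1
  vn / len
}
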