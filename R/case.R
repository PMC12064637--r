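#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with det = +1.
#' @param translation 3-vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix or 3-vector.
#' @export
apply_rigid <- function(transform, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (is.null(dim(points))) as.numeric(out) else out
}

#' @rdname rigid_transform
#' @export
invert_rigid <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*% transform$translation))
}

# Minimal rotation taking unit vector `from` onto unit vector `to`
# (Rodrigues about from x to). The azimuth about `to` is untouched, which
# makes the canonical frame deterministic.
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  c_ <- sum(from * to)
  axis <- c(from[2] * to[3] - from[3] * to[2],
            from[3] * to[1] - from[1] * to[3],
            from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about x (or y if `from` is x itself)
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * from) * from
    ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + s * K + (1 - c_) * K %*% K
}

#' Canonicalize a surgical case
#'
#' Roto-translates tumor and bone with one rigid transform so that the tumor
#' volume centroid sits at the origin and the surgical access direction maps
#' to +z (the surgeon's viewpoint). The tumor is then expanded by the safety
#' margin; all later planning runs in this canonical frame.
#'
#' @param bone,tumor watertight [triangle_mesh()] objects in a shared frame (mm).
#' @param access unit 3-vector, the surgical access direction.
#' @param n_planes positive integer, number of cutting planes n.
#' @param margin_mm non-negative safety margin (mm).
#' @param offset_config passed to [expand_tumor()].
#' @return object of class `surgical_case`: canonical `bone`, `tumor_raw`,
#'   `tumor_expanded`, `access_direction`, `n_planes`, `margin_mm`,
#'   `tumor_centroid` (origin), cached total volumes, the `transform` applied,
#'   and the bone bounding box.
#' @export
canonicalize_case <- function(bone, tumor, access = c(0, 0, 1), n_planes,
                              margin_mm = 0, offset_config = list()) {
  nrm <- sqrt(sum(as.numeric(access)^2))
  if (!is.finite(nrm) || nrm < 1e-9) stop("access direction must be a nonzero vector")
  access <- as.numeric(access) / nrm
  n_planes <- as.integer(n_planes)
  if (is.na(n_planes) || n_planes < 1L) stop("n_planes must be a positive integer")
  if (margin_mm < 0) stop("margin_mm must be non-negative")
  stopifnot_watertight(bone, "bone")
  stopifnot_watertight(tumor, "tumor")
  bone <- normalize_orientation(bone)
  tumor <- normalize_orientation(tumor)
  if (mesh_volume(tumor) <= 0) stop("tumor volume must be positive")

  R <- rotation_between(access, c(0, 0, 1))
  ct <- mesh_centroid(tumor)
  tf <- rigid_transform(R, -as.numeric(R %*% ct))
  bone <- transform_mesh(bone, tf)
  tumor <- transform_mesh(tumor, tf)
  tumor_expanded <-
    if (margin_mm > 0) do.call(expand_tumor, c(list(tumor, margin_mm), offset_config))
    else tumor
  structure(list(
    bone = bone,
    tumor_raw = tumor,
    tumor_expanded = tumor_expanded,
    access_direction = c(0, 0, 1),
    n_planes = n_planes,
    margin_mm = margin_mm,
    tumor_centroid = c(0, 0, 0),
    vol_B_tot = mesh_volume(bone),
    vol_T_tot = mesh_volume(tumor_expanded),
    vol_T_raw = mesh_volume(tumor),
    bone_bbox = mesh_bbox(bone),
    transform = tf
  ), class = "surgical_case")
}

#' @export
print.surgical_case <- function(x, ...) {
  cat(sprintf(paste0("surgical_case: n = %d planes, margin = %.2f mm\n",
                     "  bone   %8.0f mm^3 (%d faces)\n",
                     "  tumor  %8.0f mm^3 raw, %8.0f mm^3 expanded\n"),
              x$n_planes, x$margin_mm, x$vol_B_tot, nrow(x$bone$faces),
              x$vol_T_raw, x$vol_T_tot))
  invisible(x)
}

#' Expand a tumor mesh by the safety margin
#'
#' Offsets the surface outward so that every point of the input lies at
#' least `margin_mm` inside the output. Each vertex is displaced by the
#' least-squares solution of the adjacent-face constraints
#' `dot(displacement, face_normal) = margin`, which reduces to a normal
#' offset on smooth regions and to the sharp (plane-offset) corner on
#' creases; the displacement is capped at `max_scale * margin_mm`.
#'
#' @param tumor a watertight [triangle_mesh()].
#' @param margin_mm non-negative offset distance (mm).
#' @param max_scale cap on displacement magnitude relative to the margin.
#' @return the expanded, watertight [triangle_mesh()].
#' @export
expand_tumor <- function(tumor, margin_mm, max_scale = 3) {
  stopifnot_watertight(tumor, "tumor")
  tumor <- normalize_orientation(tumor)
  if (margin_mm < 0) stop("margin_mm must be non-negative")
  if (margin_mm == 0) return(tumor)
  a <- face_corner(tumor, 1); b <- face_corner(tumor, 2); c <- face_corner(tumor, 3)
  e1 <- b - a; e2 <- c - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  lens <- sqrt(rowSums(fn^2))
  keep <- lens > 1e-14
  fn[keep, ] <- fn[keep, ] / lens[keep]
  nv <- nrow(tumor$vertices)
  vert_faces <- split(rep(seq_len(nrow(tumor$faces)), 3), as.integer(tumor$faces))
  disp <- matrix(0, nv, 3)
  lam <- 1e-6
  for (v in seq_len(nv)) {
    fl <- vert_faces[[as.character(v)]]
    A <- fn[fl, , drop = FALSE]
    A <- A[lens[fl] > 1e-14, , drop = FALSE]
    if (nrow(A) == 0L) next
    M <- crossprod(A) + lam * diag(3)
    d <- solve(M, colSums(A) * margin_mm)
    dn <- sqrt(sum(d^2))
    cap <- max_scale * margin_mm
    if (dn > cap) d <- d * (cap / dn)
    disp[v, ] <- d
  }
  out <- tumor
  out$vertices <- tumor$vertices + disp
  out <- normalize_orientation(out)
  if (mesh_volume(out) <= mesh_volume(tumor))
    stop("tumor offset failed: expanded volume did not increase (self-intersection?)")
  out
}
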