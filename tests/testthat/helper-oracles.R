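# Independent oracles. These deliberately avoid the package's computational
# paths: volumes come from z-column ray casting on a grid (voxelization),
# segment intersections from a direct orientation-predicate straddle test,
# and facet-cut verdicts from rectangle sampling against the silhouette.

# Voxel-column volume: total vertical extent of the solid over a grid of
# xy columns, using parity pairing of the surface crossings of each
# column. `clip_fn`, if given, restricts columns to those where
# clip_fn(xy) is TRUE (used for the region-equivalence oracle).
voxel_volume_oracle <- function(mesh, pitch = 0.5, clip_fn = NULL) {
  bb <- mesh_bbox(mesh)
  # irrational lattice offset so columns avoid mesh vertices/edges/diagonals
  off <- pitch * (sqrt(2) - 1)
  xs <- seq(bb[1, 1] + off, bb[2, 1], by = pitch)
  ys <- seq(bb[1, 2] + off, bb[2, 2], by = pitch)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  nx <- length(xs); ny <- length(ys)
  col_of <- function(ix, iy) (iy - 1L) * nx + ix
  hits_col <- vector("list", nx * ny)
  d1x <- b[, 1] - a[, 1]; d1y <- b[, 2] - a[, 2]
  d2x <- c3[, 1] - a[, 1]; d2y <- c3[, 2] - a[, 2]
  det <- d1x * d2y - d1y * d2x
  rec <- list(); nrec <- 0L
  for (t in seq_len(nrow(f))) {
    if (abs(det[t]) < 1e-12) next
    ix <- which(xs >= min(a[t, 1], b[t, 1], c3[t, 1]) &
                  xs <= max(a[t, 1], b[t, 1], c3[t, 1]))
    iy <- which(ys >= min(a[t, 2], b[t, 2], c3[t, 2]) &
                  ys <= max(a[t, 2], b[t, 2], c3[t, 2]))
    if (length(ix) == 0L || length(iy) == 0L) next
    g <- expand.grid(ix = ix, iy = iy)
    px <- xs[g$ix] - a[t, 1]; py <- ys[g$iy] - a[t, 2]
    u <- (px * d2y[t] - py * d2x[t]) / det[t]
    w <- (d1x[t] * py - d1y[t] * px) / det[t]
    inside <- u >= 0 & w >= 0 & (u + w) <= 1
    if (!any(inside)) next
    z <- a[t, 3] + u[inside] * (b[t, 3] - a[t, 3]) + w[inside] * (c3[t, 3] - a[t, 3])
    nrec <- nrec + 1L
    rec[[nrec]] <- cbind(col_of(g$ix[inside], g$iy[inside]), z)
  }
  if (nrec == 0L) return(0)
  allrec <- do.call(rbind, rec)
  if (!is.null(clip_fn)) {
    cid <- allrec[, 1]
    ix <- ((cid - 1L) %% nx) + 1L
    iy <- ((cid - 1L) %/% nx) + 1L
    keep <- clip_fn(cbind(xs[ix], ys[iy]))
    allrec <- allrec[keep, , drop = FALSE]
    if (nrow(allrec) == 0L) return(0)
  }
  o <- order(allrec[, 1], allrec[, 2])
  cid <- allrec[o, 1]; z <- allrec[o, 2]
  total <- 0
  for (col in unique(cid)) {
    zz <- z[cid == col]
    zz <- zz[c(TRUE, diff(zz) > 1e-9)]  # drop duplicate hits on shared edges
    if (length(zz) %% 2L == 1L) next  # grazing contact; skip the column
    if (length(zz) >= 2L)
      total <- total + sum(zz[seq(2, length(zz), 2)] - zz[seq(1, length(zz), 2)])
  }
  total * pitch^2
}

# Brute-force all-pairs chain self-intersection verdict by orientation
# predicates (no intersection point computed -- independent formulation).
brute_self_intersections <- function(pts) {
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  on_seg <- function(p, q, r)  # r collinear with pq: is r within the box?
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  ns <- nrow(pts) - 1L
  count <- 0L; degenerate <- FALSE
  if (ns < 3L) return(list(count = 0L, degenerate = FALSE))
  for (i in 1:(ns - 2L)) for (j in (i + 2L):ns) {
    p1 <- pts[i, ]; p2 <- pts[i + 1L, ]; p3 <- pts[j, ]; p4 <- pts[j + 1L, ]
    o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
    o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
    if (o1 != o2 && o3 != o4) { count <- count + 1L; next }
    if (o1 == 0 && o2 == 0 && o3 == 0 && o4 == 0) {
      # collinear: overlapping or disjoint?
      if (on_seg(p1, p2, p3) || on_seg(p1, p2, p4) ||
          on_seg(p3, p4, p1) || on_seg(p3, p4, p2)) degenerate <- TRUE
      next
    }
    if ((o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
        (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2)))
      count <- count + 1L
  }
  list(count = count, degenerate = degenerate)
}

# Sampling oracle for "does this facet cut the bone": sample the facet
# rectangle and test whether any sample's vertical line pierces the bone
# close to the sample's z. A facet cuts the bone iff part of its rectangle
# is inside the bone volume.
facet_cut_sampling_oracle <- function(bone, surface, i, n_samples = 10000) {
  A <- surface$points[i, ]; B <- surface$points[i + 1L, ]
  set.seed(i * 7919L)
  t <- stats::runif(n_samples)
  zq <- stats::runif(n_samples, surface$z_range[1], surface$z_range[2])
  xy <- cbind(A[1] + t * (B[1] - A[1]), A[2] + t * (B[2] - A[2]))
  hits <- osteoplan:::vertical_line_hits(bone, xy)
  for (k in seq_len(n_samples)) {
    z <- hits[[k]]
    if (length(z) < 2L) next
    z <- sort(z)
    for (q in seq(1, length(z) - 1L, by = 2L))
      if (zq[k] >= z[q] && zq[k] <= z[q + 1L]) return(TRUE)
  }
  FALSE
}
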