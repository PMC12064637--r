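#' Build the extruded cutting surface from a path
#'
#' Extrudes the polygonal chain vertically across `z_extent`, producing one
#' rectangular planar facet (one saw cut) per chain segment. Facet normals
#' are unset until [orient_facets()] is applied.
#'
#' @param path a [cutting_path()] or 2-column point matrix.
#' @param z_extent length-2 numeric, `c(z_min, z_max)`; must strictly cover
#'   the z-extent of any mesh that will be split.
#' @return object of class `cutting_surface` with `points`, `z_range`,
#'   per-facet `normals` (NULL until oriented), `lengths`, `cum_lengths`,
#'   and a `degenerate` flag for segments shorter than 1e-6 mm.
#' @export
build_surface <- function(path, z_extent) {
  pts <- if (inherits(path, "cutting_path")) path$points else
    matrix(as.numeric(path), ncol = 2)
  z_extent <- as.numeric(z_extent)
  if (length(z_extent) != 2L || !(z_extent[1] < z_extent[2]))
    stop("z_extent must be c(z_min, z_max) with z_min < z_max")
  if (nrow(pts) < 2L) stop("need at least 2 path points")
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  lens <- sqrt(rowSums(d^2))
  structure(list(points = pts,
                 z_range = z_extent,
                 normals = NULL,
                 lengths = lens,
                 cum_lengths = c(0, cumsum(lens)),
                 degenerate = any(lens < 1e-6),
                 oriented = FALSE,
                 multi_reflex = FALSE),
            class = "cutting_surface")
}

#' @export
print.cutting_surface <- function(x, ...) {
  cat(sprintf("cutting_surface: %d facet(s), z in [%.2f, %.2f]%s\n",
              nrow(x$points) - 1L, x$z_range[1], x$z_range[2],
              if (x$oriented) ", oriented" else ""))
  invisible(x)
}

n_facets <- function(surface) nrow(surface$points) - 1L

facet_midpoints <- function(surface) {
  (surface$points[-1, , drop = FALSE] +
     surface$points[-nrow(surface$points), , drop = FALSE]) / 2
}

point_in_triangle <- function(p, a, b, c, tol = 1e-9) {
  d1 <- (p[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p[2] - b[2])
  d2 <- (p[1] - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (p[2] - c[2])
  d3 <- (p[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (p[2] - a[2])
  has_neg <- (d1 < -tol) || (d2 < -tol) || (d3 < -tol)
  has_pos <- (d1 > tol) || (d2 > tol) || (d3 > tol)
  !(has_neg && has_pos)
}

#' Orient the facet normals of a cutting surface
#'
#' Splitting keeps the component on the negative side of the oriented
#' surface, so normal direction decides which part is "resected". Three
#' configurations are distinguished by the angles that consecutive
#' point-centroid segments subtend at the tumor centroid:
#'
#' 1. every consecutive gap is below pi: all normals point away from the
#'    centroid;
#' 2. one gap exceeds pi and its pair forms an ending facet: only that
#'    facet's normal points away from the centroid;
#' 3. one gap exceeds pi at an intermediate facet: if the next path point
#'    lies inside the triangle (pair, centroid) that facet's normal faces
#'    the centroid, otherwise it points away (other facets stay away).
#'
#' More than one reflex gap cannot occur for a polar-ordered path and is
#' flagged invalid rather than guessed.
#'
#' @param surface a [build_surface()] result from a polar-ordered path.
#' @param centroid length-2 projection of the tumor centroid (origin in the
#'   canonical frame).
#' @return the surface with unit `normals` (n x 2, zero z-component implied)
#'   and `oriented = TRUE`; `multi_reflex` set when invalid.
#' @export
orient_facets <- function(surface, centroid = c(0, 0)) {
  pts <- surface$points
  centroid <- as.numeric(centroid)
  nf <- n_facets(surface)
  ang <- atan2(pts[, 2] - centroid[2], pts[, 1] - centroid[1])
  gaps <- (ang[-1] - ang[-length(ang)]) %% (2 * pi)
  reflex <- which(gaps > pi)

  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  lens <- pmax(surface$lengths, 1e-300)
  base <- cbind(d[, 2], -d[, 1]) / lens  # one of the two unit perpendiculars
  mids <- facet_midpoints(surface)
  away_dot <- rowSums(base * sweep(mids, 2, centroid, "-"))
  away <- base * ifelse(away_dot >= 0, 1, -1)  # normals pointing away from centroid

  normals <- away
  surface$multi_reflex <- length(reflex) > 1L
  if (length(reflex) == 1L) {
    k <- reflex[1]
    if (k == 1L || k == nf) {
      # ending facet subtending the reflex gap: only it points away
      normals <- -away
      normals[k, ] <- away[k, ]
    } else {
      nxt <- pts[k + 2L, ]
      if (point_in_triangle(nxt, pts[k, ], pts[k + 1L, ], centroid))
        normals[k, ] <- -away[k, ]
    }
  }
  surface$normals <- normals
  surface$centroid <- centroid
  surface$oriented <- TRUE
  surface
}

# Signed 2D distance field of the cutting chain: unsigned distance to the
# chain extended collinearly at both ends, signed by which side of that
# extended curve the query falls on (even-odd ray-crossing parity, taken
# relative to the tumor centroid's parity). Negative = centroid side =
# resected. The extension closes the open chain at infinity, so the sign
# is globally consistent and the field is continuous with zero set exactly
# on the extended curve -- a nearest-facet-normal sign (the obvious
# alternative) is discontinuous across equidistance ridges and lets the
# marching clip cut where no cutting surface exists.
chain_field <- function(surface, xy, with_param = FALSE) {
  if (!surface$oriented) stop("surface must be oriented first")
  xy <- matrix(as.numeric(xy), ncol = 2)
  nq <- nrow(xy)
  pts <- surface$points; nf <- n_facets(surface)
  BIG <- 1e6
  dir_of <- function(a, b) {
    d <- b - a; l <- sqrt(sum(d^2))
    if (l < 1e-12) c(1, 0) else d / l
  }
  ext <- rbind(pts[1, ] + dir_of(pts[2, ], pts[1, ]) * BIG,
               pts,
               pts[nf + 1L, ] + dir_of(pts[nf, ], pts[nf + 1L, ]) * BIG)
  # unsigned distance to the extended curve + crossing parity of the
  # horizontal ray from each query (half-open rule at vertices)
  best_d2 <- rep(Inf, nq)
  crossings <- integer(nq)
  if (with_param) { best_ext <- integer(nq); best_t <- numeric(nq) }
  for (i in seq_len(nrow(ext) - 1L)) {
    A <- ext[i, ]; B <- ext[i + 1L, ]
    dseg <- B - A; l2 <- max(sum(dseg^2), 1e-300)
    px <- xy[, 1] - A[1]; py <- xy[, 2] - A[2]
    t <- pmin(pmax((px * dseg[1] + py * dseg[2]) / l2, 0), 1)
    d2 <- (px - t * dseg[1])^2 + (py - t * dseg[2])^2
    if (with_param) {
      upd <- d2 < best_d2
      best_ext[upd] <- i
      best_t[upd] <- t[upd]
    }
    best_d2 <- pmin(best_d2, d2)
    straddle <- (A[2] <= xy[, 2]) != (B[2] <= xy[, 2])
    if (any(straddle)) {
      xi <- A[1] + (xy[straddle, 2] - A[2]) / (B[2] - A[2]) * (B[1] - A[1])
      hit <- straddle
      hit[straddle] <- xi > xy[straddle, 1]
      crossings <- crossings + hit
    }
  }
  ctr <- surface$centroid
  ctr_par <- 0L
  for (i in seq_len(nrow(ext) - 1L)) {
    A <- ext[i, ]; B <- ext[i + 1L, ]
    if ((A[2] <= ctr[2]) != (B[2] <= ctr[2])) {
      xi <- A[1] + (ctr[2] - A[2]) / (B[2] - A[2]) * (B[1] - A[1])
      if (xi > ctr[1]) ctr_par <- ctr_par + 1L
    }
  }
  inside <- (crossings %% 2L) == (ctr_par %% 2L)
  F <- sqrt(best_d2) * ifelse(inside, -1, 1)
  if (!with_param) return(F)
  # arc-length parameter of the nearest point on the extended curve:
  # negative before the first chain point, > total length past the last
  s <- numeric(nq)
  ne <- nrow(ext) - 1L
  sel <- best_ext == 1L
  s[sel] <- -(1 - best_t[sel]) * BIG
  sel <- best_ext == ne
  s[sel] <- surface$cum_lengths[nf + 1L] + best_t[sel] * BIG
  mid <- best_ext > 1L & best_ext < ne
  s[mid] <- surface$cum_lengths[best_ext[mid] - 1L] +
    surface$lengths[best_ext[mid] - 1L] * best_t[mid]
  list(F = F, s = s)
}

# Inverse of the arc-length parameter: (x, y) on the (extended) chain at s.
chain_point_at <- function(surface, s) {
  pts <- surface$points; cum <- surface$cum_lengths
  nf <- n_facets(surface)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nf)
  A <- pts[i, , drop = FALSE]; B <- pts[i + 1L, , drop = FALSE]
  t <- (s - cum[i]) / pmax(surface$lengths[i], 1e-300)
  A + (B - A) * t
}

#' Split a mesh with an oriented cutting surface
#'
#' Returns the capped, watertight component on the centroid (negative
#' field) side of the surface -- the resected part -- together with the
#' remainder. Mesh triangles crossing the surface are subdivided at their
#' edge crossings; both parts share the cap triangulation (built in the
#' unrolled arc-length/z plane of the extrusion), so
#' `vol(resected) + vol(remainder) = vol(mesh)` holds by construction.
#'
#' @param mesh a watertight [triangle_mesh()] whose z-extent is covered by
#'   the surface's `z_range`.
#' @param surface an [orient_facets()]-oriented `cutting_surface`.
#' @param centroid 3D point that the resected component must contain
#'   (informational; the field sign already encodes it).
#' @return list with `resected` and `remainder` ([triangle_mesh()] or NULL
#'   when empty) and `empty` (TRUE when nothing is resected).
#' @export
split_with_surface <- function(mesh, surface, centroid = c(0, 0, 0)) {
  if (!surface$oriented) stop("surface must be oriented first")
  zr <- range(mesh$vertices[, 3])
  if (zr[1] < surface$z_range[1] || zr[2] > surface$z_range[2])
    stop("surface z_range does not span the mesh z-extent")
  Fv <- chain_field(surface, mesh$vertices[, 1:2, drop = FALSE])
  eps <- 1e-9
  Fv[abs(Fv) < eps] <- -eps
  outside <- Fv > 0
  f <- mesh$faces
  o1 <- outside[f[, 1]]; o2 <- outside[f[, 2]]; o3 <- outside[f[, 3]]
  nout <- o1 + o2 + o3
  if (all(nout == 0L))
    return(list(resected = mesh, remainder = NULL, empty = FALSE))
  if (all(nout == 3L))
    return(list(resected = NULL, remainder = mesh, empty = TRUE))

  mixed <- which(nout == 1L | nout == 2L)
  keep_in <- f[nout == 0L, , drop = FALSE]
  keep_out <- f[nout == 3L, , drop = FALSE]

  # rotate each mixed face so the lone-side vertex comes first (cyclic order)
  fm <- f[mixed, , drop = FALSE]
  lone_out <- nout[mixed] == 1L  # TRUE: lone vertex is on the outside
  om <- cbind(o1[mixed], o2[mixed], o3[mixed])
  lone_pos <- integer(length(mixed))
  for (k in 1:3) lone_pos[om[, k] == lone_out] <- k
  rot <- function(pos, off) ((pos - 1L + off) %% 3L) + 1L
  av <- fm[cbind(seq_along(mixed), lone_pos)]
  bv <- fm[cbind(seq_along(mixed), rot(lone_pos, 1L))]
  cv <- fm[cbind(seq_along(mixed), rot(lone_pos, 2L))]

  # one crossing vertex per sign-changing mesh edge, shared between faces
  nv0 <- nrow(mesh$vertices)
  ekey <- function(i, j) pmin(i, j) + (nv0 + 1) * pmax(i, j)
  keys <- c(ekey(av, bv), ekey(av, cv))
  ukeys <- unique(keys)
  ei <- c(av, av); ej <- c(bv, cv)
  first <- match(ukeys, keys)
  ui <- ei[first]; uj <- ej[first]
  # the field is 1-Lipschitz in xy, so a genuine zero crossing on an edge
  # needs |F_i| + |F_j| <= its xy length; a violation means the sign flip
  # happens across a discontinuity ridge of the nearest-facet field (the
  # open chain does not actually separate these vertices) and any "cut"
  # built there would be geometric nonsense -- signal it to the caller
  exy <- mesh$vertices[ui, 1:2, drop = FALSE] - mesh$vertices[uj, 1:2, drop = FALSE]
  if (any(abs(Fv[ui]) + abs(Fv[uj]) >
           sqrt(exy[, 1]^2 + exy[, 2]^2) + 1e-6))
    return(list(resected = NULL, remainder = NULL, empty = FALSE,
                discontinuous = TRUE))
  tt <- Fv[ui] / (Fv[ui] - Fv[uj])
  cross_pts <- mesh$vertices[ui, , drop = FALSE] +
    (mesh$vertices[uj, , drop = FALSE] - mesh$vertices[ui, , drop = FALSE]) * tt
  cross_id <- nv0 + seq_along(ukeys)
  id_ab <- cross_id[match(ekey(av, bv), ukeys)]
  id_ac <- cross_id[match(ekey(av, cv), ukeys)]

  tri_b1 <- cbind(id_ab, bv, cv)             # pair-side triangle off the cut
  # directed cut edges along the inside piece's open boundary, with the
  # third ("carrier") vertex of the triangle holding that edge on each side
  cut_from <- ifelse(lone_out, id_ac, id_ab)
  cut_to <- ifelse(lone_out, id_ab, id_ac)
  w_in <- ifelse(lone_out, cv, av)
  w_out <- ifelse(lone_out, av, cv)

  verts <- rbind(mesh$vertices, cross_pts)
  caps <- build_caps(surface, verts, cut_from, cut_to)
  verts <- caps$vertices

  # carrier triangles, subdivided at any cap points inserted on the cut edge
  # (dihedral-crease crossings) so both pieces stay combinatorially closed
  in_carrier <- list(); out_carrier <- list(); nc <- 0L
  for (r in seq_along(mixed)) {
    chain <- c(cut_from[r], caps$insertions[[r]], cut_to[r])
    m <- length(chain)
    for (q in seq_len(m - 1L)) {
      nc <- nc + 1L
      in_carrier[[nc]] <- c(w_in[r], chain[q], chain[q + 1L])
      out_carrier[[nc]] <- c(w_out[r], chain[q + 1L], chain[q])
    }
  }
  in_faces <- rbind(keep_in,
                    tri_b1[lone_out, , drop = FALSE],
                    do.call(rbind, in_carrier))
  out_faces <- rbind(keep_out,
                     tri_b1[!lone_out, , drop = FALSE],
                     do.call(rbind, out_carrier))
  if (nrow(caps$faces) > 0L) {
    in_faces <- rbind(in_faces, caps$faces)
    out_faces <- rbind(out_faces, caps$faces[, c(1L, 3L, 2L), drop = FALSE])
  }
  list(resected = compact_mesh(verts, in_faces),
       remainder = compact_mesh(verts, out_faces),
       empty = FALSE)
}

# Chain the directed cut edges into closed loops and triangulate each loop
# on the unrolled (arc-length, z) plane of the extruded surface. Interior
# chain-vertex crossings are inserted so caps follow the dihedral creases;
# `insertions[[r]]` lists the ids inserted on cut edge r (from -> to order)
# so the caller can subdivide the carrier triangles to match. Returned cap
# faces are oriented for the inside (resected) piece.
build_caps <- function(surface, vertices, cut_from, cut_to) {
  nall <- nrow(vertices)
  nxt <- integer(nall)
  nxt[cut_from] <- cut_to
  row_of_from <- integer(nall)
  row_of_from[cut_from] <- seq_along(cut_from)
  insertions <- rep(list(integer(0)), length(cut_from))
  visited <- logical(nall)
  faces <- list(); nf <- 0L
  for (start in cut_from) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start
    ok <- TRUE
    repeat {
      if (visited[cur]) { ok <- length(loop) >= 3L && cur == start; break }
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      cur <- nxt[cur]
      if (cur == 0L) { ok <- FALSE; break }
    }
    if (!ok || length(loop) < 3L) next
    # unroll loop points onto (s, z)
    par <- chain_field(surface, vertices[loop, 1:2, drop = FALSE], with_param = TRUE)
    sz <- cbind(par$s, vertices[loop, 3])
    ids <- loop
    # insert crossings of interior chain vertices (dihedral creases)
    brk <- surface$cum_lengths[c(-1, -length(surface$cum_lengths))]
    if (length(brk) > 0L) {
      ids2 <- integer(0); sz2 <- NULL
      m <- length(ids)
      for (q in seq_len(m)) {
        qn <- q %% m + 1L
        ids2 <- c(ids2, ids[q])
        sz2 <- rbind(sz2, sz[q, ])
        s1 <- sz[q, 1]; s2 <- sz[qn, 1]
        cr <- brk[brk > min(s1, s2) + 1e-9 & brk < max(s1, s2) - 1e-9]
        if (length(cr) > 0L) {
          if (s1 > s2) cr <- rev(cr)
          for (sv in cr) {
            w <- (sv - s1) / (s2 - s1)
            zv <- sz[q, 2] + w * (sz[qn, 2] - sz[q, 2])
            # place on the 3D chord so the carrier subdivision tiles its
            # parent triangle exactly (keeps conservation exact); the cap
            # still conforms since it shares this vertex
            p3 <- vertices[ids[q], ] + w * (vertices[ids[qn], ] - vertices[ids[q], ])
            vertices <- rbind(vertices, p3)
            ids2 <- c(ids2, nrow(vertices))
            sz2 <- rbind(sz2, c(sv, zv))
            r <- row_of_from[ids[q]]
            if (r > 0L) insertions[[r]] <- c(insertions[[r]], nrow(vertices))
          }
        }
      }
      ids <- ids2; sz <- sz2
    }
    # cap traverses the loop opposite to the collected boundary direction
    rev_idx <- rev(seq_along(ids))
    tri <- earclip_polygon(sz[rev_idx, , drop = FALSE])
    if (is.null(tri)) {
      # fallback: fan from the loop centroid (keeps both pieces closed and
      # volume conservation exact; used only on numerically odd loops)
      ctr <- colMeans(vertices[ids, , drop = FALSE])
      par_c <- chain_field(surface, matrix(ctr[1:2], 1), with_param = TRUE)
      vertices <- rbind(vertices, ctr)
      sz <- rbind(sz, c(par_c$s, ctr[3]))
      ids <- c(ids, nrow(vertices))
      cid <- length(ids)
      m2 <- length(rev_idx)
      tri <- cbind(cid, rev_idx, rev_idx[c(2:m2, 1L)])
    } else {
      tri <- matrix(rev_idx[tri], ncol = 3)  # back to loop-local indices
    }
    # interior chords may still cross crease lines; split triangles on them
    # (exact in unrolled coordinates) so the cap follows the dihedral surface
    ref <- refine_cap_triangles(sz, tri, brk, surface, vertices, ids)
    vertices <- ref$vertices; ids <- ref$ids; tri <- ref$tri
    for (r in seq_len(nrow(tri))) {
      nf <- nf + 1L
      faces[[nf]] <- ids[tri[r, ]]
    }
  }
  fmat <- if (nf > 0L) do.call(rbind, faces) else matrix(integer(0), ncol = 3)
  list(vertices = vertices, faces = fmat, insertions = insertions)
}

# Split cap triangles along the vertical crease lines s = break of the
# unrolled plane. Splitting is exact (the split function is linear in the
# unrolled coordinates); crossing vertices are cached per edge so adjacent
# triangles stay stitched, and are mapped back to 3D on the crease line.
refine_cap_triangles <- function(sz, tri, breaks, surface, vertices, ids) {
  for (b in breaks) {
    g <- sz[, 1] - b
    g[abs(g) < 1e-9] <- 0  # on-line vertices belong to both sides
    cache <- new.env(hash = TRUE, parent = emptyenv())
    out <- list(); no <- 0L
    crossing <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- cache[[key]]
      if (!is.null(id)) return(id)
      t <- g[i] / (g[i] - g[j])
      zc <- sz[i, 2] + t * (sz[j, 2] - sz[i, 2])
      p2 <- chain_point_at(surface, b)
      vertices <<- rbind(vertices, c(p2[1], p2[2], zc))
      ids <<- c(ids, nrow(vertices))
      sz <<- rbind(sz, c(b, zc))
      g <<- c(g, 0)
      id <- length(ids)
      cache[[key]] <- id
      id
    }
    for (r in seq_len(nrow(tri))) {
      v <- tri[r, ]
      gv <- g[v]
      if (!any(gv > 0) || !any(gv < 0)) { no <- no + 1L; out[[no]] <- v; next }
      if (any(gv == 0)) {
        # one on-line vertex, the opposite edge crosses: split in two
        lp <- which(gv == 0)[1]
        z <- v[lp]; v1 <- v[lp %% 3L + 1L]; v2 <- v[(lp + 1L) %% 3L + 1L]
        x <- crossing(v1, v2)
        no <- no + 1L; out[[no]] <- c(z, v1, x)
        no <- no + 1L; out[[no]] <- c(z, x, v2)
        next
      }
      lone_side <- sum(gv > 0) == 1L
      lp <- which((gv > 0) == lone_side)[1]
      a <- v[lp]; bb <- v[lp %% 3L + 1L]; cc <- v[(lp + 1L) %% 3L + 1L]
      ab <- crossing(a, bb); ac <- crossing(a, cc)
      no <- no + 1L; out[[no]] <- c(a, ab, ac)
      no <- no + 1L; out[[no]] <- c(ab, bb, cc)
      no <- no + 1L; out[[no]] <- c(ab, cc, ac)
    }
    tri <- do.call(rbind, out)
  }
  list(sz = sz, tri = tri, vertices = vertices, ids = ids)
}

# Ear-clipping triangulation of a (preferably simple) polygon given as a
# k x 2 matrix; returns index triples consistent with the input orientation,
# or NULL when no ear can be found (self-crossing input). Vertices with
# (near-)zero triangle area at their corner -- consecutive duplicates and
# collinear runs, common when the cut grazes mesh lattice planes -- are
# retired by emitting their degenerate triangle, which keeps both split
# pieces combinatorially closed without affecting volume.
earclip_polygon <- function(poly) {
  k <- nrow(poly)
  if (k < 3L) return(NULL)
  area2 <- sum(poly[, 1] * poly[c(2:k, 1), 2] - poly[c(2:k, 1), 1] * poly[, 2])
  ccw <- area2 >= 0
  scale2 <- max(1, diff(range(poly[, 1]))^2 + diff(range(poly[, 2]))^2)
  tol_area <- 1e-12 * scale2
  corner_cross <- function(ip, iv, inx) {
    a <- poly[ip, ]; b <- poly[iv, ]; c <- poly[inx, ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (ccw) cr else -cr
  }
  idx <- seq_len(k)
  tris <- matrix(0L, k - 2L, 3L)
  nt <- 0L
  # retire degenerate corners up front in vectorized sweeps (always safe)
  repeat {
    m <- length(idx)
    if (m <= 3L) break
    ip <- idx[c(m, seq_len(m - 1L))]; inx <- idx[c(seq.int(2L, m), 1L)]
    cr <- (poly[idx, 1] - poly[ip, 1]) * (poly[inx, 2] - poly[ip, 2]) -
      (poly[idx, 2] - poly[ip, 2]) * (poly[inx, 1] - poly[ip, 1])
    degen <- which(abs(cr) <= tol_area)
    if (length(degen) == 0L) break
    # only non-adjacent positions in one sweep (removal shifts neighbors)
    take <- degen[c(TRUE, diff(degen) > 1L)]
    if (length(take) > 1L && take[1] == 1L && take[length(take)] == m)
      take <- take[-length(take)]
    for (q in take) {
      nt <- nt + 1L
      tris[nt, ] <- c(ip[q], idx[q], inx[q])
    }
    idx <- idx[-take]
  }
  while (length(idx) > 3L) {
    m <- length(idx)
    ip <- idx[c(m, seq_len(m - 1L))]; inx <- idx[c(seq.int(2L, m), 1L)]
    crs <- (poly[idx, 1] - poly[ip, 1]) * (poly[inx, 2] - poly[ip, 2]) -
      (poly[idx, 2] - poly[ip, 2]) * (poly[inx, 1] - poly[ip, 1])
    if (!ccw) crs <- -crs
    # retire a degenerate corner first (always safe)
    dg <- which(abs(crs) <= tol_area)
    if (length(dg) > 0L) {
      q <- dg[1]
      nt <- nt + 1L; tris[nt, ] <- c(ip[q], idx[q], inx[q])
      idx <- idx[-q]
      next
    }
    found <- FALSE
    for (q in which(crs > 0)) {
      a <- poly[ip[q], ]; b <- poly[idx[q], ]; c <- poly[inx[q], ]
      ov <- idx[!(idx %in% c(ip[q], idx[q], inx[q]))]
      if (length(ov) > 0L) {
        ox <- poly[ov, 1]; oy <- poly[ov, 2]
        d1 <- (ox - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (oy - b[2])
        d2 <- (ox - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (oy - c[2])
        d3 <- (ox - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (oy - a[2])
        has_neg <- d1 < 1e-12 | d2 < 1e-12 | d3 < 1e-12
        has_pos <- d1 > -1e-12 | d2 > -1e-12 | d3 > -1e-12
        if (any(!(has_neg & has_pos))) next  # some vertex inside the ear
      }
      nt <- nt + 1L
      tris[nt, ] <- c(ip[q], idx[q], inx[q])
      idx <- idx[-q]
      found <- TRUE
      break
    }
    if (!found) return(NULL)
  }
  if (length(idx) == 3L) {
    nt <- nt + 1L
    tris[nt, ] <- idx
  }
  tris[seq_len(nt), , drop = FALSE]
}

#' Resected bone and residual tumor volumes for a cutting path
#'
#' Builds and orients the extruded surface for `path` (z-extent = bone
#' z-extent inflated 5% each side), splits the bone and the margin-expanded
#' tumor, and reports the two objective volume terms. Validity checks are
#' the caller's responsibility (see [evaluate_objective()]); a null split is
#' reported through `ok = FALSE` rather than an error so the optimizer can
#' penalize it.
#'
#' @param case a [canonicalize_case()] result.
#' @param path a [cutting_path()] / point matrix (already polar-ordered).
#' @return list with `vol_B_cut`, `vol_T_left` (mm^3), `ok`, `reason`, the
#'   oriented `surface`, and the four split pieces.
#' @export
resected_volumes <- function(case, path) {
  surface <- case_surface(case, path)
  if (surface$multi_reflex)
    return(list(vol_B_cut = NA_real_, vol_T_left = NA_real_, ok = FALSE,
                reason = "multi-reflex-gap", surface = surface))
  sb <- split_with_surface(case$bone, surface, case$tumor_centroid)
  st <- split_with_surface(case$tumor_expanded, surface, case$tumor_centroid)
  if (is.null(sb$resected) || is.null(st$resected))
    return(list(vol_B_cut = NA_real_, vol_T_left = NA_real_, ok = FALSE,
                reason = "null-split", surface = surface))
  # splits are watertight by construction (tested property); the direct
  # signed volume avoids re-hashing every edge inside the optimizer loop.
  # A fold-over of the cut surface (pathological swarm configurations whose
  # unrolled cut outline self-crosses) shows up as a non-positive signed
  # volume; such splits are geometrically meaningless and get penalized.
  vol_B_cut <- signed_volume(sb$resected)
  vol_T_res <- signed_volume(st$resected)
  vol_B_rem <- if (is.null(sb$remainder)) 0 else signed_volume(sb$remainder)
  vol_T_rem <- if (is.null(st$remainder)) 0 else signed_volume(st$remainder)
  if (vol_B_cut <= 1e-9 || vol_T_res <= 1e-9 || vol_B_rem < -1e-9 || vol_T_rem < -1e-9)
    return(list(vol_B_cut = NA_real_, vol_T_left = NA_real_, ok = FALSE,
                reason = "null-split", surface = surface))
  list(vol_B_cut = vol_B_cut,
       vol_T_left = max(case$vol_T_tot - vol_T_res, 0),
       ok = TRUE, reason = NULL, surface = surface,
       bone_resected = sb$resected, bone_remainder = sb$remainder,
       tumor_resected = st$resected, tumor_remainder = st$remainder)
}

# Oriented surface for a path in a case's canonical frame.
case_surface <- function(case, path) {
  zb <- range(case$bone$vertices[, 3])
  zt <- range(case$tumor_expanded$vertices[, 3])
  zr <- c(min(zb[1], zt[1]), max(zb[2], zt[2]))
  pad <- 0.05 * (zr[2] - zr[1])
  surface <- build_surface(path, c(zr[1] - pad, zr[2] + pad))
  orient_facets(surface, case$tumor_centroid[1:2])
}
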