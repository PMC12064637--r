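#' Axis-aligned box mesh
#'
#' Each face is a subdivided grid so that splitting operations see edges no
#' longer than `resolution`; shared edges/corners are welded, so the result
#' is watertight with outward winding.
#'
#' @param lo,hi numeric 3-vectors, opposite corners (mm).
#' @param resolution target edge length (mm); `Inf` gives 2 triangles/face.
#' @return a watertight [triangle_mesh()].
#' @export
mesh_box <- function(lo, hi, resolution = Inf) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  dims <- hi - lo
  nseg <- pmax(1L, ceiling(dims / resolution))
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(); nv <- 0L
  get_vid <- function(p) {
    key <- paste(signif(p, 12), collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      key_env[[key]] <- nv
      id <- nv
    }
    id
  }
  faces <- list(); nf <- 0L
  # one grid face: origin o, spanning vectors u (nu segs) and v (nv segs);
  # quads split into triangles wound (o, u, v) right-handed
  add_face <- function(o, u, nu, v, nvv) {
    ids <- matrix(0L, nu + 1L, nvv + 1L)
    for (i in 0:nu) for (j in 0:nvv)
      ids[i + 1L, j + 1L] <- get_vid(o + u * (i / nu) + v * (j / nvv))
    for (i in 1:nu) for (j in 1:nvv) {
      a <- ids[i, j]; b <- ids[i + 1L, j]; c <- ids[i + 1L, j + 1L]; d <- ids[i, j + 1L]
      nf <<- nf + 1L; faces[[nf]] <<- c(a, b, c)
      nf <<- nf + 1L; faces[[nf]] <<- c(a, c, d)
    }
  }
  ex <- c(dims[1], 0, 0); ey <- c(0, dims[2], 0); ez <- c(0, 0, dims[3])
  nx <- nseg[1]; ny <- nseg[2]; nz <- nseg[3]
  add_face(lo, ey, ny, ex, nx)                      # bottom (z = lo), normal -z
  add_face(lo + ez, ex, nx, ey, ny)                 # top, normal +z
  add_face(lo, ex, nx, ez, nz)                      # front (y = lo), normal -y
  add_face(lo + ey, ez, nz, ex, nx)                 # back, normal +y
  add_face(lo, ez, nz, ey, ny)                      # left (x = lo), normal -x
  add_face(lo + ex, ey, ny, ez, nz)                 # right, normal +x
  m <- triangle_mesh(do.call(rbind, verts), do.call(rbind, faces))
  normalize_orientation(m)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the unit sphere, then anisotropically
#' scaled and translated. `subdivisions` doubles the edge count each level.
#'
#' @param radius scalar or 3-vector (ellipsoid semi-axes, mm).
#' @param center 3-vector (mm).
#' @param subdivisions integer >= 0.
#' @return a watertight [triangle_mesh()].
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_mid <- new.env(hash = TRUE, parent = emptyenv())
    newv <- list(); extra <- 0L
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (is.null(id)) {
        extra <<- extra + 1L
        p <- v[i, ] + v[j, ]
        newv[[extra]] <<- p / sqrt(sum(p^2))
        id <- nv + extra
        edge_mid[[key]] <- id
      }
      id
    }
    nf <- nrow(f)
    fout <- matrix(0L, nf * 4L, 3L)
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      fout[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- fout
  }
  radius <- rep(as.numeric(radius), length.out = 3)
  v <- sweep(sweep(v, 2, radius, "*"), 2, as.numeric(center), "+")
  normalize_orientation(triangle_mesh(v, f))
}

#' Surface-of-revolution mesh
#'
#' Revolves an open profile (radius_i, z_i) around the z-axis with closed
#' pole fans at both ends. Used for the capsule bone phantom.
#'
#' @param profile 2-column matrix (radius, z); first and last radius must be 0.
#' @param n_phi number of angular sectors.
#' @param center 3-vector offset.
#' @return a watertight [triangle_mesh()].
#' @export
mesh_revolve <- function(profile, n_phi = 32, center = c(0, 0, 0)) {
  profile <- as.matrix(profile)
  stopifnot(nrow(profile) >= 3, profile[1, 1] == 0, profile[nrow(profile), 1] == 0)
  m <- nrow(profile)
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- list(c(0, 0, profile[1, 2]))
  ring_ids <- list()
  nv <- 1L
  for (i in 2:(m - 1)) {
    ids <- integer(n_phi)
    for (k in seq_len(n_phi)) {
      nv <- nv + 1L
      verts[[nv]] <- c(profile[i, 1] * cos(phis[k]), profile[i, 1] * sin(phis[k]),
                       profile[i, 2])
      ids[k] <- nv
    }
    ring_ids[[i - 1L]] <- ids
  }
  nv <- nv + 1L
  verts[[nv]] <- c(0, 0, profile[m, 2])
  top <- 1L; bot <- nv
  faces <- list(); nf <- 0L
  r1 <- ring_ids[[1]]
  for (k in seq_len(n_phi)) {
    k2 <- k %% n_phi + 1L
    nf <- nf + 1L; faces[[nf]] <- c(top, r1[k], r1[k2])
  }
  if (length(ring_ids) > 1)
    for (i in seq_len(length(ring_ids) - 1L)) {
      ra <- ring_ids[[i]]; rb <- ring_ids[[i + 1L]]
      for (k in seq_len(n_phi)) {
        k2 <- k %% n_phi + 1L
        nf <- nf + 1L; faces[[nf]] <- c(ra[k], rb[k], rb[k2])
        nf <- nf + 1L; faces[[nf]] <- c(ra[k], rb[k2], ra[k2])
      }
    }
  rl <- ring_ids[[length(ring_ids)]]
  for (k in seq_len(n_phi)) {
    k2 <- k %% n_phi + 1L
    nf <- nf + 1L; faces[[nf]] <- c(bot, rl[k2], rl[k])
  }
  v <- sweep(do.call(rbind, verts), 2, as.numeric(center), "+")
  normalize_orientation(triangle_mesh(v, do.call(rbind, faces)))
}
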