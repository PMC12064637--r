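test_that("mesh I/O round-trips STL (binary + ASCII) and PLY", {
  ico <- mesh_icosphere(7.5, c(1, 2, 3), 3)
  for (ext in c("stl", "ply")) {
    p <- file.path(tempdir(), paste0("roundtrip.", ext))
    write_mesh(ico, p)
    back <- read_mesh(p)
    expect_equal(nrow(back$faces), nrow(ico$faces))
    # STL stores float32; PLY is written in full precision
    tol <- if (ext == "stl") 1e-6 else 1e-12
    expect_lt(abs(mesh_volume(back) - mesh_volume(ico)) / mesh_volume(ico), tol)
  }
  pa <- file.path(tempdir(), "ascii.stl")
  write_mesh(ico, pa, binary = FALSE)
  back <- read_mesh(pa)
  expect_lt(abs(mesh_volume(back) - mesh_volume(ico)) / mesh_volume(ico), 1e-9)
})

test_that("unit-cube STL reads as 8 vertices / 12 faces; volume and centroid are exact", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  expect_equal(nrow(cube$faces), 12L)
  p <- file.path(tempdir(), "cube.stl")
  write_mesh(cube, p)
  back <- read_mesh(p)
  expect_equal(nrow(back$vertices), 8L)
  expect_equal(nrow(back$faces), 12L)
  expect_equal(mesh_volume(back), 1.0)
  expect_equal(mesh_centroid(cube), c(0.5, 0.5, 0.5), tolerance = 1e-12)
})

test_that("a mesh with a deleted face is rejected as not watertight", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  broken <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  rep <- watertight_report(broken)
  expect_false(rep$watertight)
  expect_equal(rep$n_open_edges, 3L)
  p <- file.path(tempdir(), "broken.stl")
  write_mesh(broken, p)
  expect_error(read_mesh(p), "not watertight")
  expect_error(mesh_volume(broken), "not watertight")
})

test_that("icosphere volume approaches the analytic ball volume", {
  s <- mesh_icosphere(1, c(0, 0, 0), 4)
  expect_lt(abs(mesh_volume(s) - 4 * pi / 3) / (4 * pi / 3), 0.005)
})

test_that("volume is invariant under random rigid transforms", {
  set.seed(42)
  m <- mesh_icosphere(c(5, 3, 8), c(2, -1, 4), 3)
  v0 <- mesh_volume(m)
  for (i in 1:5) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- osteoplan:::rotation_between(c(0, 0, 1), ax)
    tf <- rigid_transform(R, stats::rnorm(3, sd = 20))
    expect_lt(abs(mesh_volume(transform_mesh(m, tf)) - v0) / v0, 1e-9)
  }
})

test_that("rigid transforms invert to identity", {
  R <- osteoplan:::rotation_between(c(1, 1, 0) / sqrt(2), c(0, 0, 1))
  tf <- rigid_transform(R, c(3, -4, 5))
  p <- matrix(stats::rnorm(30), 10, 3)
  back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, p))
  expect_lt(max(abs(back - p)), 1e-9)
})

test_that("mesh volumes agree with the voxel-column oracle on all phantom kinds", {
  for (kind in c("corner_column", "eccentric_ellipsoid", "concave_bean")) {
    ph <- make_phantom(phantom_spec(kind, resolution = 2.5))
    for (m in list(ph$bone, ph$tumor)) {
      vv <- voxel_volume_oracle(m, pitch = 0.5)
      expect_lt(abs(vv - mesh_volume(m)) / mesh_volume(m), 0.01)
    }
  }
})
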