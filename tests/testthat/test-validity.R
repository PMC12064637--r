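test_that("check_all_facets_cut flags the facet beside the bone", {
  cc <- corner_case(2)
  bone <- cc$case$bone
  # every facet crosses the footprint
  ok_path <- order_points_polar(rbind(c(9, -9), c(9, 9), c(-9, 9)))$points
  surf <- osteoplan:::case_surface(cc$case, ok_path)
  res <- check_all_facets_cut(bone, surf)
  expect_true(res$all_cut)
  expect_length(res$miss_indices, 0)
  # facet translated fully outside the footprint while its infinite plane
  # still crosses the bone: segment along x = 10 but y in [-60, -45]
  bad_path <- rbind(c(10, -60), c(10, -45), c(-9, 9))
  surf2 <- osteoplan:::case_surface(cc$case, bad_path)
  res2 <- check_all_facets_cut(bone, surf2)
  expect_false(res2$all_cut)
  expect_true(1L %in% res2$miss_indices)
})

test_that("check_all_facets_cut agrees with the facet-sampling oracle on random paths", {
  set.seed(1234)
  cc <- corner_case(2.5)
  el <- ellipsoid_case(3)
  pairs <- 0
  while (pairs < 50) {
    src <- if (pairs %% 2 == 0) cc else el
    bone <- src$case$bone
    np <- sample(3:5, 1)
    pm <- random_ring_path(np, 4, 35)
    pm <- pm + matrix(stats::rnorm(2 * np, sd = 6), ncol = 2)
    if (min(sqrt(rowSums(pm^2))) < 0.5) next
    path <- order_points_polar(pm)$points
    surf <- osteoplan:::case_surface(src$case, path)
    got <- check_all_facets_cut(bone, surf)
    pairs <- pairs + 1
    for (i in seq_len(osteoplan:::n_facets(surf))) {
      oracle <- facet_cut_sampling_oracle(bone, surf, i, n_samples = 3000)
      expect_equal(!(i %in% got$miss_indices), oracle,
                   label = sprintf("pair %d facet %d implementation", pairs, i),
                   expected.label = "sampling oracle")
    }
  }
})

test_that("find_self_intersections matches hand geometry and handles degeneracy", {
  # hand-solved crossing at (5, 0)
  res <- find_self_intersections(rbind(c(0, 0), c(10, 0), c(5, 5), c(5, -5)))
  expect_equal(nrow(res$points), 1L)
  expect_equal(res$points[1, ], c(5, 0), tolerance = 1e-12)
  expect_false(res$degenerate)
  # convex path: none
  conv <- order_points_polar(rbind(c(2, 0), c(0, 2), c(-2, 0), c(0, -2)))$points
  expect_equal(nrow(find_self_intersections(conv)$points), 0L)
  # overlapping collinear segments: degenerate, not a point
  res2 <- find_self_intersections(rbind(c(0, 0), c(10, 0), c(5, 5), c(2, 0), c(8, 0)))
  expect_true(res2$degenerate)
})

test_that("find_self_intersections agrees with the all-pairs orientation oracle", {
  set.seed(77)
  trials <- 0
  while (trials < 1000) {
    np <- sample(4:12, 1)
    pts <- matrix(stats::runif(2 * np, -10, 10), ncol = 2)
    oracle <- brute_self_intersections(pts)
    got <- find_self_intersections(pts)
    trials <- trials + 1
    if (oracle$degenerate || got$degenerate) {
      expect_equal(got$degenerate, oracle$degenerate)
    } else {
      expect_equal(nrow(got$points), oracle$count,
                   label = sprintf("trial %d crossings", trials))
    }
  }
})

test_that("self-intersection vertical-line test separates the in/out cases", {
  cc <- corner_case(2)
  bone <- cc$case$bone; tumor <- cc$case$tumor_expanded
  expect_false(self_intersection_hits_mesh(matrix(numeric(0), ncol = 2), bone, tumor))
  # crossing far outside both footprints
  expect_false(self_intersection_hits_mesh(rbind(c(200, 200)), bone, tumor))
  # crossing above the bone silhouette interior (z is irrelevant: line test)
  expect_true(self_intersection_hits_mesh(rbind(c(20, 20)), bone, tumor))
})

test_that("validity verdicts are invariant under rotations of the scene about z", {
  cc <- corner_case(2.5)
  case <- cc$case
  paths <- list(
    order_points_polar(rbind(c(9, -9), c(9, 9), c(-9, 9)))$points,
    rbind(c(10, -60), c(10, -45), c(-9, 9)))
  for (theta in c(0.4, 1.9, 3.6)) {
    R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
    tf <- rigid_transform(R, c(0, 0, 0))
    bone_r <- transform_mesh(case$bone, tf)
    for (p in paths) {
      pr <- p %*% t(R[1:2, 1:2])
      v0 <- check_all_facets_cut(case$bone, osteoplan:::case_surface(case, p))
      sr <- build_surface(pr, osteoplan:::case_surface(case, p)$z_range)
      v1 <- check_all_facets_cut(bone_r, sr)
      expect_equal(v1$all_cut, v0$all_cut)
      expect_equal(v1$miss_indices, v0$miss_indices)
    }
  }
})

test_that("validity_report composes the checks into is_valid", {
  cc <- corner_case(2)
  ok <- validity_report(cc$case, order_points_polar(rbind(c(9, -9), c(9, 9), c(-9, 9)))$points)
  expect_true(ok$is_valid)
  bad <- validity_report(cc$case, rbind(c(10, -60), c(10, -45), c(-9, 9)))
  expect_false(bad$is_valid)
  expect_false(bad$all_facets_cut)
})
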