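# Shared fixtures, built once per test run and cached. Mesh resolutions are
# test-scale (coarser than the 1 mm default) to keep the suite inside its
# time budget; the geometry they encode is identical.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

corner_case <- function(resolution = 2) {
  fixture(paste0("corner_", resolution), function() {
    ph <- make_phantom(phantom_spec("corner_column", resolution = resolution))
    list(phantom = ph,
         case = canonicalize_case(ph$bone, ph$tumor, ph$access,
                                  ph$n_planes, ph$margin_mm))
  })
}

ellipsoid_case <- function(resolution = 3) {
  fixture(paste0("ellipsoid_", resolution), function() {
    ph <- make_phantom(phantom_spec("eccentric_ellipsoid", resolution = resolution))
    list(phantom = ph,
         case = canonicalize_case(ph$bone, ph$tumor, ph$access,
                                  ph$n_planes, ph$margin_mm))
  })
}

bean_case <- function(resolution = 3) {
  fixture(paste0("bean_", resolution), function() {
    ph <- make_phantom(phantom_spec("concave_bean", resolution = resolution))
    list(phantom = ph,
         case = canonicalize_case(ph$bone, ph$tumor, ph$access,
                                  ph$n_planes, ph$margin_mm))
  })
}

# A random feasible-looking path around the origin for a case: points on a
# loose ring around the tumor footprint (not guaranteed feasible).
random_ring_path <- function(n_points, r_lo, r_hi) {
  ang <- sort(stats::runif(n_points, 0, 2 * pi))
  r <- stats::runif(n_points, r_lo, r_hi)
  cbind(r * cos(ang), r * sin(ang))
}
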