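test_that("plan_case + export produce consistent, re-derivable artifacts", {
  cc <- corner_case(2.5)
  obj <- objective_config(cc$case)
  rep <- plan_case(cc$case, obj,
                   pso_config(n_particles = 8, n_iterations = 10, seed = 21))
  expect_true(rep$feasible)
  expect_true(rep$validity$is_valid)
  # report f re-derivable from the stored best path
  re <- evaluate_objective(rep$final$path$points, cc$case, obj)
  expect_lt(abs(re$f - rep$final$f), 1e-9)
  out <- file.path(tempdir(), "planout")
  files <- export_plan(rep, cc$case, out)
  expect_true(file.exists(files$report))
  expect_true(file.exists(files$path_csv))
  expect_true(file.exists(files$facets))
  expect_true(file.exists(files$resected_stl))
  doc <- jsonlite::read_json(files$report, simplifyVector = TRUE)
  expect_equal(doc$f, rep$final$f, tolerance = 1e-12)
  expect_equal(doc$pso$seed, 21L)
  # exported resected STL is a closed solid with the reported volume
  res_mesh <- read_mesh(files$resected_stl)
  expect_lt(abs(mesh_volume(res_mesh) - rep$final$vol_B_cut) /
              rep$final$vol_B_cut, 1e-4)
  # evaluate round-trip through the path CSV
  r2 <- evaluate_case_path(cc$case, files$path_csv, obj)
  expect_lt(abs(r2$f - rep$final$f), 1e-9)
})

test_that("plan_case without ACH marks the warm start absent", {
  cc <- corner_case(2.5)
  rep <- plan_case(cc$case, objective_config(cc$case),
                   pso_config(n_particles = 6, n_iterations = 5, seed = 2),
                   use_ach = FALSE)
  expect_null(rep$ach)
  expect_null(rep$optimization$config$warm_start)
})

test_that("CLI: make-phantom writes a loadable case; n = 0 is a usage error before compute", {
  dir <- file.path(tempdir(), "cliout")
  status <- osteoplan_cli(c("make-phantom", "corner_column", dir,
                            "--resolution", "4"))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "case.json")))
  case <- read_case_file(file.path(dir, "case.json"))
  expect_equal(case$n_planes, 2L)
  expect_equal(case$vol_B_tot, 64000, tolerance = 1e-6)
  # invalid plane count is rejected before any geometry work
  status2 <- osteoplan_cli(c("plan", file.path(dir, "case.json"),
                             "--n-planes", "0"))
  expect_equal(status2, 2L)
})

test_that("CLI evaluate: optimal phantom path is accepted, facet-miss is reported", {
  dir <- file.path(tempdir(), "clieval")
  osteoplan_cli(c("make-phantom", "corner_column", dir, "--resolution", "4"))
  ph <- make_phantom(phantom_spec("corner_column", resolution = 4))
  utils::write.csv(data.frame(x = ph$optimal_path[, 1], y = ph$optimal_path[, 2]),
                   file.path(dir, "path.csv"), row.names = FALSE)
  out <- utils::capture.output(
    status <- osteoplan_cli(c("evaluate", file.path(dir, "case.json"),
                              file.path(dir, "path.csv"))))
  expect_equal(status, 0L)
  expect_true(any(grepl("0.0625", out)))
  utils::write.csv(data.frame(x = c(10, 10, -9), y = c(-60, -45, 9)),
                   file.path(dir, "bad.csv"), row.names = FALSE)
  out2 <- utils::capture.output(
    status2 <- osteoplan_cli(c("evaluate", file.path(dir, "case.json"),
                               file.path(dir, "bad.csv"))))
  expect_equal(status2, 3L)
  expect_true(any(grepl("facet-miss", out2)))
})
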