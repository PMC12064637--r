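#' Plan a resection: warm start, optimization, and report
#'
#' The end-to-end pipeline on a canonicalized case: build the
#' convex-hull-derived warm start (unless disabled or infeasible), run the
#' particle swarm, re-evaluate the best path with full detail, and
#' assemble a plan report. An infeasible warm start downgrades to a plain
#' run with a warning; an infeasible final result is flagged.
#'
#' @param case a [canonicalize_case()] result.
#' @param obj_config an [objective_config()].
#' @param pso_cfg a [pso_config()]; its `warm_start` field is overwritten
#'   by the ACH path when `use_ach` is TRUE.
#' @param use_ach build and inject the ACH warm start.
#' @return object of class `plan_report`: `case_summary`, `ach`,
#'   `optimization`, `final` (objective detail), `validity`, `feasible`.
#' @export
plan_case <- function(case, obj_config = objective_config(case),
                      pso_cfg = pso_config(), use_ach = TRUE) {
  ach <- NULL
  if (use_ach) {
    ach <- ach_initialize(case, obj_config)
    if (ach$feasible) {
      pso_cfg$warm_start <- ach$offset_points
    } else {
      warning("ACH warm start infeasible (", ach$reason,
              "); optimizing without it")
    }
  }
  opt <- pso_optimize(case, obj_config, pso_cfg)
  validity <- if (!is.null(opt$best_path))
    validity_report(case, opt$best_path) else NULL
  structure(list(
    case_summary = list(
      n_planes = case$n_planes, margin_mm = case$margin_mm,
      vol_B_tot = case$vol_B_tot, vol_T_tot = case$vol_T_tot,
      bone_bbox = case$bone_bbox),
    ach = ach,
    optimization = opt,
    final = opt$best_objective,
    validity = validity,
    feasible = opt$feasible
  ), class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat("plan_report\n")
  if (!is.null(x$ach)) print(x$ach)
  print(x$optimization)
  print(x$final)
  invisible(x)
}

#' Export plan artifacts
#'
#' Writes the machine-readable planning artifacts next to each other:
#' `report.json` (summary, history, validity), `path.csv` (the n+1 path
#' points), `facets.json` (per-facet plane equations, point + normal, for
#' downstream guide CAD), and the resected/remaining bone as STL.
#'
#' @param report a [plan_case()] result.
#' @param case the case the report was computed on.
#' @param dir output directory (created if missing).
#' @return named list of written file paths, invisibly.
#' @export
export_plan <- function(report, case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  final <- report$final
  doc <- list(
    feasible = report$feasible,
    f = final$f,
    vol_B_cut = final$vol_B_cut,
    vol_T_left = final$vol_T_left,
    penalized = final$penalized,
    reason = final$reason,
    case = report$case_summary[c("n_planes", "margin_mm", "vol_B_tot", "vol_T_tot")],
    pso = report$optimization$config[c("n_particles", "n_iterations",
                                       "schedule_kind", "seed")],
    ach = if (!is.null(report$ach)) list(
      feasible = report$ach$feasible,
      delta = report$ach$delta,
      n_hull = nrow(report$ach$hull_points),
      reason = report$ach$reason) else NULL,
    validity = if (!is.null(report$validity)) list(
      all_facets_cut = report$validity$all_facets_cut,
      facet_miss_indices = report$validity$facet_miss_indices,
      n_self_intersections = nrow(report$validity$self_intersections),
      self_intersection_hits_mesh = report$validity$self_intersection_hits_mesh,
      is_valid = report$validity$is_valid) else NULL,
    history = report$optimization$history)
  paths$report <- file.path(dir, "report.json")
  jsonlite::write_json(doc, paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(final$path)) {
    paths$path_csv <- file.path(dir, "path.csv")
    utils::write.csv(data.frame(x = final$path$points[, 1],
                                y = final$path$points[, 2]),
                     paths$path_csv, row.names = FALSE)
    surf <- case_surface(case, final$path)
    mids <- facet_midpoints(surf)
    facets <- lapply(seq_len(n_facets(surf)), function(i) list(
      point = c(mids[i, ], mean(surf$z_range)),
      normal = c(surf$normals[i, ], 0)))
    paths$facets <- file.path(dir, "facets.json")
    jsonlite::write_json(facets, paths$facets, auto_unbox = FALSE, digits = NA)
  }
  if (!is.null(final$meshes$bone_resected)) {
    paths$resected_stl <- file.path(dir, "bone_resected.stl")
    write_mesh(final$meshes$bone_resected, paths$resected_stl)
    paths$remainder_stl <- file.path(dir, "bone_remainder.stl")
    if (!is.null(final$meshes$bone_remainder))
      write_mesh(final$meshes$bone_remainder, paths$remainder_stl)
  }
  invisible(paths)
}

#' Evaluate an externally provided path against a case
#'
#' Single full-detail evaluation (the planning objective plus the validity
#' report), e.g. to assess or refine a surgeon-drawn cutting path.
#'
#' @param case a [canonicalize_case()] result.
#' @param path [cutting_path()], point matrix, or a CSV file with x,y columns.
#' @param obj_config an [objective_config()].
#' @return an `objective_result` with attached `validity`.
#' @export
evaluate_case_path <- function(case, path, obj_config = objective_config(case)) {
  if (is.character(path)) {
    df <- utils::read.csv(path)
    path <- as.matrix(df[, c("x", "y")])
  }
  pts <- if (inherits(path, "cutting_path")) path$points else
    matrix(as.numeric(path), ncol = 2)
  evaluate_objective(pts, case, obj_config, keep_meshes = TRUE)
}

#' Command-line interface
#'
#' Entry point behind the `inst/cli/osteoplan` script. Commands:
#' `plan <case.json>`, `evaluate <case.json> <path.csv>`,
#' `make-phantom <kind> <dir>`, `experiment <case.json>`. Flags (all
#' optional): `--n-planes`, `--margin`, `--access x,y,z`, `--particles`,
#' `--iterations`, `--schedule`, `--c1`, `--c2`, `--omega`, `--seed`,
#' `--no-ach`, `--k-weight`, `--out`, `--resolution`, `--repeats`.
#' Precedence: flag > case file > documented default.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
osteoplan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    cat("usage: osteoplan <plan|evaluate|make-phantom|experiment> ...\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt <- cli_options(rest)
  pos <- opt$positional
  status <- 0L
  if (cmd == "make-phantom") {
    if (length(pos) < 2L) { cat("usage: osteoplan make-phantom <kind> <dir>\n"); return(invisible(1L)) }
    ph <- make_phantom(phantom_spec(pos[1], resolution = opt$resolution))
    dir.create(pos[2], recursive = TRUE, showWarnings = FALSE)
    write_mesh(ph$bone, file.path(pos[2], "bone.stl"))
    write_mesh(ph$tumor, file.path(pos[2], "tumor.stl"))
    write_case_file(file.path(pos[2], "case.json"), "bone.stl", "tumor.stl",
                    ph$access,
                    n_planes = if (!is.null(opt$n_planes)) opt$n_planes else ph$n_planes,
                    margin_mm = if (!is.null(opt$margin)) opt$margin else ph$margin_mm)
    cat("phantom written to ", pos[2], "\n", sep = "")
  } else if (cmd %in% c("plan", "evaluate", "experiment")) {
    if (length(pos) < 1L) { cat("usage: osteoplan ", cmd, " <case.json> ...\n", sep = ""); return(invisible(1L)) }
    doc <- jsonlite::read_json(pos[1], simplifyVector = TRUE)
    if (!is.null(opt$n_planes)) doc$n_planes <- opt$n_planes
    if (!is.null(opt$margin)) doc$margin_mm <- opt$margin
    if (!is.null(opt$access)) doc$access <- opt$access
    if (is.null(doc$n_planes) || doc$n_planes < 1) {
      cat("error: n_planes must be a positive integer\n")
      return(invisible(2L))
    }
    dirn <- dirname(normalizePath(pos[1]))
    resolve <- function(p) if (file.exists(p)) p else file.path(dirn, p)
    case <- canonicalize_case(read_mesh(resolve(doc$bone)),
                              read_mesh(resolve(doc$tumor)),
                              as.numeric(doc$access), doc$n_planes,
                              if (is.null(doc$margin_mm)) 0 else doc$margin_mm)
    obj <- objective_config(case, K = opt$k_weight)
    if (cmd == "evaluate") {
      if (length(pos) < 2L) { cat("usage: osteoplan evaluate <case.json> <path.csv>\n"); return(invisible(1L)) }
      res <- evaluate_case_path(case, pos[2], obj)
      print(res)
      if (res$penalized) status <- 3L
    } else if (cmd == "plan") {
      cfg <- pso_config(n_particles = opt$particles, n_iterations = opt$iterations,
                        schedule_kind = opt$schedule, omega = opt$omega,
                        c1 = opt$c1, c2 = opt$c2, seed = opt$seed)
      rep <- plan_case(case, obj, cfg, use_ach = !opt$no_ach)
      print(rep)
      files <- export_plan(rep, case, opt$out)
      cat("artifacts in ", opt$out, "\n", sep = "")
      if (!rep$feasible) status <- 3L
    } else {
      grid <- list(
        variable = pso_config(n_particles = opt$particles,
                              n_iterations = opt$iterations,
                              schedule_kind = "variable", seed = opt$seed),
        c2_2_c2_2 = pso_config(n_particles = opt$particles,
                               n_iterations = opt$iterations,
                               schedule_kind = "constant", omega = 0.8,
                               c1 = 2, c2 = 2, seed = opt$seed))
      tab <- run_experiment(case, grid, repeats = opt$repeats, obj_config = obj,
                            base_seed = opt$seed)
      print(tab)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(tab, file.path(opt$out, "experiment.csv"), row.names = FALSE)
    }
  } else {
    cat("unknown command: ", cmd, "\n", sep = "")
    status <- 1L
  }
  invisible(status)
}

# Minimal flag parser (flags may appear anywhere; "--flag value" pairs).
cli_options <- function(args) {
  opt <- list(particles = 150L, iterations = 100L, schedule = "variable",
              omega = 0.8, c1 = 2, c2 = 2, seed = 1L, no_ach = FALSE,
              k_weight = 100, out = "osteoplan_out", resolution = 1,
              repeats = 3L, n_planes = NULL, margin = NULL, access = NULL,
              positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    grab <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "--n-planes" = { opt$n_planes <- as.integer(grab()) },
      "--margin" = { opt$margin <- as.numeric(grab()) },
      "--access" = { opt$access <- as.numeric(strsplit(grab(), ",")[[1]]) },
      "--particles" = { opt$particles <- as.integer(grab()) },
      "--iterations" = { opt$iterations <- as.integer(grab()) },
      "--schedule" = { opt$schedule <- grab() },
      "--c1" = { opt$c1 <- as.numeric(grab()) },
      "--c2" = { opt$c2 <- as.numeric(grab()) },
      "--omega" = { opt$omega <- as.numeric(grab()) },
      "--seed" = { opt$seed <- as.integer(grab()) },
      "--k-weight" = { opt$k_weight <- as.numeric(grab()) },
      "--out" = { opt$out <- grab() },
      "--resolution" = { opt$resolution <- as.numeric(grab()) },
      "--repeats" = { opt$repeats <- as.integer(grab()) },
      "--no-ach" = { opt$no_ach <- TRUE },
      { opt$positional <- c(opt$positional, a) })
    i <- i + 1L
  }
  opt
}
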