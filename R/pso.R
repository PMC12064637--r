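#' Particle swarm configuration
#'
#' Standard global-best PSO over the `2(n+1)` path coordinates. Two
#' coefficient schedules are supported: `constant` (fixed omega, c1, c2;
#' the reference grid holds omega = 0.8 and c1 + c2 = 4) and `variable`,
#' which interpolates linearly from exploration to exploitation across
#' iterations (omega 0.9 -> 0.4, c1 2.5 -> 0.5, c2 0.5 -> 2.5 by default).
#'
#' @param n_particles swarm size (reference default 150).
#' @param n_iterations iteration count (reference default 100).
#' @param schedule_kind `"constant"` or `"variable"`.
#' @param omega,c1,c2 constant-schedule coefficients.
#' @param omega_range,c1_range,c2_range variable-schedule endpoints
#'   (start -> end).
#' @param seed integer RNG seed; every run with the same seed is
#'   bit-reproducible.
#' @param warm_start optional [cutting_path()] (or point matrix) replacing
#'   one random particle's initial position.
#' @param velocity_clamp velocity limit as a fraction of the bounding-box
#'   diagonal, applied per component.
#' @return object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 150, n_iterations = 100,
                       schedule_kind = c("variable", "constant"),
                       omega = 0.8, c1 = 2, c2 = 2,
                       omega_range = c(0.9, 0.4),
                       c1_range = c(2.5, 0.5),
                       c2_range = c(0.5, 2.5),
                       seed = 1L, warm_start = NULL,
                       velocity_clamp = 0.2) {
  schedule_kind <- match.arg(schedule_kind)
  stopifnot(n_particles >= 1, n_iterations >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 schedule_kind = schedule_kind,
                 omega = omega, c1 = c1, c2 = c2,
                 omega_range = omega_range, c1_range = c1_range,
                 c2_range = c2_range,
                 seed = as.integer(seed),
                 warm_start = warm_start,
                 velocity_clamp = velocity_clamp),
            class = "pso_config")
}

#' Coefficient schedule
#'
#' @param iteration 1-based iteration index.
#' @param config a [pso_config()].
#' @return named vector `c(omega, c1, c2)` for that iteration; the variable
#'   schedule interpolates linearly from the first to the last iteration.
#' @export
coefficient_schedule <- function(iteration, config) {
  if (config$schedule_kind == "constant")
    return(c(omega = config$omega, c1 = config$c1, c2 = config$c2))
  t <- if (config$n_iterations > 1L)
    (iteration - 1) / (config$n_iterations - 1) else 0
  lerp <- function(r) r[1] + t * (r[2] - r[1])
  c(omega = lerp(config$omega_range), c1 = lerp(config$c1_range),
    c2 = lerp(config$c2_range))
}

#' Optimize the cutting path with particle swarm optimization
#'
#' Particles are `2(n+1)`-dimensional positions (xy pairs of the path
#' points), initialized uniformly inside the bone's xy bounding box;
#' positions are clamped to the box (with the offending velocity component
#' zeroed) and velocities clamped per component. If a warm start is given
#' it replaces particle 1's initial position, so the returned best can
#' never be worse than the warm start's own fitness.
#'
#' @param case a [canonicalize_case()] result.
#' @param obj_config an [objective_config()].
#' @param config a [pso_config()].
#' @param progress optional function(iteration, best_f) callback.
#' @param objective_fn optional replacement fitness `function(raw) -> f`
#'   (for algorithmic sanity checks); the default evaluates
#'   [evaluate_objective()] on the case.
#' @return object of class `optimization_result`: `best_path`,
#'   `best_objective`, `history` (best-ever f per iteration, including the
#'   initial evaluation), `penalized_fraction`, `feasible`, `config`,
#'   `wall_time_s`.
#' @export
pso_optimize <- function(case, obj_config = objective_config(case),
                         config = pso_config(), progress = NULL,
                         objective_fn = NULL) {
  t_start <- proc.time()[3]
  np <- config$n_particles
  dim <- 2L * (case$n_planes + 1L)
  bb <- case$bone_bbox
  lo <- rep(bb[1, 1:2], case$n_planes + 1L)   # interleaved x,y per point
  hi <- rep(bb[2, 1:2], case$n_planes + 1L)
  span <- hi - lo
  vmax <- config$velocity_clamp * sqrt(sum((bb[2, 1:2] - bb[1, 1:2])^2))

  set.seed(config$seed)
  pos <- matrix(stats::runif(np * dim, rep(lo, each = np), rep(hi, each = np)),
                nrow = np)
  vel <- matrix(stats::runif(np * dim, -0.1, 0.1), nrow = np) *
    matrix(rep(span, each = np), nrow = np)
  if (!is.null(config$warm_start)) {
    ws <- if (inherits(config$warm_start, "cutting_path"))
      config$warm_start$points else matrix(as.numeric(config$warm_start), ncol = 2)
    if (nrow(ws) != case$n_planes + 1L)
      stop("warm start must have n_planes + 1 points")
    pos[1, ] <- as.numeric(t(ws))
    vel[1, ] <- 0
  }

  eval_f <- if (is.null(objective_fn)) {
    function(x) evaluate_objective(x, case, obj_config)$f
  } else objective_fn
  fvals <- apply(pos, 1, eval_f)
  pbest <- pos
  pbest_f <- fvals
  gi <- which.min(pbest_f)
  gbest <- pbest[gi, ]
  gbest_f <- pbest_f[gi]
  history <- numeric(config$n_iterations + 1L)
  history[1] <- gbest_f
  pen_frac <- numeric(config$n_iterations + 1L)
  pen_frac[1] <- mean(fvals >= obj_config$penalty_value)

  for (it in seq_len(config$n_iterations)) {
    cf <- coefficient_schedule(it, config)
    r1 <- matrix(stats::runif(np * dim), nrow = np)
    r2 <- matrix(stats::runif(np * dim), nrow = np)
    vel <- cf[["omega"]] * vel +
      cf[["c1"]] * r1 * (pbest - pos) +
      cf[["c2"]] * r2 * sweep(pos, 2, gbest, function(p, g) g - p)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pos + vel
    # clamp to bounds, zeroing the offending velocity component
    for (j in seq_len(dim)) {
      low <- pos[, j] < lo[j]; high <- pos[, j] > hi[j]
      if (any(low)) { pos[low, j] <- lo[j]; vel[low, j] <- 0 }
      if (any(high)) { pos[high, j] <- hi[j]; vel[high, j] <- 0 }
    }
    fvals <- apply(pos, 1, eval_f)
    better <- fvals < pbest_f
    pbest[better, ] <- pos[better, , drop = FALSE]
    pbest_f[better] <- fvals[better]
    gi <- which.min(pbest_f)
    if (pbest_f[gi] < gbest_f) {
      gbest <- pbest[gi, ]
      gbest_f <- pbest_f[gi]
    }
    history[it + 1L] <- gbest_f
    pen_frac[it + 1L] <- mean(fvals >= obj_config$penalty_value)
    if (!is.null(progress)) progress(it, gbest_f)
  }
  best_obj <- if (is.null(objective_fn))
    evaluate_objective(gbest, case, obj_config, keep_meshes = TRUE)
  else structure(list(f = gbest_f, penalized = FALSE, path = NULL),
                 class = "objective_result")
  structure(list(best_path = best_obj$path,
                 best_raw = gbest,
                 best_objective = best_obj,
                 history = history,
                 penalized_fraction = pen_frac,
                 feasible = !best_obj$penalized,
                 config = config,
                 wall_time_s = proc.time()[3] - t_start),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(paste0("optimization_result: best f = %.6f (%s) in %.1f s\n",
                     "  %d particles x %d iterations, schedule %s\n"),
              x$best_objective$f,
              if (x$feasible) "feasible" else "INFEASIBLE",
              x$wall_time_s, x$config$n_particles, x$config$n_iterations,
              x$config$schedule_kind))
  invisible(x)
}

#' Repeat-run experiment over PSO configurations
#'
#' Runs each configuration `repeats` times with consecutive seeds
#' (`base_seed + 0 ... repeats - 1`) and summarizes the final objective:
#' mean, standard deviation, and 95% confidence half-width computed as
#' `1.96 * sd / sqrt(repeats)`.
#'
#' @param case a [canonicalize_case()] result.
#' @param configs named list of [pso_config()] objects.
#' @param repeats runs per configuration.
#' @param obj_config an [objective_config()].
#' @param base_seed first seed; each repeat increments it.
#' @param objective_fn optional stub fitness, as in [pso_optimize()].
#' @return data.frame with one row per configuration (`config`, `mean`,
#'   `sd`, `ci95`, `n_feasible`) plus attribute `runs` holding all final f
#'   values.
#' @export
run_experiment <- function(case, configs, repeats = 10,
                           obj_config = objective_config(case),
                           base_seed = 1L, objective_fn = NULL) {
  stopifnot(length(configs) > 0, repeats >= 1)
  if (is.null(names(configs)))
    names(configs) <- paste0("config", seq_along(configs))
  allf <- matrix(NA_real_, nrow = repeats, ncol = length(configs),
                 dimnames = list(NULL, names(configs)))
  feas <- matrix(FALSE, nrow = repeats, ncol = length(configs))
  for (ci in seq_along(configs)) {
    for (r in seq_len(repeats)) {
      cfg <- configs[[ci]]
      cfg$seed <- as.integer(base_seed + r - 1L)
      res <- pso_optimize(case, obj_config, cfg, objective_fn = objective_fn)
      allf[r, ci] <- res$best_objective$f
      feas[r, ci] <- res$feasible
    }
  }
  out <- data.frame(
    config = names(configs),
    mean = colMeans(allf),
    sd = apply(allf, 2, stats::sd),
    ci95 = 1.96 * apply(allf, 2, stats::sd) / sqrt(repeats),
    n_feasible = colSums(feas),
    row.names = NULL)
  out$sd[is.na(out$sd)] <- 0
  out$ci95[is.na(out$ci95)] <- 0
  attr(out, "runs") <- allf
  out
}
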