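# Particle swarm search over the two Bezier control offsets (alpha, beta).
# The swarm minimizes path length under the crop-clearance constraint, with a
# position-update step factor that shrinks as iterations accumulate.

#' Adaptive position-update factor
#'
#' r(n) = 1 - tanh(n / (1 + n_max)): equal to 1 at the first iteration and
#' strictly decreasing, so the particles' position steps shrink as the search
#' proceeds.
#'
#' @param n iteration index (0-based), 0 <= n <= n_max.
#' @param n_max maximum number of iterations (>= 1).
#' @return the dimensionless factor r in (0, 1].
#' @export
adaptive_factor <- function(n, n_max) {
  if (any(!is.finite(n)) || any(n < 0)) stop("n must be >= 0", call. = FALSE)
  stop_if_not_scalar(n_max, "n_max")
  if (n_max < 1) stop("n_max must be >= 1", call. = FALSE)
  if (any(n > n_max)) stop("n must not exceed n_max", call. = FALSE)
  1 - tanh(n / (1 + n_max))
}

#' Swarm configuration
#'
#' @param n_particles swarm size.
#' @param n_max number of iterations.
#' @param omega inertia factor.
#' @param c1,c2 cognitive / social learning factors.
#' @param penalty fitness penalty (mm) added when a candidate trajectory
#'   fails the clearance check.
#' @param seed optional RNG seed for reproducible runs.
#' @return an object of class \code{swarm_config}.
#' @export
swarm_config <- function(n_particles = 5, n_max = 200, omega = 0.7,
                         c1 = 1.5, c2 = 1.5, penalty = 1e6, seed = NULL) {
  n_particles <- as.integer(n_particles); n_max <- as.integer(n_max)
  if (n_particles < 1L) stop("n_particles must be >= 1", call. = FALSE)
  if (n_max < 1L) stop("n_max must be >= 1", call. = FALSE)
  if (omega <= 0 || c1 <= 0 || c2 <= 0)
    stop("omega, c1, c2 must be positive", call. = FALSE)
  structure(list(n_particles = n_particles, n_max = n_max, omega = omega,
                 c1 = c1, c2 = c2, penalty = penalty, seed = seed),
            class = "swarm_config")
}

#' Initialize a swarm over a rectangular search box
#'
#' Positions are drawn uniformly inside \code{bounds}; velocities start at
#' zero. Personal and global bests are seeded from the initial evaluation.
#'
#' @param cfg a \code{\link{swarm_config}}. If \code{cfg$seed} is non-NULL the
#'   RNG is seeded here.
#' @param bounds 2 x 2 matrix: rows are dimensions (alpha, beta), columns are
#'   lower/upper limits.
#' @param fitness function \code{f(pos)} taking a length-2 position, returning
#'   a scalar (penalized) fitness in mm.
#' @return an object of class \code{swarm_state}.
#' @export
init_swarm <- function(cfg, bounds, fitness) {
  stopifnot(inherits(cfg, "swarm_config"))
  bounds <- matrix(as.numeric(bounds), 2, 2)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  np <- cfg$n_particles
  pos <- cbind(stats::runif(np, bounds[1, 1], bounds[1, 2]),
               stats::runif(np, bounds[2, 1], bounds[2, 2]))
  fit <- apply(pos, 1, fitness)
  g <- which.min(fit)
  structure(list(pos = pos, vel = matrix(0, np, 2),
                 pbest_pos = pos, pbest_fit = fit,
                 gbest_pos = pos[g, ], gbest_fit = fit[g],
                 n = 0L, bounds = bounds),
            class = "swarm_state")
}

#' Advance the swarm by one iteration
#'
#' Velocity update v <- omega v + c1 R1 (pbest - x) + c2 R2 (gbest - x) with
#' fresh uniform draws R1, R2 per particle and dimension, then position update
#' x <- x + r v with r the \code{\link{adaptive_factor}} at the current
#' iteration. Positions are clipped to the search box and the clipped
#' component's velocity zeroed; personal and global bests are refreshed.
#'
#' @param state a \code{\link{init_swarm}} state.
#' @param cfg a \code{\link{swarm_config}}.
#' @param fitness fitness function as in \code{\link{init_swarm}}.
#' @return the updated \code{swarm_state} (iteration counter incremented).
#' @export
swarm_step <- function(state, cfg, fitness) {
  stopifnot(inherits(state, "swarm_state"), inherits(cfg, "swarm_config"))
  np <- nrow(state$pos)
  R1 <- matrix(stats::runif(np * 2), np, 2)
  R2 <- matrix(stats::runif(np * 2), np, 2)
  vel <- cfg$omega * state$vel +
    cfg$c1 * R1 * (state$pbest_pos - state$pos) +
    cfg$c2 * R2 * (matrix(state$gbest_pos, np, 2, byrow = TRUE) - state$pos)
  r <- adaptive_factor(state$n, cfg$n_max)
  pos <- state$pos + r * vel
  for (d in 1:2) {
    lo <- state$bounds[d, 1]; hi <- state$bounds[d, 2]
    out <- pos[, d] < lo | pos[, d] > hi
    vel[out, d] <- 0
    pos[, d] <- clamp(pos[, d], lo, hi)
  }
  fit <- apply(pos, 1, fitness)
  better <- fit < state$pbest_fit
  state$pbest_pos[better, ] <- pos[better, ]
  state$pbest_fit[better] <- fit[better]
  g <- which.min(state$pbest_fit)
  state$gbest_pos <- state$pbest_pos[g, ]
  state$gbest_fit <- state$pbest_fit[g]
  state$pos <- pos; state$vel <- vel
  state$n <- state$n + 1L
  state
}

# Penalized fitness for a scene: path length, plus cfg$penalty when the
# candidate violates the clearance requirement.
scene_fitness <- function(scene, penalty) {
  emb <- plane_embedding(scene$s, scene$e)
  e2 <- c(emb$span, 0)
  function(pos) {
    traj <- build_arch(c(0, 0), e2, scene$obstacle, scene$params,
                       alpha = pos[1], beta = pos[2], embedding = emb)
    len <- path_length(traj)
    rep <- check_clearance(traj, margin = scene$params$margin)
    if (rep$feasible) len else len + penalty
  }
}

scene_bounds <- function(scene) {
  rbind(alpha = c(0, 0.8 * scene$params$h2),
        beta  = c(0, 0.8 * (scene$obstacle$w1 + scene$obstacle$w2)))
}

#' Optimize the Bezier transition offsets for a spray scene
#'
#' Runs the particle swarm over (alpha, beta) to find the shortest
#' crop-clearing arch trajectory between the scene's two weed positions.
#'
#' @param scene a \code{\link{spray_scene}}.
#' @param cfg a \code{\link{swarm_config}}.
#' @return an object of class \code{pso_plan}: best \code{alpha}, \code{beta},
#'   the corresponding \code{trajectory} (with plane embedding attached),
#'   \code{fitness} (its path length, mm), \code{clearance} report,
#'   \code{feasible} flag and the per-iteration global-best \code{history}.
#'   If no particle ever satisfies the clearance constraint the plan is
#'   returned with \code{feasible = FALSE} and a warning.
#' @export
optimize_transition <- function(scene, cfg = swarm_config()) {
  stopifnot(inherits(scene, "spray_scene"), inherits(cfg, "swarm_config"))
  fitness <- scene_fitness(scene, cfg$penalty)
  state <- init_swarm(cfg, scene_bounds(scene), fitness)
  history <- numeric(cfg$n_max)
  for (it in seq_len(cfg$n_max)) {
    state <- swarm_step(state, cfg, fitness)
    history[it] <- state$gbest_fit
  }
  emb <- plane_embedding(scene$s, scene$e)
  traj <- build_arch(c(0, 0), c(emb$span, 0), scene$obstacle, scene$params,
                     alpha = state$gbest_pos[1], beta = state$gbest_pos[2],
                     embedding = emb)
  rep <- check_clearance(traj, margin = scene$params$margin)
  feasible <- rep$feasible && state$gbest_fit < cfg$penalty
  if (!feasible)
    warning("no clearance-feasible trajectory found after ", cfg$n_max,
            " iterations; returning the best penalized candidate")
  structure(list(alpha = state$gbest_pos[1], beta = state$gbest_pos[2],
                 trajectory = traj, fitness = path_length(traj),
                 clearance = rep, feasible = feasible,
                 history = history, scene = scene, config = cfg),
            class = "pso_plan")
}

#' @export
print.pso_plan <- function(x, ...) {
  cat("Particle-swarm Bezier transition plan\n")
  cat(sprintf("  alpha = %.4f mm, beta = %.4f mm\n", x$alpha, x$beta))
  cat(sprintf("  path length: %.3f mm (%s)\n", x$fitness,
              if (x$feasible) "clearance feasible" else "NO feasible candidate"))
  cat(sprintf("  clearance margin over footprint: %.3f mm\n",
              x$clearance$min_margin))
  cat(sprintf("  swarm: %d particles, %d iterations\n",
              x$config$n_particles, x$config$n_max))
  invisible(x)
}

#' @export
summary.pso_plan <- function(object, ...) {
  print(object)
  cat(sprintf("  global-best fitness: start %.3f -> end %.3f mm\n",
              object$history[1], object$history[length(object$history)]))
  invisible(object)
}

#' @export
plot.pso_plan <- function(x, which = c("trajectory", "history"), ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    plot(x$trajectory, ...)
  } else {
    plot(seq_along(x$history), x$history, type = "l",
         xlab = "iteration", ylab = "global-best path length (mm)",
         main = "Swarm convergence", ...)
  }
  invisible(x)
}

#' Exhaustive grid search over the control-offset box
#'
#' Test oracle for \code{\link{optimize_transition}}: evaluates the same
#' penalized fitness on a regular grid and returns the argmin.
#'
#' @param scene a \code{\link{spray_scene}}.
#' @param resolution grid points per axis (>= 20).
#' @param penalty infeasibility penalty (mm).
#' @return list with \code{alpha}, \code{beta}, \code{fitness},
#'   \code{feasible}.
#' @export
grid_oracle <- function(scene, resolution = 40, penalty = 1e6) {
  resolution <- as.integer(resolution)
  if (resolution < 20L) stop("resolution must be >= 20", call. = FALSE)
  b <- scene_bounds(scene)
  fitness <- scene_fitness(scene, penalty)
  alphas <- seq(b[1, 1], b[1, 2], length.out = resolution)
  betas <- seq(b[2, 1], b[2, 2], length.out = resolution)
  grid <- as.matrix(expand.grid(alpha = alphas, beta = betas))
  fit <- apply(grid, 1, fitness)
  i <- which.min(fit)
  list(alpha = unname(grid[i, 1]), beta = unname(grid[i, 2]),
       fitness = unname(fit[i]), feasible = unname(fit[i]) < penalty)
}
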