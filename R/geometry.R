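# Arch ("inverted-U") seedling-avoidance trajectory in the vertical working
# plane. Coordinates are millimetres; the plane's u axis points from the start
# weed S towards the end weed E, z is height above ground.

#' Crop obstacle model
#'
#' A crop plant is idealized as a vertical cylinder standing between the two
#' weed positions: \code{w1} is the distance from the start point S to the near
#' edge of the cylinder footprint along u, \code{w2} the cylinder radius and
#' \code{h3} the plant height. The footprint occupies \code{[w1, w1 + 2*w2]}
#' on the u axis, so the bottom-circle centre sits at \code{u = w1 + w2}.
#'
#' @param w1 standoff from S to the near footprint edge (mm).
#' @param w2 cylinder radius (mm).
#' @param h3 plant height (mm).
#' @return an object of class \code{crop_obstacle}.
#' @export
crop_obstacle <- function(w1, w2, h3) {
  stop_if_not_scalar(w1, "w1"); stop_if_not_scalar(w2, "w2")
  stop_if_not_scalar(h3, "h3")
  if (w1 < 0 || w2 < 0 || h3 < 0)
    stop("obstacle parameters w1, w2, h3 must be non-negative", call. = FALSE)
  structure(list(w1 = w1, w2 = w2, h3 = h3), class = "crop_obstacle")
}

#' @export
print.crop_obstacle <- function(x, ...) {
  cat(sprintf("Crop cylinder: standoff w1 = %g mm, radius w2 = %g mm, height h3 = %g mm\n",
              x$w1, x$w2, x$h3))
  cat(sprintf("  footprint on u: [%g, %g] mm\n", x$w1, x$w1 + 2 * x$w2))
  invisible(x)
}

#' Trajectory phase parameters
#'
#' @param h1 vertical ascent S to P0 (mm, >= 0).
#' @param h2 vertical extent of the Bezier transition (mm, > 0); the apex of
#'   the arch is at height \code{h1 + h2}.
#' @param margin extra clearance required over the obstacle (mm).
#' @param samples polyline samples per trajectory phase.
#' @return an object of class \code{trajectory_params}.
#' @export
trajectory_params <- function(h1 = 20, h2 = 150, margin = 0, samples = 200) {
  stop_if_not_scalar(h1, "h1"); stop_if_not_scalar(h2, "h2")
  stop_if_not_scalar(margin, "margin")
  if (h1 < 0) stop("h1 must be >= 0", call. = FALSE)
  if (h2 <= 0) stop("h2 must be > 0", call. = FALSE)
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  samples <- as.integer(samples)
  if (samples < 2L) stop("samples must be >= 2", call. = FALSE)
  structure(list(h1 = h1, h2 = h2, margin = margin, samples = samples),
            class = "trajectory_params")
}

#' Cubic Bezier segment
#'
#' @param p0,p1,p2,p3 length-2 (u, z) control points (mm).
#' @return an object of class \code{bezier_segment}: a 4 x 2 control matrix.
#' @export
bezier_segment <- function(p0, p1, p2, p3) {
  m <- rbind(as_planar(p0, "p0"), as_planar(p1, "p1"),
             as_planar(p2, "p2"), as_planar(p3, "p3"))
  dimnames(m) <- list(c("p0", "p1", "p2", "p3"), c("u", "z"))
  structure(m, class = c("bezier_segment", "matrix"))
}

#' Evaluate a cubic Bezier curve
#'
#' B(t) = (1-t)^3 P0 + 3 t (1-t)^2 P1 + 3 t^2 (1-t) P2 + t^3 P3.
#'
#' @param seg a \code{\link{bezier_segment}}.
#' @param t curve parameter(s) in [0, 1].
#' @return a \code{length(t)} x 2 matrix of (u, z) points.
#' @export
eval_cubic_bezier <- function(seg, t) {
  stopifnot(inherits(seg, "bezier_segment"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("t must lie in [0, 1]", call. = FALSE)
  w <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  out <- w %*% unclass(seg)
  colnames(out) <- c("u", "z")
  out
}

# Analytic first/second derivatives of the cubic at t (length(t) x 2 each).
bezier_derivatives <- function(seg, t) {
  P <- unclass(seg)
  d1 <- 3 * (cbind((1 - t)^2, 2 * t * (1 - t), t^2) %*%
               rbind(P[2, ] - P[1, ], P[3, ] - P[2, ], P[4, ] - P[3, ]))
  d2 <- 6 * (cbind(1 - t, t) %*%
               rbind(P[3, ] - 2 * P[2, ] + P[1, ], P[4, ] - 2 * P[3, ] + P[2, ]))
  list(d1 = d1, d2 = d2)
}

#' Curvature of a cubic Bezier curve
#'
#' k(t) = |u' z'' - u'' z'| / (u'^2 + z'^2)^(3/2) with analytic derivatives.
#' The curvature is what the planner's control-point bounds keep smooth at the
#' junction with the horizontal phase.
#'
#' @inheritParams eval_cubic_bezier
#' @return numeric vector of curvatures (1/mm).
#' @export
bezier_curvature <- function(seg, t) {
  stopifnot(inherits(seg, "bezier_segment"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("t must lie in [0, 1]", call. = FALSE)
  d <- bezier_derivatives(seg, t)
  speed2 <- rowSums(d$d1^2)
  if (any(speed2 < 1e-18))
    stop("degenerate Bezier segment: zero first derivative, curvature is singular",
         call. = FALSE)
  unname(abs(d$d1[, 1] * d$d2[, 2] - d$d2[, 1] * d$d1[, 2]) / speed2^1.5)
}

sample_line <- function(a, b, n) {
  t <- seq(0, 1, length.out = n)
  cbind(u = a[1] + t * (b[1] - a[1]), z = a[2] + t * (b[2] - a[2]))
}

#' Build the arch-shaped seedling-avoidance trajectory
#'
#' Constructs the five-phase path S -> P0 (vertical ascent, height h1),
#' P0..P3 (cubic Bezier transition up to the apex height h1 + h2),
#' P3 -> P4 (horizontal pass over the crop cylinder), P4..P5 (mirrored Bezier
#' transition down) and P5 -> E (vertical descent). The transition's shape is
#' set by two offsets: \code{alpha} moves the first control point P1 straight
#' up from P0 (bounded by 0.8 h2) and \code{beta} pulls the second control
#' point P2 horizontally back from P3 towards S (bounded by 0.8 (w1 + w2)).
#' The E-side transition mirrors the same offsets.
#'
#' @param s,e length-2 (u, z) trajectory endpoints at ground level (z = 0),
#'   with \code{s = c(0, 0)} as the plane origin.
#' @param obstacle a \code{\link{crop_obstacle}}.
#' @param params a \code{\link{trajectory_params}}.
#' @param alpha vertical control offset for P1, in [0, 0.8 h2] (mm).
#' @param beta horizontal control offset for P2, in [0, 0.8 (w1 + w2)] (mm).
#' @param embedding optional \code{\link{plane_embedding}} recorded for
#'   mapping the planar path back into the robot frame.
#' @return an object of class \code{arch_trajectory}.
#' @export
build_arch <- function(s, e, obstacle, params, alpha = 0, beta = 0,
                       embedding = NULL) {
  s <- as_planar(s, "s"); e <- as_planar(e, "e")
  stopifnot(inherits(obstacle, "crop_obstacle"),
            inherits(params, "trajectory_params"))
  if (abs(s[2]) > 1e-9 || abs(e[2]) > 1e-9)
    stop("s and e must be at ground level (z = 0)", call. = FALSE)
  if (abs(s[1]) > 1e-9)
    stop("s must be the plane origin c(0, 0)", call. = FALSE)
  if (e[1] <= 0)
    stop("e must lie at positive u (the u axis points from S to E)", call. = FALSE)

  h1 <- params$h1; h2 <- params$h2; H <- h1 + h2
  w1 <- obstacle$w1; w2 <- obstacle$w2; h3 <- obstacle$h3
  alpha_max <- 0.8 * h2
  beta_max <- 0.8 * (w1 + w2)
  if (alpha < 0 || alpha > alpha_max)
    stop(sprintf("alpha must lie in [0, %.6g] (0.8 h2)", alpha_max), call. = FALSE)
  if (beta < 0 || beta > beta_max)
    stop(sprintf("beta must lie in [0, %.6g] (0.8 (w1 + w2))", beta_max), call. = FALSE)
  if (H <= h3)
    stop(sprintf("infeasible scene: apex height h1 + h2 = %g does not exceed plant height h3 = %g",
                 H, h3), call. = FALSE)

  L <- e[1]
  p0 <- c(0, h1)
  p3 <- c(w1, H)
  p1 <- p0 + c(0, alpha)           # along S -> P0, i.e. straight up
  p2 <- p3 - c(beta, 0)            # along P4 -> P3, i.e. back towards S
  p4 <- c(w1 + 2 * w2, H)
  p5 <- c(L, h1)
  bez_up <- bezier_segment(p0, p1, p2, p3)
  bez_dn <- bezier_segment(p4, p4 + c(beta, 0), p5 + c(0, alpha), p5)

  n <- params$samples
  tseq <- seq(0, 1, length.out = n)
  phases <- list(
    ascent     = sample_line(s, p0, n),
    transition_up   = eval_cubic_bezier(bez_up, tseq),
    horizontal = sample_line(p3, p4, n),
    transition_down = eval_cubic_bezier(bez_dn, tseq),
    descent    = sample_line(p5, e, n)
  )
  # phase joints are sampled twice (end of one phase, start of the next) so
  # every phase slice carries its own endpoints; the repeated points are
  # zero-length chords and harmless downstream
  phase_name <- rep(names(phases), each = n)
  tpar <- rep(tseq, times = length(phases))
  poly <- do.call(rbind, phases)
  structure(list(
    s = s, e = e, obstacle = obstacle, params = params,
    alpha = alpha, beta = beta,
    bezier_up = bez_up, bezier_down = bez_dn,
    p0 = p0, p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
    polyline = poly,
    phase = phase_name, t = tpar,
    embedding = embedding
  ), class = "arch_trajectory")
}

#' Polyline path length
#'
#' Sum of Euclidean chord lengths over the sampled trajectory polyline; this
#' is the quantity the swarm optimizer minimizes.
#'
#' @param traj an \code{\link{arch_trajectory}}, or a plain n x 2 / n x 3
#'   matrix of points.
#' @return total length (mm).
#' @export
path_length <- function(traj) {
  pts <- if (inherits(traj, "arch_trajectory")) traj$polyline else as.matrix(traj)
  if (nrow(pts) < 2L) stop("polyline needs at least 2 points", call. = FALSE)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

#' Check crop clearance of a trajectory
#'
#' A trajectory clears the crop when every polyline point whose u coordinate
#' falls over the cylinder footprint \code{[w1, w1 + 2*w2]} stays at least
#' \code{margin} above the plant height h3.
#'
#' @param traj an \code{\link{arch_trajectory}}.
#' @param obstacle a \code{\link{crop_obstacle}}; defaults to the one the
#'   trajectory was built against.
#' @param margin required extra height over h3 (mm).
#' @return an object of class \code{clearance_report}: list with
#'   \code{feasible}, \code{min_margin} (achieved minimum of z - h3 over the
#'   footprint, \code{Inf} when the footprint is not crossed),
#'   \code{footprint_crossed} and \code{margin}.
#' @export
check_clearance <- function(traj, obstacle = traj$obstacle, margin = 0) {
  stopifnot(inherits(traj, "arch_trajectory"), inherits(obstacle, "crop_obstacle"))
  stop_if_not_scalar(margin, "margin")
  lo <- obstacle$w1; hi <- obstacle$w1 + 2 * obstacle$w2
  u <- traj$polyline[, 1]; z <- traj$polyline[, 2]
  over <- u >= lo & u <= hi
  if (!any(over)) {
    if (lo > max(traj$e[1], traj$s[1]) || hi < min(traj$s[1], traj$e[1]))
      warning("obstacle footprint lies outside the trajectory span; trivially clear")
    return(structure(list(feasible = TRUE, min_margin = Inf,
                          footprint_crossed = FALSE, margin = margin),
                     class = "clearance_report"))
  }
  min_z <- min(z[over])
  structure(list(feasible = min_z >= obstacle$h3 + margin,
                 min_margin = min_z - obstacle$h3,
                 footprint_crossed = TRUE, margin = margin),
            class = "clearance_report")
}

#' @export
print.clearance_report <- function(x, ...) {
  cat(sprintf("Clearance: %s (min margin over footprint: %s mm, required: %g mm)\n",
              if (x$feasible) "feasible" else "INFEASIBLE",
              if (is.finite(x$min_margin)) sprintf("%.3f", x$min_margin) else "inf",
              x$margin))
  invisible(x)
}

#' Embed the vertical working plane in the robot frame
#'
#' The planner works in the vertical plane through the two weed positions,
#' with S at the origin and the u axis pointing towards E. This returns the
#' rigid transform between that plane and the 3-D robot frame.
#'
#' @param s3,e3 length-3 robot-frame weed positions (mm) at equal ground
#'   height.
#' @return an object of class \code{plane_embedding} with closures
#'   \code{to_plane(p)} (n x 3 -> n x 2) and \code{to_world(q)}
#'   (n x 2 -> n x 3), plus \code{origin}, \code{u_axis} and \code{span}
#'   (the distance |SE|).
#' @export
plane_embedding <- function(s3, e3) {
  s3 <- as_world(s3, "s3"); e3 <- as_world(e3, "e3")
  d <- e3 - s3
  span <- vnorm(d[1:2])
  if (span < 1e-12)
    stop("degenerate embedding: coincident (or vertically stacked) endpoints",
         call. = FALSE)
  if (abs(d[3]) > 1e-6)
    stop("s3 and e3 must be at the same ground height", call. = FALSE)
  ux <- c(d[1:2] / span, 0)
  to_plane <- function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    rel <- sweep(p, 2, s3)
    cbind(u = rel %*% ux, z = rel[, 3])
  }
  to_world <- function(q) {
    q <- matrix(as.numeric(q), ncol = 2)
    w <- cbind(s3[1] + q[, 1] * ux[1],
               s3[2] + q[, 1] * ux[2],
               s3[3] + q[, 2])
    colnames(w) <- c("x", "y", "z")
    w
  }
  structure(list(origin = s3, u_axis = ux, span = span,
                 to_plane = to_plane, to_world = to_world),
            class = "plane_embedding")
}

#' World-frame coordinates of a trajectory polyline
#'
#' @param traj an \code{\link{arch_trajectory}}.
#' @return n x 3 matrix (x, y, z) in mm. Without an embedding the plane is
#'   taken as the robot x-z plane (y = 0).
#' @export
trajectory_world <- function(traj) {
  stopifnot(inherits(traj, "arch_trajectory"))
  if (is.null(traj$embedding)) {
    cbind(x = traj$polyline[, 1], y = 0, z = traj$polyline[, 2])
  } else {
    traj$embedding$to_world(traj$polyline)
  }
}

#' @export
print.arch_trajectory <- function(x, ...) {
  cat("Arch seedling-avoidance trajectory\n")
  cat(sprintf("  span |SE|: %g mm; apex height: %g mm (h1 = %g, h2 = %g)\n",
              x$e[1], x$params$h1 + x$params$h2, x$params$h1, x$params$h2))
  cat(sprintf("  control offsets: alpha = %.3f mm, beta = %.3f mm\n", x$alpha, x$beta))
  cat(sprintf("  path length: %.3f mm over %d polyline points\n",
              path_length(x), nrow(x$polyline)))
  rep <- check_clearance(x, margin = x$params$margin)
  cat(sprintf("  clearance over crop footprint: %s\n",
              if (rep$feasible) sprintf("feasible (margin %.2f mm)", rep$min_margin)
              else "INFEASIBLE"))
  invisible(x)
}

#' @export
plot.arch_trajectory <- function(x, ...) {
  ob <- x$obstacle
  plot(x$polyline, type = "l", xlab = "u (mm)", ylab = "z (mm)", asp = 1,
       main = "Seedling-avoidance trajectory", ...)
  graphics::rect(ob$w1, 0, ob$w1 + 2 * ob$w2, ob$h3, border = "forestgreen",
                 col = grDevices::adjustcolor("forestgreen", 0.25))
  ctrl <- rbind(x$p0, x$p1, x$p2, x$p3, x$p4, x$p4 + c(x$beta, 0),
                x$p5 + c(0, x$alpha), x$p5)
  graphics::points(ctrl, pch = 4, col = "red")
  graphics::points(rbind(x$s, x$e), pch = 19, col = "blue")
  invisible(x)
}

#' Read a spray-scene description from JSON
#'
#' Expected shape: \code{{"s": [x,y,z], "e": [x,y,z],
#' "obstacle": {"w1": , "w2": , "h3": }, "params": {"h1": , "h2": ,
#' "margin": }}}, all in mm.
#'
#' @param path JSON file path.
#' @return a scene list with elements \code{s}, \code{e} (world points),
#'   \code{obstacle} and \code{params}.
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spray_scene(s = x$s, e = x$e,
              obstacle = crop_obstacle(x$obstacle$w1, x$obstacle$w2, x$obstacle$h3),
              params = trajectory_params(h1 = x$params$h1, h2 = x$params$h2,
                                         margin = x$params$margin %||% 0,
                                         samples = x$params$samples %||% 200))
}

#' Assemble a spray scene
#'
#' @param s,e length-3 robot-frame weed positions (mm).
#' @param obstacle a \code{\link{crop_obstacle}}.
#' @param params a \code{\link{trajectory_params}}.
#' @return a list of class \code{spray_scene}.
#' @export
spray_scene <- function(s, e, obstacle, params) {
  structure(list(s = as_world(s, "s"), e = as_world(e, "e"),
                 obstacle = obstacle, params = params),
            class = "spray_scene")
}

#' Write a spray scene to JSON
#'
#' @param scene a \code{\link{spray_scene}}.
#' @param path output file.
#' @export
write_scene <- function(scene, path) {
  jsonlite::write_json(list(
    s = scene$s, e = scene$e,
    obstacle = scene$obstacle[c("w1", "w2", "h3")],
    params = scene$params[c("h1", "h2", "margin", "samples")]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a trajectory polyline to CSV
#'
#' Columns: phase, t (parameter within phase), u_mm, z_mm and the robot-frame
#' x_mm, y_mm obtained through the trajectory's plane embedding.
#'
#' @param traj an \code{\link{arch_trajectory}}.
#' @param path output CSV file.
#' @export
write_trajectory_csv <- function(traj, path) {
  w <- trajectory_world(traj)
  df <- data.frame(phase = traj$phase, t = traj$t,
                   u_mm = traj$polyline[, 1], z_mm = traj$polyline[, 2],
                   x_mm = w[, 1], y_mm = w[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
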