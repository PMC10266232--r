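# Delta parallel-arm kinematics. The fixed base sits at the frame origin with
# its three shoulder joints at azimuths 0, 120, 240 degrees and the moving
# platform hangs below (negative z). Joint angles are measured from the
# horizontal, positive downwards, so deeper targets mean larger angles on the
# knee-out branch.

#' Delta arm geometry
#'
#' @param base_radius distance from the base centre to a shoulder joint (mm).
#' @param platform_radius distance from the platform centre to a forearm
#'   attachment (mm).
#' @param upper_arm driven upper-arm length (mm).
#' @param forearm passive forearm length (mm).
#' @param mount_height height of the base plane above the ground frame the
#'   trajectories live in (mm): a trajectory point at ground z maps to
#'   arm-frame z - mount_height.
#' @param joint_limits length-2 admissible joint-angle interval (radians).
#' @return an object of class \code{delta_geometry}.
#' @export
delta_geometry <- function(base_radius = 150, platform_radius = 50,
                           upper_arm = 200, forearm = 400,
                           mount_height = 500,
                           joint_limits = c(-pi / 2, pi * 0.75)) {
  v <- c(base_radius, platform_radius, upper_arm, forearm)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all delta-arm lengths must be positive", call. = FALSE)
  structure(list(base_radius = base_radius, platform_radius = platform_radius,
                 upper_arm = upper_arm, forearm = forearm,
                 mount_height = mount_height,
                 joint_limits = sort(as.numeric(joint_limits)),
                 azimuths = c(0, 2 * pi / 3, 4 * pi / 3)),
            class = "delta_geometry")
}

#' @export
print.delta_geometry <- function(x, ...) {
  cat(sprintf(paste0("Delta arm: base r = %g, platform r = %g, ",
                     "upper arm = %g, forearm = %g mm (mount %g mm)\n"),
              x$base_radius, x$platform_radius, x$upper_arm, x$forearm,
              x$mount_height), ...)
  invisible(x)
}

rotz <- function(a) {
  cbind(c(cos(a), sin(a), 0), c(-sin(a), cos(a), 0), c(0, 0, 1))
}

# One arm's IK in its own vertical plane (arm rotated onto azimuth 0).
ik_single_arm <- function(p, g, arm) {
  pr <- as.numeric(rotz(-g$azimuths[arm]) %*% p)
  px <- pr[1] + g$platform_radius - g$base_radius
  py <- pr[2]
  pz <- pr[3]
  L1 <- g$upper_arm; L2 <- g$forearm
  k <- (px^2 + py^2 + pz^2 + L1^2 - L2^2) / (2 * L1)
  C <- sqrt(px^2 + pz^2)
  if (C < 1e-12 || abs(k) > C)
    stop(sprintf("point out of workspace for arm %d", arm), call. = FALSE)
  delta <- atan2(pz, px)
  cand <- c(acos(clamp(k / C, -1, 1)) - delta,
            -acos(clamp(k / C, -1, 1)) - delta)
  # knee-out branch: elbow farther from the central axis (larger cos(theta))
  theta <- cand[which.max(cos(cand))]
  if (theta < g$joint_limits[1] || theta > g$joint_limits[2])
    stop(sprintf("joint angle %.3f rad outside limits for arm %d", theta, arm),
         call. = FALSE)
  theta
}

#' Inverse kinematics of the delta arm
#'
#' Maps an effector position (arm frame, z negative below the base) to the
#' three motor angles on the knee-out branch.
#'
#' @param p length-3 arm-frame point (mm) or an n x 3 matrix.
#' @param g a \code{\link{delta_geometry}}.
#' @return length-3 angle vector (radians), or an n x 3 matrix for matrix
#'   input; unreachable points raise an error naming the offending arm.
#' @export
inverse_kinematics <- function(p, g) {
  stopifnot(inherits(g, "delta_geometry"))
  if (is.matrix(p)) {
    out <- t(apply(p, 1, inverse_kinematics, g = g))
    colnames(out) <- c("theta1", "theta2", "theta3")
    return(out)
  }
  p <- as_world(p, "p")
  vapply(1:3, function(a) ik_single_arm(p, g, a), numeric(1))
}

#' Forward kinematics of the delta arm
#'
#' Places the three elbows from the joint angles and intersects the three
#' forearm spheres, taking the lower (negative-z) intersection.
#'
#' @param angles length-3 joint angles (radians).
#' @param g a \code{\link{delta_geometry}}.
#' @return length-3 effector position (arm frame, mm).
#' @export
forward_kinematics <- function(angles, g) {
  stopifnot(inherits(g, "delta_geometry"))
  angles <- as.numeric(angles)
  if (length(angles) != 3L || any(!is.finite(angles)))
    stop("angles must be a finite length-3 vector", call. = FALSE)
  L1 <- g$upper_arm; L2 <- g$forearm
  rad <- g$base_radius - g$platform_radius
  centers <- t(vapply(1:3, function(a) {
    as.numeric(rotz(g$azimuths[a]) %*%
                 c(rad + L1 * cos(angles[a]), 0, -L1 * sin(angles[a])))
  }, numeric(3)))
  # trilateration: subtract sphere 1 from spheres 2, 3 -> two planes
  A <- 2 * (centers[2:3, ] - matrix(centers[1, ], 2, 3, byrow = TRUE))
  b <- rowSums(centers[2:3, ]^2) - sum(centers[1, ]^2)
  # parametrize solution line: p = p0 + t * n, n = null space of A,
  # p0 the minimum-norm particular solution
  qrA <- qr(t(A))
  n <- qr.Q(qrA, complete = TRUE)[, 3]
  p0 <- as.numeric(t(A) %*% solve(A %*% t(A), b))
  d <- p0 - centers[1, ]
  # |d + t n|^2 = L2^2 with |n| = 1
  bq <- 2 * sum(d * n)
  cq <- sum(d^2) - L2^2
  disc <- bq^2 - 4 * cq
  if (disc < 0)
    stop("forearm spheres do not intersect for these angles", call. = FALSE)
  t1 <- (-bq + sqrt(disc)) / 2
  t2 <- (-bq - sqrt(disc)) / 2
  p1 <- p0 + t1 * n
  p2 <- p0 + t2 * n
  if (p1[3] <= p2[3]) p1 else p2
}

#' Discretize a trajectory at equal arc-length spacing
#'
#' Resamples the trajectory polyline into \code{n} points whose consecutive
#' spacings along the polyline are equal, keeping the exact endpoints; this is
#' the point stream handed to the joint controller.
#'
#' @param traj an \code{\link{arch_trajectory}} (world coordinates are used,
#'   via the plane embedding when present) or a plain n x 2 / n x 3 polyline
#'   matrix.
#' @param n number of output points (>= 2), 100 by default.
#' @return n x k matrix of points (k = input dimension).
#' @export
discretize_trajectory <- function(traj, n = 100) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  pts <- if (inherits(traj, "arch_trajectory")) trajectory_world(traj)
         else as.matrix(traj)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < .Machine$double.eps) {
    out <- pts[rep(1L, n), , drop = FALSE]
    return(out)
  }
  target <- seq(0, total, length.out = n)
  out <- matrix(NA_real_, n, ncol(pts))
  for (j in seq_len(ncol(pts)))
    out[, j] <- stats::approx(cum, pts[, j], xout = target, ties = "ordered")$y
  out[1, ] <- pts[1, ]
  out[n, ] <- pts[nrow(pts), ]
  colnames(out) <- colnames(pts)
  out
}

#' Per-step joint-angle differences along a point stream
#'
#' Solves the inverse kinematics at every discretized trajectory point (after
#' shifting ground-frame z by the arm's mount height) and returns the
#' difference of the three joint angles between adjacent points -- the
#' rotation increments the three motors execute per step.
#'
#' @param points n x 3 matrix of ground-frame points (mm).
#' @param g a \code{\link{delta_geometry}}.
#' @return list with \code{angles} (n x 3, radians) and \code{deltas}
#'   ((n-1) x 3); a workspace failure reports the offending point index.
#' @export
joint_deltas <- function(points, g) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  arm_pts <- points
  arm_pts[, 3] <- arm_pts[, 3] - g$mount_height
  angles <- matrix(NA_real_, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    angles[i, ] <- tryCatch(inverse_kinematics(arm_pts[i, ], g),
                            error = function(e) {
                              stop(sprintf("trajectory point %d: %s", i,
                                           conditionMessage(e)), call. = FALSE)
                            })
  }
  colnames(angles) <- c("theta1", "theta2", "theta3")
  deltas <- diff(angles)
  colnames(deltas) <- c("dtheta1", "dtheta2", "dtheta3")
  list(angles = angles, deltas = deltas)
}

#' Write a joint command table to CSV
#'
#' Columns: step, x, y, z (ground frame, mm), theta1..3 (radians) and the
#' per-step increments dtheta1..3 (first step zero).
#'
#' @param points n x 3 matrix of ground-frame points.
#' @param joints a \code{\link{joint_deltas}} result for those points.
#' @param path output CSV file.
#' @export
write_joint_csv <- function(points, joints, path) {
  n <- nrow(points)
  df <- data.frame(step = seq_len(n),
                   x = points[, 1], y = points[, 2], z = points[, 3],
                   theta1 = joints$angles[, 1], theta2 = joints$angles[, 2],
                   theta3 = joints$angles[, 3],
                   dtheta1 = c(0, joints$deltas[, 1]),
                   dtheta2 = c(0, joints$deltas[, 2]),
                   dtheta3 = c(0, joints$deltas[, 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
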