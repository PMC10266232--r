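# End-to-end workflow: field image + crop boxes -> weed positions (mm) ->
# per-weeding-cycle swarm-optimized arch trajectory -> joint command tables.
# A weeding cycle is the end-effector motion from one weed position to the
# next; each cycle is clearance-checked against the crop nearest to its path.

#' Pipeline configuration
#'
#' One seed governs every stochastic stage (per-cycle swarm seeds are derived
#' from it).
#'
#' @param seg a \code{\link{seg_config}}.
#' @param calib a \code{\link{camera_calib}}.
#' @param params a \code{\link{trajectory_params}}.
#' @param swarm a \code{\link{swarm_config}}.
#' @param geometry a \code{\link{delta_geometry}}.
#' @param crop_height_mm assumed crop plant height h3 (mm); the camera looks
#'   straight down, so height cannot be measured from the image.
#' @param arm_origin_mm robot-frame position the weed visiting order starts
#'   from.
#' @param n_points discretization count for the joint command stream.
#' @param solve_joints solve inverse kinematics per cycle.
#' @param seed master seed.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seg = seg_config(), calib = camera_calib(),
                            params = trajectory_params(),
                            swarm = swarm_config(),
                            geometry = delta_geometry(),
                            crop_height_mm = 150,
                            arm_origin_mm = c(0, 0), n_points = 100,
                            solve_joints = TRUE, seed = 1) {
  stopifnot(inherits(seg, "seg_config"), inherits(calib, "camera_calib"),
            inherits(params, "trajectory_params"),
            inherits(swarm, "swarm_config"),
            inherits(geometry, "delta_geometry"))
  structure(list(seg = seg, calib = calib, params = params, swarm = swarm,
                 geometry = geometry, crop_height_mm = crop_height_mm,
                 arm_origin_mm = as.numeric(arm_origin_mm),
                 n_points = as.integer(n_points),
                 solve_joints = isTRUE(solve_joints),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Nearest-neighbour visiting order over robot-frame weed positions, starting
# from the arm origin.
order_weeds <- function(pos_mm, origin) {
  n <- nrow(pos_mm)
  if (n <= 1L) return(seq_len(n))
  left <- seq_len(n)
  cur <- origin
  out <- integer(0)
  while (length(left)) {
    d <- sqrt((pos_mm[left, 1] - cur[1])^2 + (pos_mm[left, 2] - cur[2])^2)
    k <- left[which.min(d)]
    out <- c(out, k)
    cur <- pos_mm[k, 1:2]
    left <- setdiff(left, k)
  }
  out
}

# Derive the crop obstacle for the cycle from the crop box nearest to the
# segment midpoint: cylinder radius = half the smaller box side in mm,
# standoff from the projection of the box centre onto the S->E axis.
cycle_obstacle <- function(s_mm, e_mm, crop_boxes, calib, crop_height_mm) {
  if (is.null(crop_boxes) || nrow(crop_boxes) == 0L)
    return(crop_obstacle(w1 = 1, w2 = 0, h3 = 0))
  ctr_px <- cbind((crop_boxes$xmin + crop_boxes$xmax) / 2,
                  (crop_boxes$ymin + crop_boxes$ymax) / 2)
  ctr_mm <- pixel_to_robot(ctr_px, calib)
  mid <- (s_mm + e_mm) / 2
  d <- sqrt((ctr_mm[, 1] - mid[1])^2 + (ctr_mm[, 2] - mid[2])^2)
  k <- which.min(d)
  w2 <- 0.5 * min(crop_boxes$xmax[k] - crop_boxes$xmin[k],
                  crop_boxes$ymax[k] - crop_boxes$ymin[k]) * calib$mm_per_px
  u_axis <- (e_mm - s_mm)[1:2]
  L <- vnorm(u_axis)
  center_u <- sum((ctr_mm[k, 1:2] - s_mm[1:2]) * u_axis / L)
  crop_obstacle(w1 = max(center_u - w2, 1), w2 = w2, h3 = crop_height_mm)
}

#' Run the full weeding pipeline on one image
#'
#' Segments weeds, maps their centres into the robot frame, orders them
#' nearest-neighbour from the arm origin, and plans one swarm-optimized arch
#' trajectory per consecutive weed pair, clearance-checked against the
#' nearest crop; optionally solves the joint command stream per cycle.
#'
#' @param img height x width x 3 image array in [0, 255].
#' @param crop_boxes data.frame of crop pixel boxes (xmin, ymin, xmax, ymax),
#'   or NULL when no crops are present.
#' @param cfg a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory: writes report JSON, per-cycle
#'   trajectory and joint CSVs, and an overlay PNG.
#' @return an object of class \code{weeding_run}: \code{weeds} (pixel and mm
#'   positions in visiting order), \code{cycles} (per consecutive pair:
#'   plan, clearance margin, feasibility, joints or the workspace failure
#'   message), \code{timings} (seconds per stage) and the config. No weeds
#'   yields an empty successful report; an infeasible cycle is recorded and
#'   the run continues.
#' @export
run_pipeline <- function(img, crop_boxes, cfg = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  seg <- segment_weeds(img, crop_boxes, cfg$seg)
  timings["segmentation"] <- tic() - t0

  weeds <- seg$weeds
  if (nrow(weeds) == 0L) {
    run <- structure(list(weeds = weeds, cycles = list(), timings = timings,
                          segmentation = seg, config = cfg),
                     class = "weeding_run")
    if (!is.null(out_dir)) write_run_outputs(run, img, out_dir)
    return(run)
  }
  pos_mm <- pixel_to_robot(as.matrix(weeds[, c("centroid_x", "centroid_y")]),
                           cfg$calib)
  ord <- order_weeds(pos_mm, cfg$arm_origin_mm)
  weeds <- weeds[ord, ]
  pos_mm <- pos_mm[ord, , drop = FALSE]
  weeds$x_mm <- pos_mm[, 1]; weeds$y_mm <- pos_mm[, 2]
  weeds$visit <- seq_len(nrow(weeds))

  cycles <- list()
  t0 <- tic()
  n_cycles <- max(0L, nrow(weeds) - 1L)
  for (ci in seq_len(n_cycles)) {
    s_mm <- pos_mm[ci, ]; e_mm <- pos_mm[ci + 1, ]
    obstacle <- cycle_obstacle(s_mm, e_mm, crop_boxes, cfg$calib,
                               cfg$crop_height_mm)
    scene <- spray_scene(s_mm, e_mm, obstacle, cfg$params)
    swarm <- cfg$swarm
    swarm$seed <- (cfg$seed * 1000L + ci) %% .Machine$integer.max
    plan <- withCallingHandlers(
      optimize_transition(scene, swarm),
      warning = function(w) invokeRestart("muffleWarning"))
    cyc <- list(from = ci, to = ci + 1, obstacle = obstacle, plan = plan,
                fitness = plan$fitness, margin = plan$clearance$min_margin,
                feasible = plan$feasible, joints = NULL, joint_error = NULL)
    if (cfg$solve_joints) {
      pts <- discretize_trajectory(plan$trajectory, cfg$n_points)
      cyc$points <- pts
      jd <- tryCatch(joint_deltas(pts, cfg$geometry), error = identity)
      if (inherits(jd, "error")) cyc$joint_error <- conditionMessage(jd)
      else cyc$joints <- jd
    }
    cycles[[ci]] <- cyc
  }
  timings["planning"] <- tic() - t0

  run <- structure(list(weeds = weeds, cycles = cycles, timings = timings,
                        segmentation = seg, config = cfg),
                   class = "weeding_run")
  if (!is.null(out_dir)) write_run_outputs(run, img, out_dir)
  run
}

#' @export
print.weeding_run <- function(x, ...) {
  cat(sprintf("Weeding run: %d weeds, %d cycles\n",
              nrow(x$weeds), length(x$cycles)))
  for (cyc in x$cycles) {
    cat(sprintf("  cycle %d->%d: length %.1f mm, margin %s mm, %s%s\n",
                cyc$from, cyc$to, cyc$fitness,
                if (is.finite(cyc$margin)) sprintf("%.1f", cyc$margin) else "inf",
                if (cyc$feasible) "feasible" else "INFEASIBLE",
                if (!is.null(cyc$joint_error)) " (joint solve failed)" else ""))
  }
  cat(sprintf("  timings (s): %s\n",
              paste(sprintf("%s %.2f", names(x$timings), x$timings),
                    collapse = ", ")))
  invisible(x)
}

draw_box_outline <- function(img, box, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- clamp(round(box[1]) + 1, 1, w); x1 <- clamp(round(box[3]), 1, w)
  y0 <- clamp(round(box[2]) + 1, 1, h); y1 <- clamp(round(box[4]), 1, h)
  for (ch in 1:3) {
    img[y0:y1, c(x0, x1), ch] <- col[ch]
    img[c(y0, y1), x0:x1, ch] <- col[ch]
  }
  img
}

write_run_outputs <- function(run, img, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    n_weeds = nrow(run$weeds),
    n_cycles = length(run$cycles),
    weeds = run$weeds,
    cycles = lapply(run$cycles, function(cyc) list(
      from = cyc$from, to = cyc$to,
      alpha = cyc$plan$alpha, beta = cyc$plan$beta,
      fitness_mm = cyc$fitness,
      margin_mm = if (is.finite(cyc$margin)) cyc$margin else "inf",
      feasible = cyc$feasible,
      joint_error = cyc$joint_error,
      history = cyc$plan$history
    )),
    timings_s = as.list(run$timings)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (cyc in run$cycles) {
    write_trajectory_csv(cyc$plan$trajectory,
                         file.path(out_dir, sprintf("cycle_%02d_trajectory.csv",
                                                    cyc$from)))
    if (!is.null(cyc$joints))
      write_joint_csv(cyc$points, cyc$joints,
                      file.path(out_dir, sprintf("cycle_%02d_joints.csv",
                                                 cyc$from)))
  }
  overlay <- img
  if (!is.null(run$segmentation$crop_boxes) &&
      nrow(run$segmentation$crop_boxes)) {
    for (i in seq_len(nrow(run$segmentation$crop_boxes)))
      overlay <- draw_box_outline(
        overlay, unlist(run$segmentation$crop_boxes[i, c("xmin", "ymin",
                                                         "xmax", "ymax")]),
        c(0, 0, 255))
  }
  if (nrow(run$weeds)) {
    for (i in seq_len(nrow(run$weeds)))
      overlay <- draw_box_outline(
        overlay, unlist(run$weeds[i, c("xmin", "ymin", "xmax", "ymax")]),
        c(255, 0, 0))
  }
  write_image_rgb(overlay, file.path(out_dir, "overlay.png"))
  invisible(out_dir)
}
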