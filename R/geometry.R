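#' World geometry of the preference aquarium
#'
#' Holds every coordinate convention of the apparatus: a 45 x 15 cm aquarium
#' filled to 11 cm, split along its length into three equal 15-cm compartments
#' (left / center / right); one 15 x 8.5 cm monitor flush against each short
#' wall with its top at the water surface; and an overhead color+depth camera
#' 40 cm above the water, streaming 640 x 360 frames.
#'
#' All world coordinates are tank-anchored centimetres: `x` runs along the
#' tank length (0 at the left monitor wall, 45 at the right), `y` across the
#' width, `z` up from the bottom (water surface at 11). Monitor coordinates
#' are pixels with `u` horizontal from each monitor's own left edge and `v`
#' down from the top (= water surface). Camera pixels have their origin at the
#' top-left of the frame, with the tank centered in a fixed-scale
#' sub-rectangle.
#'
#' @param tank_length,tank_width,water_depth tank extents, cm.
#' @param compartment_bounds the two x-boundaries splitting the tank into
#'   left/center/right compartments, cm.
#' @param camera_height_above_surface camera height over the water, m.
#' @param camera_frame camera frame size, px (width, height).
#' @param camera_span_cm world span covered by the full camera frame, cm
#'   (width, height); the tank is centered inside it at fixed scale.
#' @param monitor_size_cm physical monitor size, cm (width, height).
#' @param monitor_px_per_cm monitor pixel pitch, px/cm. The default 68.27
#'   (1024 px across 15 cm) makes the 350/150 px fleeing thresholds correspond
#'   to about 5.1 and 2.2 cm.
#' @return an object of class `world_geometry`.
#' @examples
#' g <- world_geometry()
#' g$monitor_frame      # 1024 x 580
#' @export
world_geometry <- function(tank_length = 45, tank_width = 15, water_depth = 11,
                           compartment_bounds = c(15, 30),
                           camera_height_above_surface = 0.40,
                           camera_frame = c(640, 360),
                           camera_span_cm = c(48, 27),
                           monitor_size_cm = c(15, 8.5),
                           monitor_px_per_cm = 68.27) {
  g <- list(tank_length = tank_length, tank_width = tank_width,
            water_depth = water_depth,
            compartment_bounds = compartment_bounds,
            camera_height_above_surface = camera_height_above_surface,
            camera_frame = as.integer(camera_frame),
            camera_span_cm = camera_span_cm,
            camera_px_per_cm = camera_frame[1] / camera_span_cm[1],
            monitor_size_cm = monitor_size_cm,
            monitor_px_per_cm = monitor_px_per_cm,
            monitor_frame = as.integer(round(monitor_size_cm * monitor_px_per_cm)))
  ext <- c(g$tank_length, g$tank_width, g$water_depth, g$camera_frame,
           g$monitor_size_cm, g$monitor_px_per_cm,
           g$camera_height_above_surface, g$camera_span_cm)
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    stop("all geometry extents must be strictly positive")
  }
  if (length(compartment_bounds) != 2 ||
      any(diff(c(0, compartment_bounds, tank_length)) <= 0)) {
    stop("compartment_bounds must be two increasing x-values inside the tank")
  }
  if (abs(g$camera_frame[1] / g$camera_span_cm[1] -
          g$camera_frame[2] / g$camera_span_cm[2]) > 1e-6) {
    stop("camera_span_cm must give the same px/cm scale on both axes")
  }
  structure(g, class = "world_geometry")
}

#' @export
print.world_geometry <- function(x, ...) {
  cat("<world_geometry>\n")
  cat(sprintf("  tank: %g x %g cm, water %g cm; compartments at x = %s cm\n",
              x$tank_length, x$tank_width, x$water_depth,
              paste(x$compartment_bounds, collapse = ", ")))
  cat(sprintf("  monitors: %g x %g cm = %d x %d px (%.2f px/cm)\n",
              x$monitor_size_cm[1], x$monitor_size_cm[2],
              x$monitor_frame[1], x$monitor_frame[2], x$monitor_px_per_cm))
  cat(sprintf("  camera: %d x %d px, %.2f px/cm, %.2f m above the surface\n",
              x$camera_frame[1], x$camera_frame[2], x$camera_px_per_cm,
              x$camera_height_above_surface))
  invisible(x)
}

# accept c(x, y, z) or an n x 3 matrix; always return an n x 3 matrix
.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("world points need 3 columns (x, y, z)")
  storage.mode(p) <- "double"
  p
}

.check_in_tank <- function(p, g, what = "point") {
  bad <- p[, 1] < 0 | p[, 1] > g$tank_length |
         p[, 2] < 0 | p[, 2] > g$tank_width |
         p[, 3] < 0 | p[, 3] > g$water_depth
  if (any(bad | !is.finite(p))) {
    stop(sprintf("%s outside the tank volume (x in [0,%g], y in [0,%g], z in [0,%g])",
                 what, g$tank_length, g$tank_width, g$water_depth))
  }
  invisible(TRUE)
}

#' Assign a world point to the left, center or right compartment
#'
#' The tank is split along its length into three equal compartments.
#' Intervals are half-open with the boundary points belonging to the
#' compartment to their right (`x = 15` is center, `x = 30` is right) and the
#' far wall closing the right compartment.
#'
#' @param p a world point `c(x, y, z)`, an n x 3 matrix of points, or a plain
#'   numeric vector of x-coordinates.
#' @param g a [world_geometry()].
#' @return character vector of `"left"`, `"center"`, `"right"`.
#' @export
assign_compartment <- function(p, g = world_geometry()) {
  x <- if (is.null(dim(p)) && length(p) != 3) as.numeric(p) else {
    pm <- .as_points(p); .check_in_tank(pm, g); pm[, 1]
  }
  if (any(!is.finite(x) | x < 0 | x > g$tank_length)) {
    stop("x-coordinate outside the tank length")
  }
  b <- g$compartment_bounds
  c("left", "center", "right")[1L + (x >= b[1]) + (x >= b[2])]
}

#' Project a world point onto a monitor plane
#'
#' Drops the along-tank coordinate and maps the cross-section onto the
#' monitor's pixel frame as if the experimental fish and the on-screen
#' stimulus swam in the same plane. The u-axis runs from each monitor's own
#' left edge, so the left and right projections of one point are mirror
#' images: `u_left + u_right = monitor width`.
#'
#' @param p world point(s); see [assign_compartment()].
#' @param side `"left"` or `"right"` monitor.
#' @param g a [world_geometry()].
#' @return numeric `c(u, v)` (or an n x 2 matrix), monitor px.
#' @export
project_to_monitor <- function(p, side = c("left", "right"),
                               g = world_geometry()) {
  side <- match.arg(side)
  pm <- .as_points(p)
  .check_in_tank(pm, g)
  s <- g$monitor_px_per_cm
  u <- if (side == "left") pm[, 2] * s else (g$tank_width - pm[, 2]) * s
  v <- (g$water_depth - pm[, 3]) * s
  out <- cbind(u = u, v = v)
  if (nrow(out) == 1) out[1, ] else out
}

#' Euclidean distance between two monitor points
#'
#' The head-to-head pixel distance that drives the pursuit controller
#' (Pythagorean distance in the monitor plane).
#'
#' @param a,b monitor points `c(u, v)`.
#' @return distance in px.
#' @export
monitor_head_distance <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite monitor point")
  sqrt(sum((a[1:2] - b[1:2])^2))
}

#' Map a world point into the camera frame
#'
#' Affine map of (x, y) into a centered sub-rectangle of the camera frame at
#' the fixed camera scale, plus the depth reading the camera would return for
#' the fish: camera height over the surface plus the submersion depth.
#'
#' @param p world point(s).
#' @param g a [world_geometry()].
#' @return `c(px, py, depth_m)` (or an n x 3 matrix): continuous camera pixel
#'   coordinates and depth in metres.
#' @export
world_to_camera_px <- function(p, g = world_geometry()) {
  pm <- .as_points(p)
  .check_in_tank(pm, g)
  s <- g$camera_px_per_cm
  px <- (pm[, 1] - g$tank_length / 2) * s + g$camera_frame[1] / 2
  py <- (pm[, 2] - g$tank_width / 2) * s + g$camera_frame[2] / 2
  depth <- g$camera_height_above_surface + (g$water_depth - pm[, 3]) / 100
  out <- cbind(px = px, py = py, depth_m = depth)
  if (nrow(out) == 1) out[1, ] else out
}

#' Invert the camera mapping back to tank coordinates
#'
#' Exact inverse of [world_to_camera_px()] on its image.
#'
#' @param px,py continuous camera pixel coordinates.
#' @param depth_m camera depth reading, m.
#' @param g a [world_geometry()].
#' @return world point(s) `c(x, y, z)` in cm.
#' @export
camera_px_to_world <- function(px, py, depth_m, g = world_geometry()) {
  s <- g$camera_px_per_cm
  x <- (px - g$camera_frame[1] / 2) / s + g$tank_length / 2
  y <- (py - g$camera_frame[2] / 2) / s + g$tank_width / 2
  z <- g$water_depth - (depth_m - g$camera_height_above_surface) * 100
  out <- cbind(x = x, y = y, z = z)
  if (nrow(out) == 1) out[1, ] else out
}
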