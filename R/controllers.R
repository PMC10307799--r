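#' Stimulus-controller parameters
#'
#' Frame-rate and the constants of the five motion programs. Defaults are the
#' apparatus values: 30 updates per second; pursuit onset delayed until the
#' head-to-head distance exceeds 16 px; speed equal to that distance divided
#' by 650 (px per ms, so the per-frame step is `d * dt * 1000 / 650`, about
#' d/19.5); idle jitter of 0..2 px; fleeing triggered when the heads come
#' within 350 px horizontally and 150 px vertically (inclusive); yaw limited
#' to \[0, 180\] degrees (head left / head right) and pitch to \[-30, 30\].
#'
#' @param dt frame interval, s.
#' @param deadband_px pursuit deadband, px (strict: motion only when the
#'   distance is greater than this).
#' @param velocity_divisor distance-to-speed divisor of the pursuit law.
#' @param velocity_time_unit time unit of the pursuit speed; only
#'   `"ms"` (px per millisecond) is implemented, giving life-like speeds.
#' @param jitter_max_px largest idle offset of the motionless program, px.
#' @param flee_dx_px,flee_dy_px fleeing trigger thresholds, px.
#' @param yaw_limits,pitch_limits animation rotation limits, degrees.
#' @param flee_teleport if `TRUE` the fleeing relocation jumps instead of
#'   travelling under the pursuit velocity law.
#' @param flee_arrive_tol_px distance at which a relocation counts as arrived, px.
#' @return an object of class `controller_params`.
#' @export
controller_params <- function(dt = 1 / 30, deadband_px = 16,
                              velocity_divisor = 650,
                              velocity_time_unit = "ms",
                              jitter_max_px = 2,
                              flee_dx_px = 350, flee_dy_px = 150,
                              yaw_limits = c(0, 180),
                              pitch_limits = c(-30, 30),
                              flee_teleport = FALSE,
                              flee_arrive_tol_px = 1) {
  velocity_time_unit <- match.arg(velocity_time_unit, "ms")
  stopifnot(dt > 0, deadband_px > 0, velocity_divisor > 0, jitter_max_px >= 0,
            flee_dx_px > 0, flee_dy_px > 0, flee_arrive_tol_px > 0,
            diff(yaw_limits) > 0, diff(pitch_limits) > 0)
  structure(list(dt = dt, deadband_px = deadband_px,
                 velocity_divisor = velocity_divisor,
                 velocity_time_unit = velocity_time_unit,
                 jitter_max_px = jitter_max_px,
                 flee_dx_px = flee_dx_px, flee_dy_px = flee_dy_px,
                 yaw_limits = yaw_limits, pitch_limits = pitch_limits,
                 flee_teleport = flee_teleport,
                 flee_arrive_tol_px = flee_arrive_tol_px),
            class = "controller_params")
}

.ctrl_vec <- function(p, g) {
  c(p$dt, p$deadband_px, p$velocity_divisor, p$jitter_max_px,
    p$flee_dx_px, p$flee_dy_px, p$yaw_limits, p$pitch_limits,
    as.numeric(p$flee_teleport), p$flee_arrive_tol_px)
}

#' Stimulus state on one monitor
#'
#' @param mode motion-type name, see [motion_types()].
#' @param u,v on-screen position, monitor px.
#' @param yaw,pitch orientation, degrees (yaw 0 = head left, 180 = head right).
#' @param visible whether a stimulus fish is displayed.
#' @param relocation_target optional `c(u, v)` of an in-progress fleeing
#'   relocation; `NULL` otherwise.
#' @param g a [world_geometry()] used to default the position to the monitor
#'   center.
#' @return an object of class `stimulus_state`.
#' @export
stimulus_state <- function(mode = "absent", u = NULL, v = NULL,
                           yaw = 0, pitch = 0, visible = mode != "absent",
                           relocation_target = NULL, g = world_geometry()) {
  motion_code(mode)
  if (is.null(u)) u <- g$monitor_frame[1] / 2
  if (is.null(v)) v <- g$monitor_frame[2] / 2
  if (u < 0 || u > g$monitor_frame[1] || v < 0 || v > g$monitor_frame[2]) {
    stop("stimulus position outside the monitor frame")
  }
  if (yaw < 0 || yaw > 180 || pitch < -30 || pitch > 30) {
    stop("orientation outside the animation limits")
  }
  if (!is.null(relocation_target) && mode != "fleeing") {
    stop("relocation_target is only meaningful for the fleeing program")
  }
  structure(list(mode = mode, u = u, v = v, yaw = yaw, pitch = pitch,
                 visible = visible, relocation_target = relocation_target),
            class = "stimulus_state")
}

#' @export
print.stimulus_state <- function(x, ...) {
  cat(sprintf("<stimulus_state> %s%s at (%.1f, %.1f) px, yaw %g, pitch %g\n",
              x$mode, if (x$visible) "" else " (hidden)", x$u, x$v,
              x$yaw, x$pitch))
  invisible(x)
}

#' Per-frame stimulus updates
#'
#' One frame of each motion program, applied to a [stimulus_state()].
#' `update_motionless()` offsets the fish 0..2 px left or right of the monitor
#' center (an offset from center, not a random walk, so it never drifts).
#' `update_chasing()` moves toward the target under the proportional velocity
#' law with the 16 px deadband and orients the head toward the target.
#' `update_flipped()` is chasing of the left/right mirrored target.
#' `update_fleeing()` relocates to a uniform random point on the opposite
#' monitor half when the target comes within the trigger box, travelling under
#' the pursuit velocity law; new triggers are ignored while a relocation is in
#' progress. `update_independent()` copies the state from a playback track.
#'
#' Random draws come from the R RNG, so `set.seed()` makes sessions exactly
#' reproducible.
#'
#' @param s a [stimulus_state()] of the matching mode.
#' @param target the projected head of the experimental fish on this monitor,
#'   `c(u, v)` px.
#' @param p [controller_params()].
#' @param g [world_geometry()].
#' @param track a `playback_track` (see [record_playback()]).
#' @param frame_in_period 0-based frame index into the track.
#' @return the updated `stimulus_state`.
#' @name stimulus-updates
NULL

#' @rdname stimulus-updates
#' @export
update_motionless <- function(s, p = controller_params(), g = world_geometry()) {
  stopifnot(s$mode == "motionless")
  uv <- cpp_motionless_step(g$monitor_frame[1] / 2, g$monitor_frame[2] / 2,
                            p$jitter_max_px)
  s$u <- uv[1]; s$v <- uv[2]
  s$yaw <- p$yaw_limits[1]; s$pitch <- 0
  s
}

#' @rdname stimulus-updates
#' @export
update_chasing <- function(s, target, p = controller_params(),
                           g = world_geometry()) {
  stopifnot(s$mode %in% c("chasing", "flipped"))
  res <- cpp_chase_step(s$u, s$v, target[1], target[2], p$dt, p$deadband_px,
                        p$velocity_divisor, g$monitor_frame[1],
                        g$monitor_frame[2], TRUE)
  s$u <- res[1]; s$v <- res[2]
  op <- orient_toward(s, target, p)
  s$yaw <- op[1]; s$pitch <- op[2]
  s
}

#' @rdname stimulus-updates
#' @export
update_flipped <- function(s, target, p = controller_params(),
                           g = world_geometry()) {
  stopifnot(s$mode == "flipped")
  mirrored <- c(g$monitor_frame[1] - target[1], target[2])
  update_chasing(s, mirrored, p, g)
}

#' @rdname stimulus-updates
#' @export
update_fleeing <- function(s, target, p = controller_params(),
                           g = world_geometry()) {
  stopifnot(s$mode == "fleeing")
  rel <- !is.null(s$relocation_target)
  ru <- if (rel) s$relocation_target[1] else 0
  rv <- if (rel) s$relocation_target[2] else 0
  res <- cpp_flee_step(s$u, s$v, target[1], target[2], rel, ru, rv,
                       p$dt, p$velocity_divisor, p$flee_dx_px, p$flee_dy_px,
                       g$monitor_frame[1], g$monitor_frame[2],
                       p$flee_teleport, p$flee_arrive_tol_px)
  s$u <- res[1]; s$v <- res[2]
  s$relocation_target <- if (res[3] > 0) c(res[4], res[5]) else NULL
  op <- orient_toward(s, target, p)
  s$yaw <- op[1]; s$pitch <- op[2]
  s
}

#' @rdname stimulus-updates
#' @export
update_independent <- function(s, track, frame_in_period) {
  stopifnot(s$mode == "independent")
  n <- nrow(track$frames)
  if (frame_in_period < 0 || frame_in_period >= n) {
    stop("frame_in_period outside the playback track (scheduling error)")
  }
  row <- track$frames[frame_in_period + 1L, ]
  s$u <- row$u; s$v <- row$v; s$yaw <- row$yaw; s$pitch <- row$pitch
  s
}

#' Orient the stimulus head toward a target
#'
#' Yaw snaps to 0 (head left) or 180 (head right) depending on where the
#' target lies, unchanged on a tie; pitch is the elevation of the target in
#' the monitor plane clamped to the animation limits.
#'
#' @inheritParams stimulus-updates
#' @return `c(yaw, pitch)` degrees.
#' @export
orient_toward <- function(s, target, p = controller_params()) {
  cpp_orient_toward(s$u, s$v, target[1], target[2], s$yaw, s$pitch,
                    p$yaw_limits[1], p$yaw_limits[2],
                    p$pitch_limits[1], p$pitch_limits[2])
}

#' Extract a playback track from a logged session
#'
#' Cuts the stimulus trajectory of one full stimulus period out of a
#' [simulate_session()] log, producing the frame-by-frame track that the
#' `independent` program replays. Replaying the track reproduces the logged
#' stimulus positions exactly.
#'
#' @param log a `session_log`.
#' @param side `"left"` or `"right"`: which monitor's stimulus to extract.
#' @return an object of class `playback_track` with a `frames` data frame
#'   (`frame`, `u`, `v`, `yaw`, `pitch`) covering the stimulus period.
#' @export
record_playback <- function(log, side = c("left", "right")) {
  side <- match.arg(side)
  fr <- log$frames
  vis <- fr[[paste0(side, "_visible")]]
  idx <- which(vis)
  need <- log$meta$n_frames / 4   # one full period
  if (length(idx) < need) {
    stop("log does not contain a full stimulus period on the ", side, " monitor")
  }
  pre <- paste0(side, "_")
  frames <- data.frame(frame = seq_len(length(idx)) - 1L,
                       u = fr[[paste0(pre, "u")]][idx],
                       v = fr[[paste0(pre, "v")]][idx],
                       yaw = fr[[paste0(pre, "yaw")]][idx],
                       pitch = fr[[paste0(pre, "pitch")]][idx])
  structure(list(frames = frames,
                 source = list(side = side, seed = log$meta$seed,
                               left_mode = log$meta$left_mode,
                               right_mode = log$meta$right_mode)),
            class = "playback_track")
}

#' @export
print.playback_track <- function(x, ...) {
  cat(sprintf("<playback_track> %d frames from a %s-monitor %s stimulus\n",
              nrow(x$frames), x$source$side, x$source$left_mode))
  invisible(x)
}

#' Write / read playback tracks
#'
#' Tracks are stored as plain CSV (`frame,u,v,yaw,pitch`) with a JSON sidecar
#' recording the source session.
#'
#' @param track a `playback_track`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `write_playback_track()` returns `path` invisibly;
#'   `read_playback_track()` returns the `playback_track`.
#' @export
write_playback_track <- function(track, path) {
  write.csv(track$frames, path, row.names = FALSE)
  jsonlite::write_json(track$source, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_playback_track
#' @export
read_playback_track <- function(path) {
  frames <- read.csv(path)
  side <- paste0(path, ".json")
  src <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
         else list()
  structure(list(frames = frames, source = src), class = "playback_track")
}

#' Generate the fixed set of playback tracks for the independent program
#'
#' Simulates chasing sessions with fresh agent seeds (fish that never serve in
#' the experiment) and records their stimulus-period trajectories. The same
#' tracks, in the same order, are replayed for every fish.
#'
#' @param n number of tracks.
#' @param seed base seed for the donor sessions.
#' @param g,ctrl,agent world, controller, and agent parameters.
#' @param n_frames session length in frames (default a full 20-min session).
#' @return list of `playback_track` objects.
#' @export
make_playback_tracks <- function(n = 4, seed = 20230628,
                                 g = world_geometry(),
                                 ctrl = controller_params(),
                                 agent = agent_params(),
                                 n_frames = 36000L) {
  lapply(seq_len(n), function(i) {
    log <- simulate_session(left_mode = "chasing", right_mode = "absent",
                            seed = seed + i, g = g, ctrl = ctrl, agent = agent,
                            n_frames = n_frames)
    record_playback(log, "left")
  })
}
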