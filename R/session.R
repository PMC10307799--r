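#' Simulate one closed-loop session
#'
#' Runs a full 20-min session at 30 FPS: four equal periods (presession and
#' Periods 1-3) with the stimulus monitors blank except during Period 2, when
#' each monitor runs its assigned motion program. The loop is closed every
#' frame: the controllers receive the fish's current head position projected
#' onto their monitor, and the agent steps against the fresh stimulus states.
#'
#' Two engines produce bit-identical logs: the compiled loop (`"cpp"`,
#' default) and a frame-by-frame R loop (`"r"`) over the same single-step
#' primitives, kept as a cross-checking reference.
#'
#' @param left_mode,right_mode motion-type names for the two monitors.
#' @param seed integer seed; every random draw in the session flows from it.
#' @param g,ctrl,agent world geometry, controller and agent parameters.
#' @param n_frames session length in frames; must be divisible by 4.
#' @param visible_frames 0-based `[start, end)` frame window during which
#'   stimuli are displayed; default Period 2 (the third quarter).
#' @param left_track,right_track `playback_track` objects, required when the
#'   corresponding mode is `"independent"`.
#' @param engine `"cpp"` or `"r"`.
#' @return an object of class `session_log`: a list with `meta` (all
#'   parameters and the seed) and `frames`, one row per frame with the fish
#'   head/body/tail world coordinates, validity flag, and both stimulus
#'   states (u, v, yaw, pitch, visible) plus the period label (0 =
#'   presession, 1-3).
#' @examples
#' log <- simulate_session("chasing", "absent", seed = 1, n_frames = 1200)
#' table(log$frames$period)
#' @export
simulate_session <- function(left_mode = "absent", right_mode = "absent",
                             seed = 1L, g = world_geometry(),
                             ctrl = controller_params(),
                             agent = agent_params(),
                             n_frames = 36000L, visible_frames = NULL,
                             left_track = NULL, right_track = NULL,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n_frames <- as.integer(n_frames)
  if (n_frames <= 0 || n_frames %% 4L != 0L) {
    stop("n_frames must be a positive multiple of 4 (four equal periods)")
  }
  lcode <- motion_code(left_mode)
  rcode <- motion_code(right_mode)
  q <- n_frames %/% 4L
  if (is.null(visible_frames)) visible_frames <- c(2L * q, 3L * q)
  visible_frames <- as.integer(visible_frames)

  trmat <- function(track, mode) {
    if (mode != "independent") return(matrix(0, 0, 4))
    if (is.null(track)) stop("an 'independent' monitor needs a playback track")
    as.matrix(track$frames[, c("u", "v", "yaw", "pitch")])
  }
  ltr <- trmat(left_track, left_mode)
  rtr <- trmat(right_track, right_mode)

  kap <- function(mode) unname(agent$attraction[[mode]])

  set.seed(seed)
  ang <- runif(1, 0, 2 * pi)
  start_head <- c(g$tank_length / 2, g$tank_width / 2, g$water_depth / 2)
  start_vel <- agent$mean_speed * c(cos(ang), sin(ang), 0)

  geomv <- c(g$tank_length, g$tank_width, g$water_depth,
             g$monitor_frame[1], g$monitor_frame[2], g$monitor_px_per_cm)
  ctrlv <- .ctrl_vec(ctrl, g)
  agentv <- c(agent$mean_speed, agent$velocity_relaxation, agent$noise_sd,
              agent$wall_margin, agent$wall_repulsion,
              kap(left_mode), kap(right_mode),
              agent$motion_salience_bonus, agent$salience_frames)

  raw <- if (engine == "cpp") {
    cpp_simulate_session(n_frames, visible_frames[1], visible_frames[2],
                         lcode, rcode, ltr, rtr, geomv, ctrlv, agentv,
                         start_head, start_vel)
  } else {
    .simulate_session_r(n_frames, visible_frames, left_mode, right_mode,
                        ltr, rtr, g, ctrl, agent, start_head, start_vel)
  }

  bt <- .body_tail(raw$head, raw$vel, g)
  frame <- seq_len(n_frames) - 1L
  frames <- data.frame(
    frame = frame, t = frame * ctrl$dt,
    period = (frame %/% q),
    head_x = raw$head[, 1], head_y = raw$head[, 2], head_z = raw$head[, 3],
    body_x = bt$body[, 1], body_y = bt$body[, 2], body_z = bt$body[, 3],
    tail_x = bt$tail[, 1], tail_y = bt$tail[, 2], tail_z = bt$tail[, 3],
    valid = TRUE,
    left_mode = left_mode, left_u = raw$left[, 1], left_v = raw$left[, 2],
    left_yaw = raw$left[, 3], left_pitch = raw$left[, 4],
    left_visible = raw$left[, 5] > 0,
    right_mode = right_mode, right_u = raw$right[, 1],
    right_v = raw$right[, 2], right_yaw = raw$right[, 3],
    right_pitch = raw$right[, 4], right_visible = raw$right[, 5] > 0)

  structure(list(
    meta = list(seed = seed, left_mode = left_mode, right_mode = right_mode,
                n_frames = n_frames, visible_frames = visible_frames,
                dt = ctrl$dt, fps = 1 / ctrl$dt, engine = engine,
                geometry = unclass(g), controller = unclass(ctrl),
                agent = unclass(agent)),
    frames = frames), class = "session_log")
}

# reference engine: the same closed loop assembled from the single-step
# primitives, consuming the identical RNG stream as the compiled loop
.simulate_session_r <- function(n_frames, visible_frames, left_mode,
                                right_mode, ltr, rtr, g, ctrl, agent,
                                start_head, start_vel) {
  mW <- g$monitor_frame[1]; mH <- g$monitor_frame[2]
  s <- g$monitor_px_per_cm
  head <- matrix(0, n_frames, 3); vel <- matrix(0, n_frames, 3)
  stim <- list(left = matrix(NA_real_, n_frames, 7),
               right = matrix(NA_real_, n_frames, 7))
  modes <- c(left = left_mode, right = right_mode)
  tracks <- list(left = ltr, right = rtr)
  st <- list(left = list(u = mW / 2, v = mH / 2, yaw = ctrl$yaw_limits[1],
                         pitch = 0, reloc = FALSE, ru = 0, rv = 0,
                         last_moved = -1e6),
             right = list(u = mW / 2, v = mH / 2, yaw = ctrl$yaw_limits[1],
                          pitch = 0, reloc = FALSE, ru = 0, rv = 0,
                          last_moved = -1e6))
  h <- start_head; v <- start_vel
  keff <- c(0, 0)
  for (t0 in seq_len(n_frames) - 1L) {
    head[t0 + 1L, ] <- h; vel[t0 + 1L, ] <- v
    in_window <- t0 >= visible_frames[1] && t0 < visible_frames[2]
    for (i in 1:2) {
      sd_ <- c("left", "right")[i]
      mode <- modes[[sd_]]
      x <- st[[sd_]]
      visible <- in_window && mode != "absent"
      tu <- if (i == 1) h[2] * s else (g$tank_width - h[2]) * s
      tv <- (g$water_depth - h[3]) * s
      moved <- FALSE
      if (visible) {
        if (mode == "motionless") {
          pu <- x$u
          uv <- cpp_motionless_step(mW / 2, mH / 2, ctrl$jitter_max_px)
          x$u <- uv[1]; x$v <- uv[2]
          x$yaw <- ctrl$yaw_limits[1]; x$pitch <- 0
          moved <- x$u != pu
        } else if (mode %in% c("chasing", "flipped")) {
          ttu <- if (mode == "flipped") mW - tu else tu
          res <- cpp_chase_step(x$u, x$v, ttu, tv, ctrl$dt, ctrl$deadband_px,
                                ctrl$velocity_divisor, mW, mH, TRUE)
          moved <- res[3] > 0
          x$u <- res[1]; x$v <- res[2]
          op <- cpp_orient_toward(x$u, x$v, ttu, tv, x$yaw, x$pitch,
                                  ctrl$yaw_limits[1], ctrl$yaw_limits[2],
                                  ctrl$pitch_limits[1], ctrl$pitch_limits[2])
          x$yaw <- op[1]; x$pitch <- op[2]
        } else if (mode == "fleeing") {
          res <- cpp_flee_step(x$u, x$v, tu, tv, x$reloc, x$ru, x$rv,
                               ctrl$dt, ctrl$velocity_divisor,
                               ctrl$flee_dx_px, ctrl$flee_dy_px, mW, mH,
                               ctrl$flee_teleport, ctrl$flee_arrive_tol_px)
          x$u <- res[1]; x$v <- res[2]; x$reloc <- res[3] > 0
          x$ru <- res[4]; x$rv <- res[5]
          moved <- res[6] > 0
          op <- cpp_orient_toward(x$u, x$v, tu, tv, x$yaw, x$pitch,
                                  ctrl$yaw_limits[1], ctrl$yaw_limits[2],
                                  ctrl$pitch_limits[1], ctrl$pitch_limits[2])
          x$yaw <- op[1]; x$pitch <- op[2]
        } else if (mode == "independent") {
          k <- t0 - visible_frames[1] + 1L
          pu <- x$u; pv <- x$v
          x$u <- tracks[[sd_]][k, 1]; x$v <- tracks[[sd_]][k, 2]
          x$yaw <- tracks[[sd_]][k, 3]; x$pitch <- tracks[[sd_]][k, 4]
          moved <- x$u != pu || x$v != pv
        }
        if (moved) x$last_moved <- t0
        salient <- t0 - x$last_moved < agent$salience_frames
        keff[i] <- unname(agent$attraction[[mode]]) *
          if (salient) agent$motion_salience_bonus else 1
      } else {
        x$u <- mW / 2; x$v <- mH / 2
        x$yaw <- ctrl$yaw_limits[1]; x$pitch <- 0
        x$reloc <- FALSE; x$last_moved <- -1e6
        keff[i] <- 0
      }
      stim[[sd_]][t0 + 1L, ] <- c(x$u, x$v, x$yaw, x$pitch,
                                  as.numeric(visible),
                                  if (x$reloc) x$ru else NA_real_,
                                  if (x$reloc) x$rv else NA_real_)
      st[[sd_]] <- x
    }
    drift <- cpp_attraction_drift(h, keff[1], keff[2], g$tank_length,
                                  g$tank_width, g$water_depth)
    res <- cpp_agent_step(h, v, drift, agent$mean_speed,
                          agent$velocity_relaxation, agent$noise_sd,
                          agent$wall_margin, agent$wall_repulsion,
                          c(g$tank_length, g$tank_width, g$water_depth),
                          ctrl$dt)
    h <- res[1:3]; v <- res[4:6]
  }
  list(head = head, vel = vel, left = stim$left, right = stim$right)
}

#' @export
print.session_log <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<session_log> %s vs %s | %d frames (%.1f min at %g FPS), seed %s\n",
              m$left_mode, m$right_mode, m$n_frames,
              m$n_frames * m$dt / 60, m$fps, format(m$seed)))
  cat(sprintf("  stimuli displayed in frames [%d, %d)\n",
              m$visible_frames[1], m$visible_frames[2]))
  invisible(x)
}

#' @export
summary.session_log <- function(object, ...) {
  s <- session_side_times(object)
  cat("time in compartments (s) per period:\n")
  print(s, row.names = FALSE)
  invisible(s)
}

#' Time spent in each compartment during one period
#'
#' Scores the per-frame head position into the left/center/right compartments
#' (1/30 s per frame). Frames carried forward after a tracking miss count at
#' the last valid position, which is already how they are stored.
#'
#' @param log a `session_log`.
#' @param period 1, 2 or 3.
#' @param g geometry; defaults to the one stored in the log.
#' @return named numeric `c(left, center, right)` in seconds.
#' @export
time_in_compartments <- function(log, period, g = NULL) {
  stopifnot(length(period) == 1, period %in% 1:3)
  if (is.null(g)) g <- do.call(world_geometry,
                               log$meta$geometry[names(formals(world_geometry))[
                                 names(formals(world_geometry)) %in%
                                   names(log$meta$geometry)]])
  fr <- log$frames[log$frames$period == period, ]
  if (nrow(fr) == 0) stop("period ", period, " is empty in this log")
  comp <- assign_compartment(fr$head_x, g)
  n <- c(left = sum(comp == "left"), center = sum(comp == "center"),
         right = sum(comp == "right"))
  n * log$meta$dt
}

#' Compartment times for all periods of a session
#'
#' @param log a `session_log`.
#' @return data frame with one row per period (1-3) and columns
#'   `left_s`, `center_s`, `right_s`.
#' @export
session_side_times <- function(log) {
  out <- do.call(rbind, lapply(1:3, function(p) {
    tt <- time_in_compartments(log, p)
    data.frame(period = p, left_s = tt[["left"]], center_s = tt[["center"]],
               right_s = tt[["right"]])
  }))
  rownames(out) <- NULL
  out
}
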