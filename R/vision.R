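#' Tracker parameters for the synthetic vision stack
#'
#' The classical stand-in for the trained detector pair: an intensity
#' threshold + connected-components blob detector plays the object detector's
#' role (bounding box), and principal-axis keypoint extraction with the head
#' at the darker end plays the pose estimator's role. Imperfection is
#' injected explicitly: Gaussian keypoint jitter and a per-frame miss
#' probability. The detector-gating contract is kept exactly: keypoints are
#' valid only when every one lies inside the bounding box.
#'
#' @param intensity_threshold pixels darker than this (0-255) are foreground.
#' @param min_blob_px smallest connected component accepted as a fish.
#' @param miss_probability per-frame probability that the keypoints are lost.
#' @param keypoint_jitter_px Gaussian sd added to each keypoint coordinate, px.
#' @param head_intensity_cut intensity below which pixels count as the dark
#'   head disk.
#' @param bbox_pad_px padding added around the tight blob bounding box, px.
#' @return an object of class `tracker_params`.
#' @export
tracker_params <- function(intensity_threshold = 160, min_blob_px = 30,
                           miss_probability = 0, keypoint_jitter_px = 0,
                           head_intensity_cut = 55, bbox_pad_px = 2) {
  stopifnot(intensity_threshold >= 0, intensity_threshold <= 255,
            min_blob_px >= 1, miss_probability >= 0, miss_probability <= 1,
            keypoint_jitter_px >= 0)
  structure(list(intensity_threshold = intensity_threshold,
                 min_blob_px = min_blob_px,
                 miss_probability = miss_probability,
                 keypoint_jitter_px = keypoint_jitter_px,
                 head_intensity_cut = head_intensity_cut,
                 bbox_pad_px = bbox_pad_px),
            class = "tracker_params")
}

#' Render a synthetic overhead color + depth frame
#'
#' White background; the fish drawn as a dark ellipse (body length along the
#' heading) with a darker head disk, in the camera's pixel frame. The depth
#' raster is constant at the surface depth except over fish pixels, where it
#' reads the camera-to-fish distance.
#'
#' Matrices are indexed `[px_x, px_y]` with pixel (i, j) centered at
#' continuous camera coordinates (i - 0.5, j - 0.5).
#'
#' @param fish list with `head`, `body` (world cm) and optionally `tail`;
#'   rows of a `session_log` work via [fish_state_at()].
#' @param g a [world_geometry()].
#' @param body_intensity,head_intensity ellipse and head-disk gray levels.
#' @return list with `color` (0-255 matrix) and `depth` (metres matrix).
#' @export
render_frames <- function(fish, g = world_geometry(),
                          body_intensity = 90, head_intensity = 30) {
  W <- g$camera_frame[1]; H <- g$camera_frame[2]
  color <- matrix(255, W, H)
  depth <- matrix(g$camera_height_above_surface, W, H)
  hc <- world_to_camera_px(fish$head, g)
  bc <- world_to_camera_px(fish$body, g)
  s <- g$camera_px_per_cm
  len <- if (!is.null(fish$length_cm)) fish$length_cm else 3
  a <- len / 2 * s                       # semi-major, px
  b <- max(0.35 * s, 2)                  # semi-minor, px
  dirv <- hc[1:2] - bc[1:2]
  nv <- sqrt(sum(dirv^2))
  dirv <- if (nv > 1e-9) dirv / nv else c(1, 0)

  paint <- function(cx, cy, mask_fun, intensity, z_cm) {
    rad <- a + 2
    xs <- max(1, floor(cx - rad)):min(W, ceiling(cx + rad))
    ys <- max(1, floor(cy - rad)):min(H, ceiling(cy + rad))
    if (!length(xs) || !length(ys)) return(invisible())
    px <- outer(xs - 0.5, rep(1, length(ys)))
    py <- outer(rep(1, length(xs)), ys - 0.5)
    m <- mask_fun(px - cx, py - cy)
    sub <- color[xs, ys, drop = FALSE]
    sub[m] <- pmin(sub[m], intensity)
    color[xs, ys] <<- sub
    dsub <- depth[xs, ys, drop = FALSE]
    dsub[m] <- g$camera_height_above_surface + (g$water_depth - z_cm) / 100
    depth[xs, ys] <<- dsub
  }
  # body ellipse centered at the body keypoint, long axis along the heading
  paint(bc[1], bc[2], function(dx, dy) {
    lon <- dx * dirv[1] + dy * dirv[2]
    lat <- -dx * dirv[2] + dy * dirv[1]
    (lon / a)^2 + (lat / b)^2 <= 1
  }, body_intensity, fish$body[3])
  # darker head disk
  hr <- max(0.35 * s, 2)
  paint(hc[1], hc[2], function(dx, dy) dx^2 + dy^2 <= hr^2,
        head_intensity, fish$head[3])
  list(color = color, depth = depth)
}

#' Fish state at one frame of a session log
#'
#' @param log a `session_log`.
#' @param frame 0-based frame index.
#' @return list with `head`, `body`, `tail` world points and `length_cm`.
#' @export
fish_state_at <- function(log, frame) {
  r <- log$frames[log$frames$frame == frame, ]
  if (nrow(r) != 1) stop("frame ", frame, " not in log")
  list(head = c(r$head_x, r$head_y, r$head_z),
       body = c(r$body_x, r$body_y, r$body_z),
       tail = c(r$tail_x, r$tail_y, r$tail_z),
       length_cm = log$meta$agent$fish_length_cm)
}

#' Detect the fish bounding box in a color frame
#'
#' Thresholds the frame, labels connected components, and returns the tight
#' bounding box of the largest component (padded by 2 px) if it reaches
#' `min_blob_px`; `NULL` otherwise.
#'
#' @param color camera color matrix from [render_frames()].
#' @param tp [tracker_params()].
#' @return list `(x0, x1, y0, y1)` in continuous camera px, or `NULL`.
#' @export
detect_bbox <- function(color, tp = tracker_params()) {
  fg <- color < tp$intensity_threshold
  if (!any(fg)) return(NULL)
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(lab[lab > 0])
  if (!length(tab) || max(tab) < tp$min_blob_px) return(NULL)
  best <- which.max(tab)
  idx <- which(lab == best, arr.ind = TRUE)
  pad <- tp$bbox_pad_px
  # pixel (i, j) spans [i-1, i] x [j-1, j] in continuous coordinates
  list(x0 = max(0, min(idx[, 1]) - 1 - pad),
       x1 = min(nrow(color), max(idx[, 1]) + pad),
       y0 = max(0, min(idx[, 2]) - 1 - pad),
       y1 = min(ncol(color), max(idx[, 2]) + pad))
}

#' Detect head/body/tail keypoints in a color frame
#'
#' Classical pose stand-in: the blob's principal axis gives the body axis;
#' the darker end is the head (refined as the centroid of the head-disk
#' pixels), the opposite end is the tail, and the blob centroid is the body.
#' Gaussian jitter and per-frame dropout are injected per `tp`.
#'
#' @param color camera color matrix.
#' @param tp [tracker_params()].
#' @return list with `head`, `body`, `tail` continuous camera-px points, or
#'   `NULL` on a (possibly injected) miss.
#' @export
detect_keypoints <- function(color, tp = tracker_params()) {
  if (tp$miss_probability > 0 && runif(1) < tp$miss_probability) return(NULL)
  fg <- which(color < tp$intensity_threshold, arr.ind = TRUE)
  if (nrow(fg) < tp$min_blob_px) return(NULL)
  pts <- cbind(fg[, 1] - 0.5, fg[, 2] - 0.5)
  ctr <- colMeans(pts)
  cc <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  ax <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  proj <- sweep(pts, 2, ctr) %*% ax
  qs <- stats::quantile(proj, c(0.12, 0.88))
  end_lo <- proj <= qs[1]; end_hi <- proj >= qs[2]
  ints <- color[fg]
  head_end_hi <- mean(ints[end_hi]) < mean(ints[end_lo])
  dark <- ints <= tp$head_intensity_cut
  hpt <- if (any(dark)) colMeans(pts[dark, , drop = FALSE]) else {
    colMeans(pts[if (head_end_hi) end_hi else end_lo, , drop = FALSE])
  }
  tpt <- colMeans(pts[if (head_end_hi) end_lo else end_hi, , drop = FALSE])
  kp <- list(head = hpt, body = ctr, tail = tpt)
  if (tp$keypoint_jitter_px > 0) {
    kp <- lapply(kp, function(p) p + rnorm(2, sd = tp$keypoint_jitter_px))
  }
  kp
}

#' Gate keypoints against the detector bounding box
#'
#' The validity contract of the dual-detector tracker: a detection is valid
#' only when a bounding box exists, keypoints exist, and every keypoint lies
#' inside the box (edges inclusive).
#'
#' @param bbox from [detect_bbox()] (or `NULL`).
#' @param keypoints from [detect_keypoints()] (or `NULL`).
#' @return list with `bbox`, `keypoints`, and logical `valid`.
#' @export
gate_detections <- function(bbox, keypoints) {
  valid <- !is.null(bbox) && !is.null(keypoints) &&
    all(vapply(keypoints, function(p) {
      p[1] >= bbox$x0 && p[1] <= bbox$x1 && p[2] >= bbox$y0 && p[2] <= bbox$y1
    }, logical(1)))
  list(bbox = bbox, keypoints = keypoints, valid = valid)
}

#' Track one frame: render-independent detection to a 3D fish state
#'
#' Runs detection and gating on a color+depth frame pair and converts the
#' keypoints to tank coordinates using the depth sampled at each keypoint.
#' On an invalid detection the previous state is carried forward with
#' `valid = FALSE` (minimal-motion hold); an invalid first frame is an error
#' so the session runner can retry.
#'
#' @param frames list with `color` and `depth` matrices.
#' @param previous previous fish state (list with `head`, `body`, `tail`),
#'   or `NULL` at the first frame.
#' @param tp [tracker_params()].
#' @param g [world_geometry()].
#' @return fish-state list with `head`, `body`, `tail` (world cm) and `valid`.
#' @export
track_frame <- function(frames, previous = NULL, tp = tracker_params(),
                        g = world_geometry()) {
  det <- gate_detections(detect_bbox(frames$color, tp),
                         detect_keypoints(frames$color, tp))
  if (!det$valid) {
    if (is.null(previous)) {
      stop("no valid detection at the first frame; retry next frame")
    }
    previous$valid <- FALSE
    return(previous)
  }
  to_world <- function(p) {
    i <- min(max(ceiling(p[1]), 1), nrow(frames$depth))
    j <- min(max(ceiling(p[2]), 1), ncol(frames$depth))
    camera_px_to_world(p[1], p[2], frames$depth[i, j], g)
  }
  out <- lapply(det$keypoints, to_world)
  list(head = as.numeric(out$head), body = as.numeric(out$body),
       tail = as.numeric(out$tail), valid = TRUE)
}

#' Closed-loop session through the full vision stack
#'
#' The "full-stack" variant of [simulate_session()]: every frame, the true
#' fish state is rendered to a synthetic color+depth frame, the tracker
#' recovers the fish from the images, and the stimulus controllers are driven
#' by the *tracked* head (as in the physical apparatus) while the agent
#' evolves from its true state. Supports the chasing/flipped/absent/
#' motionless programs.
#'
#' @inheritParams simulate_session
#' @param tp [tracker_params()].
#' @return a `session_log` whose `frames` carry the tracked head under
#'   `track_x/y/z` next to the true state, with `valid` from the tracker.
#' @export
simulate_session_fullstack <- function(left_mode = "chasing",
                                       right_mode = "absent", seed = 1L,
                                       g = world_geometry(),
                                       ctrl = controller_params(),
                                       agent = agent_params(),
                                       tp = tracker_params(),
                                       n_frames = 1800L,
                                       visible_frames = NULL) {
  n_frames <- as.integer(n_frames)
  if (n_frames %% 4L != 0L) stop("n_frames must be a multiple of 4")
  q <- n_frames %/% 4L
  if (is.null(visible_frames)) visible_frames <- c(2L * q, 3L * q)
  for (m in c(left_mode, right_mode)) {
    if (!m %in% c("absent", "motionless", "chasing", "flipped")) {
      stop("full-stack sessions support absent/motionless/chasing/flipped")
    }
  }
  mW <- g$monitor_frame[1]; mH <- g$monitor_frame[2]
  s <- g$monitor_px_per_cm
  set.seed(seed)
  ang <- runif(1, 0, 2 * pi)
  h <- c(g$tank_length / 2, g$tank_width / 2, g$water_depth / 2)
  v <- agent$mean_speed * c(cos(ang), sin(ang), 0)
  dims <- c(g$tank_length, g$tank_width, g$water_depth)
  modes <- c(left = left_mode, right = right_mode)
  st <- list(left = list(u = mW / 2, v = mH / 2, yaw = 0, pitch = 0,
                         last_moved = -1e6),
             right = list(u = mW / 2, v = mH / 2, yaw = 0, pitch = 0,
                          last_moved = -1e6))
  prev_track <- NULL
  head <- matrix(0, n_frames, 3); vel <- matrix(0, n_frames, 3)
  track <- matrix(0, n_frames, 3); validv <- logical(n_frames)
  stim <- list(left = matrix(NA_real_, n_frames, 7),
               right = matrix(NA_real_, n_frames, 7))
  hb_dir <- c(1, 0, 0)
  for (t0 in seq_len(n_frames) - 1L) {
    head[t0 + 1L, ] <- h; vel[t0 + 1L, ] <- v
    sp <- sqrt(sum(v^2))
    if (sp > 1e-9) hb_dir <- v / sp
    body <- pmin(pmax(h - hb_dir, 0), dims)
    fr <- render_frames(list(head = h, body = body,
                             length_cm = agent$fish_length_cm), g)
    tracked <- track_frame(fr, prev_track, tp, g)
    prev_track <- tracked
    track[t0 + 1L, ] <- tracked$head
    validv[t0 + 1L] <- tracked$valid
    in_window <- t0 >= visible_frames[1] && t0 < visible_frames[2]
    keff <- c(0, 0)
    for (i in 1:2) {
      sd_ <- c("left", "right")[i]
      mode <- modes[[sd_]]
      x <- st[[sd_]]
      visible <- in_window && mode != "absent"
      # target = projected tracked head; like the direct engine this is NOT
      # clamped to the screen (the bottom of the water column projects below
      # the monitor; the pursuit law aims at the projected point while the
      # stimulus position itself stays on-screen)
      th <- tracked$head
      tu <- if (i == 1) th[2] * s else (g$tank_width - th[2]) * s
      tv <- (g$water_depth - th[3]) * s
      moved <- FALSE
      if (visible) {
        if (mode == "motionless") {
          pu <- x$u
          uv <- cpp_motionless_step(mW / 2, mH / 2, ctrl$jitter_max_px)
          x$u <- uv[1]; x$v <- uv[2]; x$yaw <- 0; x$pitch <- 0
          moved <- x$u != pu
        } else {
          ttu <- if (mode == "flipped") mW - tu else tu
          res <- cpp_chase_step(x$u, x$v, ttu, tv, ctrl$dt, ctrl$deadband_px,
                                ctrl$velocity_divisor, mW, mH, TRUE)
          moved <- res[3] > 0
          x$u <- res[1]; x$v <- res[2]
          op <- cpp_orient_toward(x$u, x$v, ttu, tv, x$yaw, x$pitch,
                                  ctrl$yaw_limits[1], ctrl$yaw_limits[2],
                                  ctrl$pitch_limits[1], ctrl$pitch_limits[2])
          x$yaw <- op[1]; x$pitch <- op[2]
        }
        if (moved) x$last_moved <- t0
        salient <- t0 - x$last_moved < agent$salience_frames
        keff[i] <- unname(agent$attraction[[mode]]) *
          if (salient) agent$motion_salience_bonus else 1
      } else {
        x$u <- mW / 2; x$v <- mH / 2; x$yaw <- 0; x$pitch <- 0
        x$last_moved <- -1e6
      }
      stim[[sd_]][t0 + 1L, ] <- c(x$u, x$v, x$yaw, x$pitch,
                                  as.numeric(visible), NA_real_, NA_real_)
      st[[sd_]] <- x
    }
    drift <- cpp_attraction_drift(h, keff[1], keff[2], dims[1], dims[2], dims[3])
    res <- cpp_agent_step(h, v, drift, agent$mean_speed,
                          agent$velocity_relaxation, agent$noise_sd,
                          agent$wall_margin, agent$wall_repulsion, dims,
                          ctrl$dt)
    h <- res[1:3]; v <- res[4:6]
  }
  bt <- .body_tail(head, vel, g)
  frame <- seq_len(n_frames) - 1L
  frames <- data.frame(
    frame = frame, t = frame * ctrl$dt, period = frame %/% q,
    head_x = head[, 1], head_y = head[, 2], head_z = head[, 3],
    body_x = bt$body[, 1], body_y = bt$body[, 2], body_z = bt$body[, 3],
    tail_x = bt$tail[, 1], tail_y = bt$tail[, 2], tail_z = bt$tail[, 3],
    track_x = track[, 1], track_y = track[, 2], track_z = track[, 3],
    valid = validv,
    left_mode = left_mode, left_u = stim$left[, 1], left_v = stim$left[, 2],
    left_yaw = stim$left[, 3], left_pitch = stim$left[, 4],
    left_visible = stim$left[, 5] > 0,
    right_mode = right_mode, right_u = stim$right[, 1],
    right_v = stim$right[, 2], right_yaw = stim$right[, 3],
    right_pitch = stim$right[, 4], right_visible = stim$right[, 5] > 0)
  structure(list(
    meta = list(seed = seed, left_mode = left_mode, right_mode = right_mode,
                n_frames = n_frames, visible_frames = visible_frames,
                dt = ctrl$dt, fps = 1 / ctrl$dt, engine = "fullstack",
                geometry = unclass(g), controller = unclass(ctrl),
                agent = unclass(agent), tracker = unclass(tp)),
    frames = frames), class = "session_log")
}
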