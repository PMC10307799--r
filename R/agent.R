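#' Behavioral parameters of the simulated experimental fish
#'
#' The synthetic stand-in for a live subject: an Ornstein-Uhlenbeck swimmer
#' whose velocity relaxes toward a preferred cruising speed along its current
#' heading, perturbed by Gaussian noise, repelled softly from the walls, and
#' biased toward whichever monitor currently shows an attractive stimulus.
#' The attraction gain depends on the displayed motion type, which is how the
#' stimulus-dependent spatial bias that the pipeline measures is generated.
#' This is a generative assumption, not a model of zebrafish: conclusions
#' drawn from it concern the pipeline, never the animals.
#'
#' Defaults emulate adult zebrafish scale: ~6 cm/s cruising with ~2 cm/s
#' velocity fluctuations crosses the 45-cm tank in seconds, so compartment
#' occupancy mixes quickly once the monitors go blank.
#' The attraction map was calibrated once (see `scripts/calibrate.R`) so that
#' a simulated first experiment lands on the observed fold-preference scale;
#' the vignette documents the calibration.
#'
#' @param mean_speed preferred cruising speed, cm/s.
#' @param velocity_relaxation OU relaxation rate, 1/s.
#' @param noise_sd velocity noise intensity, cm/s^1.5.
#' @param wall_margin distance from a wall where repulsion starts, cm.
#' @param wall_repulsion peak wall repulsion, cm/s^2.
#' @param attraction named gain map (cm/s^2) from motion type to attraction
#'   toward the monitor showing it; `absent` must be 0.
#' @param motion_salience_bonus multiplier on the gain while the stimulus has
#'   moved within the last second (30 frames).
#' @param salience_frames length of the salience window, frames.
#' @param fish_length_cm body length used for the head/body/tail keypoints
#'   and rendering, cm.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(mean_speed = 6, velocity_relaxation = 2,
                         noise_sd = 4, wall_margin = 2, wall_repulsion = 30,
                         attraction = c(absent = 0, motionless = 0.3,
                                        chasing = 1.3, fleeing = 0.55,
                                        flipped = 0.75, independent = 0.9),
                         motion_salience_bonus = 1.5,
                         salience_frames = 30L,
                         fish_length_cm = 3) {
  stopifnot(mean_speed >= 0, velocity_relaxation >= 0, noise_sd >= 0,
            wall_margin > 0, wall_repulsion >= 0,
            motion_salience_bonus > 0, salience_frames >= 1,
            fish_length_cm > 0)
  miss <- setdiff(motion_types(), names(attraction))
  if (length(miss)) {
    stop("attraction map missing motion types: ", paste(miss, collapse = ", "))
  }
  if (any(attraction < 0) || attraction[["absent"]] != 0) {
    stop("attraction gains must be non-negative and 0 for 'absent'")
  }
  structure(list(mean_speed = mean_speed,
                 velocity_relaxation = velocity_relaxation,
                 noise_sd = noise_sd, wall_margin = wall_margin,
                 wall_repulsion = wall_repulsion,
                 attraction = attraction[motion_types()],
                 motion_salience_bonus = motion_salience_bonus,
                 salience_frames = as.integer(salience_frames),
                 fish_length_cm = fish_length_cm),
            class = "agent_params")
}

#' Social attraction drift on the simulated fish
#'
#' Acceleration pulling the fish toward the midpoints of the monitor walls,
#' weighted by the attraction gain of each side's currently displayed motion
#' type. Invisible or absent stimuli contribute nothing; a stimulus that has
#' moved within the salience window gets the salience bonus.
#'
#' @param head fish head position `c(x, y, z)`, cm.
#' @param left,right [stimulus_state()] of each monitor.
#' @param p [agent_params()].
#' @param g [world_geometry()].
#' @param left_salient,right_salient whether each stimulus moved within the
#'   salience window.
#' @return drift acceleration `c(ax, ay, az)`, cm/s^2.
#' @export
attraction_drift <- function(head, left, right, p = agent_params(),
                             g = world_geometry(),
                             left_salient = FALSE, right_salient = FALSE) {
  keff <- function(s, salient) {
    if (is.null(s) || !isTRUE(s$visible) || s$mode == "absent") return(0)
    unname(p$attraction[[s$mode]]) * if (salient) p$motion_salience_bonus else 1
  }
  cpp_attraction_drift(as.numeric(head), keff(left, left_salient),
                       keff(right, right_salient),
                       g$tank_length, g$tank_width, g$water_depth)
}

#' One 1/30-s step of the fish agent
#'
#' Updates velocity by OU relaxation + drift + wall repulsion + noise and
#' integrates the position with reflection at the walls. Consumes exactly
#' three normal draws from the R RNG.
#'
#' @param fish list with `head` and `velocity` (3-vectors).
#' @param drift attraction drift from [attraction_drift()].
#' @param p [agent_params()].
#' @param g [world_geometry()].
#' @param dt step, s.
#' @return the updated `fish` list.
#' @export
step_agent <- function(fish, drift = c(0, 0, 0), p = agent_params(),
                       g = world_geometry(), dt = 1 / 30) {
  res <- cpp_agent_step(as.numeric(fish$head), as.numeric(fish$velocity),
                        as.numeric(drift), p$mean_speed,
                        p$velocity_relaxation, p$noise_sd, p$wall_margin,
                        p$wall_repulsion,
                        c(g$tank_length, g$tank_width, g$water_depth), dt)
  fish$head <- res[1:3]
  fish$velocity <- res[4:6]
  fish
}

# body and tail trail the head against the heading at ~1 cm spacing,
# clamped into the tank; headings are carried forward through zero-speed frames
.body_tail <- function(head, vel, g, spacing = 1) {
  n <- nrow(head)
  sp <- sqrt(rowSums(vel^2))
  dir <- vel / pmax(sp, 1e-12)
  ok <- sp > 1e-9
  if (!all(ok)) {
    last <- c(1, 0, 0)
    for (i in seq_len(n)) {
      if (ok[i]) last <- dir[i, ] else dir[i, ] <- last
    }
  }
  clampm <- function(m) {
    m[, 1] <- pmin(pmax(m[, 1], 0), g$tank_length)
    m[, 2] <- pmin(pmax(m[, 2], 0), g$tank_width)
    m[, 3] <- pmin(pmax(m[, 3], 0), g$water_depth)
    m
  }
  list(body = clampm(head - spacing * dir),
       tail = clampm(head - 2 * spacing * dir))
}
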