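# Condition-order literals for both experiments, kept in one place so any
# transcription question about the published order tables is isolated here.
#
# Each experiment is a sequence of 4-session blocks per fish; a condition is
# two adjacent blocks (4 sessions one side assignment, 4 reversed), and the
# blank-monitor control is interspersed as two-session sets around the
# conditions. The block order below is read per fish group, top to bottom,
# from the published order tables.

# Experiment 1: four fish groups, blocks numbered 1..6.
# Entries: condition name, stimulus A (first-named) and B, and A's side in
# that block.
.exp1_orders <- list(
  `1M` = 1, `3F` = 1, `2M` = 2, `4F` = 2, `5M` = 3, `7F` = 3, `6M` = 4, `8F` = 4)

.exp1_blocks <- list(
  # group 1 (1M, 3F)
  list(c("Motionless-vs-Absent", "left"), c("Motionless-vs-Absent", "right"),
       c("Chasing-vs-Absent", "left"), c("Chasing-vs-Absent", "right"),
       c("Chasing-vs-Motionless", "left"), c("Chasing-vs-Motionless", "right")),
  # group 2 (2M, 4F)
  list(c("Motionless-vs-Absent", "right"), c("Motionless-vs-Absent", "left"),
       c("Chasing-vs-Absent", "right"), c("Chasing-vs-Absent", "left"),
       c("Chasing-vs-Motionless", "right"), c("Chasing-vs-Motionless", "left")),
  # group 3 (5M, 7F)
  list(c("Chasing-vs-Absent", "left"), c("Chasing-vs-Absent", "right"),
       c("Motionless-vs-Absent", "left"), c("Motionless-vs-Absent", "right"),
       c("Chasing-vs-Motionless", "left"), c("Chasing-vs-Motionless", "right")),
  # group 4 (6M, 8F)
  list(c("Chasing-vs-Absent", "right"), c("Chasing-vs-Absent", "left"),
       c("Motionless-vs-Absent", "right"), c("Motionless-vs-Absent", "left"),
       c("Chasing-vs-Motionless", "right"), c("Chasing-vs-Motionless", "left")))

# Experiment 2: two fish groups, blocks numbered 1..8.
.exp2_orders <- list(
  `1M` = 1, `3F` = 1, `5M` = 1, `7F` = 1, `2M` = 2, `4F` = 2, `6M` = 2, `8F` = 2)

.exp2_blocks <- list(
  # group 1 (1M, 3F, 5M, 7F)
  list(c("Chasing-vs-Fleeing-1", "left"), c("Chasing-vs-Fleeing-1", "right"),
       c("Chasing-vs-Flipped", "left"), c("Chasing-vs-Flipped", "right"),
       c("Chasing-vs-Independent", "left"), c("Chasing-vs-Independent", "right"),
       c("Chasing-vs-Fleeing-2", "left"), c("Chasing-vs-Fleeing-2", "right")),
  # group 2 (2M, 4F, 6M, 8F)
  list(c("Chasing-vs-Fleeing-1", "right"), c("Chasing-vs-Fleeing-1", "left"),
       c("Chasing-vs-Flipped", "right"), c("Chasing-vs-Flipped", "left"),
       c("Chasing-vs-Independent", "right"), c("Chasing-vs-Independent", "left"),
       c("Chasing-vs-Fleeing-2", "right"), c("Chasing-vs-Fleeing-2", "left")))

# motion pair (A, B) of a condition name; A is the first-named stimulus
.condition_modes <- function(condition) {
  map <- list(
    "Motionless-vs-Absent" = c("motionless", "absent"),
    "Chasing-vs-Absent" = c("chasing", "absent"),
    "Chasing-vs-Motionless" = c("chasing", "motionless"),
    "Chasing-vs-Fleeing-1" = c("chasing", "fleeing"),
    "Chasing-vs-Fleeing-2" = c("chasing", "fleeing"),
    "Chasing-vs-Flipped" = c("chasing", "flipped"),
    "Chasing-vs-Independent" = c("chasing", "independent"),
    "Absent-vs-Absent" = c("absent", "absent"))
  m <- map[[condition]]
  if (is.null(m)) stop("unknown condition: ", condition)
  m
}

.default_fish <- c("1M", "2M", "3F", "4F", "5M", "6M", "7F", "8F")

# deterministic per-session seed from (experiment, fish, session); keeps any
# single session reproducible in isolation; stays below 2^31
.session_seed <- function(base_seed, experiment, fish_idx, session_idx) {
  (as.numeric(base_seed) * 48271 + experiment * 16807 +
     fish_idx * 69621 + session_idx * 131) %% 2147483629
}

.build_plan <- function(experiment, fish_ids, seed, orders, blocks_by_group) {
  stopifnot(all(fish_ids %in% names(orders)))
  rows <- list()
  for (fi in seq_along(fish_ids)) {
    fish <- fish_ids[fi]
    blocks <- blocks_by_group[[orders[[fish]]]]
    n_cond <- length(blocks) / 2
    sidx <- 0L
    ava_set <- 0L
    add_ava_set <- function() {
      ava_set <<- ava_set + 1L
      for (k in 1:2) {
        sidx <<- sidx + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          experiment = experiment, fish = fish,
          condition = "Absent-vs-Absent", session = sidx,
          session_in_condition = (ava_set - 1L) * 2L + k,
          ava_set = ava_set, block = NA_integer_,
          a_name = "absent", b_name = "absent",
          a_side = c("left", "right")[k],
          left_mode = "absent", right_mode = "absent",
          seed = .session_seed(seed, experiment, fi, sidx))
      }
    }
    add_ava_set()  # before the first condition
    for (ci in seq_len(n_cond)) {
      for (bi in (2 * ci - 1):(2 * ci)) {
        blk <- blocks[[bi]]
        cond <- blk[1]; a_side <- blk[2]
        ab <- .condition_modes(cond)
        for (k in 1:4) {
          sidx <- sidx + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            experiment = experiment, fish = fish, condition = cond,
            session = sidx,
            session_in_condition = (bi - (2 * ci - 1)) * 4L + k,
            ava_set = NA_integer_, block = bi,
            a_name = ab[1], b_name = ab[2], a_side = a_side,
            left_mode = if (a_side == "left") ab[1] else ab[2],
            right_mode = if (a_side == "left") ab[2] else ab[1],
            seed = .session_seed(seed, experiment, fi, sidx))
        }
      }
      # interspersed blank-monitor sets: after each condition in the first
      # experiment; in the second, in every between-condition gap, keeping the
      # total at eight sessions
      if (experiment == 1L || ci < n_cond) add_ava_set()
    }
  }
  sessions <- do.call(rbind, rows)
  rownames(sessions) <- NULL
  structure(list(experiment = experiment, fish = fish_ids,
                 base_seed = seed, sessions = sessions),
            class = "experiment_plan")
}

#' Build the session plans of the two experiments
#'
#' Constructs the complete within-subject designs: per fish, each condition
#' runs as eight consecutive sessions with the two stimuli swapping monitors
#' after the fourth session (4/4 side counterbalancing), condition orders
#' follow the published per-fish-group order tables, and the Absent-vs-Absent
#' control is interspersed as four two-session sets (8 sessions per fish).
#' Experiment 1 compares motionless, chasing, and absent; Experiment 2
#' compares chasing against fleeing (twice), flipped, and playback.
#'
#' @param fish_ids fish identifiers; defaults to the eight subjects
#'   (4 male, 4 female) of the study design.
#' @param seed base seed; per-session seeds are derived from it by a stable
#'   hash so any single session is reproducible in isolation.
#' @return an `experiment_plan`: list with `sessions`, a data frame of one
#'   row per session in run order per fish (condition, side assignment of
#'   stimulus A, per-monitor motion types, seed).
#' @export
build_experiment1_plan <- function(fish_ids = .default_fish, seed = 1L) {
  .build_plan(1L, fish_ids, seed, .exp1_orders, .exp1_blocks)
}

#' @rdname build_experiment1_plan
#' @export
build_experiment2_plan <- function(fish_ids = .default_fish, seed = 1L) {
  .build_plan(2L, fish_ids, seed, .exp2_orders, .exp2_blocks)
}

#' @export
print.experiment_plan <- function(x, ...) {
  s <- x$sessions
  cat(sprintf("<experiment_plan> Experiment %d: %d fish, %d sessions each\n",
              x$experiment, length(x$fish), nrow(s) / length(x$fish)))
  cat("  conditions:",
      paste(unique(s$condition[order(s$session)]), collapse = ", "), "\n")
  invisible(x)
}

#' Run every session of an experiment plan
#'
#' Simulates each planned session with its derived seed and immediately
#' reduces the frame log to per-period compartment times, so a full
#' experiment fits comfortably in memory. Playback tracks for the
#' `independent` program are generated once (four donor recordings) and
#' replayed in the same fixed cyclic order for every fish.
#'
#' @param plan from [build_experiment1_plan()] / [build_experiment2_plan()].
#' @param agent one [agent_params()] for all fish, or a named list per fish.
#' @param ctrl,g controller parameters and geometry.
#' @param n_frames frames per session; the default is the full 20-min
#'   session, smaller multiples of 4 scale every period down together.
#' @param tracks optional list of `playback_track`; generated if needed.
#' @param keep_logs if `TRUE` the full `session_log` objects are kept under
#'   `$logs` (memory-hungry for full-length experiments).
#' @param out_dir if non-`NULL`, each session log is also written as JSONL
#'   under this directory together with a CSV session index.
#' @return an `experiment_result`: the plan plus `times`, a data frame with
#'   one row per session x period holding `left_s`, `center_s`, `right_s`.
#' @export
run_experiment <- function(plan, agent = agent_params(),
                           ctrl = controller_params(), g = world_geometry(),
                           n_frames = 36000L, tracks = NULL,
                           keep_logs = FALSE, out_dir = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  sess <- plan$sessions
  needs_tracks <- any(sess$left_mode == "independent" |
                      sess$right_mode == "independent")
  if (needs_tracks && is.null(tracks)) {
    tracks <- make_playback_tracks(4, seed = plan$base_seed + 977L,
                                   g = g, ctrl = ctrl,
                                   agent = if (inherits(agent, "agent_params"))
                                     agent else agent[[1]],
                                   n_frames = n_frames)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  logs <- if (keep_logs) vector("list", nrow(sess)) else NULL
  rows <- vector("list", nrow(sess))
  for (i in seq_len(nrow(sess))) {
    r <- sess[i, ]
    ap <- if (inherits(agent, "agent_params")) agent else agent[[r$fish]]
    tr_idx <- ((r$session_in_condition - 1L) %% 4L) + 1L
    pick <- function(mode) if (mode == "independent") tracks[[tr_idx]] else NULL
    log <- simulate_session(r$left_mode, r$right_mode, seed = r$seed,
                            g = g, ctrl = ctrl, agent = ap,
                            n_frames = n_frames,
                            left_track = pick(r$left_mode),
                            right_track = pick(r$right_mode))
    tt <- session_side_times(log)
    rows[[i]] <- cbind(r[rep(1, nrow(tt)), c("experiment", "fish",
                                             "condition", "session",
                                             "session_in_condition",
                                             "ava_set", "a_side")],
                       tt, row.names = NULL)
    if (keep_logs) logs[[i]] <- log
    if (!is.null(out_dir)) {
      write_session_log(log, file.path(out_dir,
        sprintf("exp%d_%s_s%03d.jsonl", r$experiment, r$fish, r$session)))
    }
  }
  times <- do.call(rbind, rows)
  rownames(times) <- NULL
  if (!is.null(out_dir)) {
    write.csv(sess, file.path(out_dir, "session_index.csv"), row.names = FALSE)
    write.csv(times, file.path(out_dir, "session_times.csv"), row.names = FALSE)
  }
  structure(list(plan = plan, times = times, logs = logs),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> Experiment %d: %d sessions simulated\n",
              x$plan$experiment, nrow(x$plan$sessions)))
  invisible(x)
}
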