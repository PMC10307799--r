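#' Run configuration
#'
#' A nested list with one section per pipeline stage (`geometry`,
#' `controller`, `agent`, `tracker`, `scheduler`, `stats`) plus a global
#' `seed` and `out_dir`. Defaults are the apparatus values; a YAML file only
#' needs the keys it overrides, and unknown keys are rejected rather than
#' silently ignored.
#'
#' @param path YAML file; `NULL` or an empty file keeps all defaults.
#' @return a `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping")
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config section(s): ",
                          paste(bad, collapse = ", "))
    for (sec in names(user)) {
      if (is.list(cfg[[sec]])) {
        badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(badk)) stop(sprintf("unknown key(s) in '%s': %s", sec,
                                       paste(badk, collapse = ", ")))
        cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @export
default_config <- function() {
  g <- world_geometry(); ctrl <- controller_params()
  ag <- agent_params(); tp <- tracker_params()
  list(seed = 1L, out_dir = "zebrapref-out",
       geometry = list(tank_length = g$tank_length,
                       tank_width = g$tank_width,
                       water_depth = g$water_depth,
                       monitor_px_per_cm = g$monitor_px_per_cm),
       controller = unclass(ctrl)[c("dt", "deadband_px", "velocity_divisor",
                                    "jitter_max_px", "flee_dx_px",
                                    "flee_dy_px", "flee_teleport")],
       agent = list(mean_speed = ag$mean_speed,
                    velocity_relaxation = ag$velocity_relaxation,
                    noise_sd = ag$noise_sd,
                    attraction = as.list(ag$attraction),
                    motion_salience_bonus = ag$motion_salience_bonus),
       tracker = unclass(tp)[c("intensity_threshold", "min_blob_px",
                               "miss_probability", "keypoint_jitter_px")],
       scheduler = list(experiment = 1L, n_frames = 36000L),
       stats = list(candidates = candidate_random_structures()))
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @param path_out where to write the YAML.
#' @export
save_config <- function(cfg, path_out) {
  yaml::write_yaml(unclass(cfg), path_out, precision = 15)
  invisible(path_out)
}

#' Realize parameter objects from a config
#'
#' @param cfg a `run_config` from [load_config()].
#' @return list with `geometry`, `controller`, `agent`, `tracker` parameter
#'   objects.
#' @export
config_params <- function(cfg) {
  ag <- cfg$agent
  ag$attraction <- unlist(ag$attraction)
  list(geometry = do.call(world_geometry, cfg$geometry),
       controller = do.call(controller_params, cfg$controller),
       agent = do.call(agent_params, ag),
       tracker = do.call(tracker_params, cfg$tracker))
}

#' Write / read a session log as JSON Lines
#'
#' One JSON object per line: a `meta` header line followed by one frame
#' record per frame. The round trip is lossless for all fields.
#'
#' @param log a `session_log`.
#' @param path output path (`.jsonl`).
#' @return `path` invisibly; `read_session_log()` returns the `session_log`.
#' @export
write_session_log <- function(log, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(list(record = "meta"), log$meta),
                              auto_unbox = TRUE, digits = NA, null = "null"),
             con)
  jsonlite::stream_out(log$frames, con, digits = NA, verbose = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty session log: ", path)
  meta <- try(jsonlite::fromJSON(lines[1]), silent = TRUE)
  if (inherits(meta, "try-error") || !identical(meta$record, "meta")) {
    stop("parse error in ", path, " at line 1: missing meta header")
  }
  meta$record <- NULL
  frames <- try(jsonlite::stream_in(
    textConnection(lines[-1]), verbose = FALSE), silent = TRUE)
  if (inherits(frames, "try-error")) {
    # locate the offending line for the error message
    for (i in seq_along(lines[-1])) {
      ok <- try(jsonlite::fromJSON(lines[i + 1]), silent = TRUE)
      if (inherits(ok, "try-error")) {
        stop("parse error in ", path, " at line ", i + 1)
      }
    }
    stop("parse error in ", path)
  }
  if (nrow(frames) != meta$n_frames) {
    stop("truncated session log: expected ", meta$n_frames, " frames, found ",
         nrow(frames), " (", path, ")")
  }
  structure(list(meta = meta, frames = frames), class = "session_log")
}

#' Ingest an external long table of preference data
#'
#' Reads a deposited long table (CSV, or xlsx when the readxl package is
#' available) of per fish x condition x period records and maps it onto the
#' package's preference records so the statistics stage can be re-run on it.
#' Column names are matched case-insensitively against common aliases;
#' either a ready `log_ratio` column or the pair of pooled side times must
#' be present.
#'
#' @param path CSV or xlsx file.
#' @param sheet sheet name/number for xlsx input.
#' @return a `preference_table`-compatible data frame with `fish`,
#'   `condition`, `period`, `log_ratio` (and side times when provided).
#' @export
read_preference_table <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx needs the readxl package; export to CSV instead")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    read.csv(path, check.names = FALSE)
  }
  nm <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(names(raw))))
  alias <- function(...) {
    hits <- match(c(...), nm)
    hits <- hits[!is.na(hits)]
    if (length(hits)) raw[[hits[1]]] else NULL
  }
  fish <- alias("fish", "fish_id", "subject", "id")
  condition <- alias("condition", "condition_name", "cond")
  period <- alias("period", "phase")
  if (is.null(fish) || is.null(condition) || is.null(period)) {
    stop("table must provide fish, condition and period columns")
  }
  out <- data.frame(fish = fish, condition = condition, period = period)
  lr <- alias("log_ratio", "log10_ratio", "logratio", "log_time_ratio")
  ta <- alias("time_a", "time_a_s", "side_a_time", "t_a")
  tb <- alias("time_b", "time_b_s", "side_b_time", "t_b")
  if (!is.null(lr)) {
    out$log_ratio <- as.numeric(lr)
  } else if (!is.null(ta) && !is.null(tb)) {
    out$time_A <- as.numeric(ta); out$time_B <- as.numeric(tb)
    out$log_ratio <- log10(out$time_A / out$time_B)
  } else {
    stop("table must provide either log_ratio or the time_A/time_B pair")
  }
  out$period <- as.integer(gsub("[^0-9]", "", as.character(out$period)))
  if (anyNA(out$period) || !all(out$period %in% 1:3)) {
    stop("period column must encode periods 1-3")
  }
  class(out) <- c("preference_table", "data.frame")
  out
}

#' Simulate, score and analyze one experiment end to end
#'
#' The `replicate` pipeline: build the plan, simulate every session, score
#' the preference records, and run the inferential chain.
#'
#' @param experiment 1 or 2.
#' @param seed base seed.
#' @param agent,ctrl,g parameter objects.
#' @param n_frames frames per session (the default is the full 20-min
#'   session; smaller multiples of 4 shrink all periods together).
#' @param out_dir optional directory for tidy CSV outputs.
#' @param candidates random-structure candidates for the analysis.
#' @return list with `plan`, `result`, `records`, `scale` (Period-2 fold
#'   preferences) and `analysis`.
#' @export
replicate_experiment <- function(experiment = 1, seed = 1L,
                                 agent = agent_params(),
                                 ctrl = controller_params(),
                                 g = world_geometry(),
                                 n_frames = 36000L, out_dir = NULL,
                                 candidates = candidate_random_structures()) {
  plan <- if (experiment == 1) build_experiment1_plan(seed = seed)
          else build_experiment2_plan(seed = seed)
  result <- run_experiment(plan, agent = agent, ctrl = ctrl, g = g,
                           n_frames = n_frames)
  records <- preference_table(result)
  scale <- preference_scale(records)
  analysis <- run_paper_analysis(records, candidates = candidates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(records),
              file.path(out_dir, "preference_records.csv"), row.names = FALSE)
    write.csv(scale, file.path(out_dir, "preference_scale.csv"),
              row.names = FALSE)
    write_analysis_report(analysis, file.path(out_dir, "analysis"))
  }
  list(plan = plan, result = result, records = records, scale = scale,
       analysis = analysis)
}
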