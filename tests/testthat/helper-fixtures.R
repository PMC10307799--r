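# shared fixtures: tiny sessions and toy tables built in code

quick_agent <- function(...) agent_params(...)

# agent with no social attraction at all (pure OU swimmer)
null_agent <- function(...) {
  agent_params(attraction = c(absent = 0, motionless = 0, chasing = 0,
                              fleeing = 0, flipped = 0, independent = 0), ...)
}

# single-kappa agent: attraction only for the given mode
mono_agent <- function(mode, kappa, ...) {
  att <- c(absent = 0, motionless = 0, chasing = 0, fleeing = 0,
           flipped = 0, independent = 0)
  att[mode] <- kappa
  agent_params(attraction = att, ...)
}

# pooled condition log-ratio for n_fish x n_sess counterbalanced sessions of
# mode_a vs mode_b under one agent; the workhorse of the calibration-style
# tests
pooled_log_ratio <- function(mode_a, mode_b, agent, period = 2,
                             n_fish = 8, n_sess = 8, base_seed = 100,
                             n_frames = 36000L) {
  vapply(seq_len(n_fish), function(f) {
    tot_a <- 0; tot_b <- 0
    for (s in seq_len(n_sess)) {
      a_side <- if (s <= n_sess / 2) "left" else "right"
      log <- simulate_session(
        left_mode = if (a_side == "left") mode_a else mode_b,
        right_mode = if (a_side == "left") mode_b else mode_a,
        seed = base_seed + 1009 * f + s, agent = agent, n_frames = n_frames)
      tt <- time_in_compartments(log, period)
      tot_a <- tot_a + tt[[if (a_side == "left") "left" else "right"]]
      tot_b <- tot_b + tt[[if (a_side == "left") "right" else "left"]]
    }
    log10(max(tot_a, 1 / 60) / max(tot_b, 1 / 60))
  }, numeric(1))
}

# synthetic long table of log ratios for the stats chain: balanced
# fish x condition x period design with chosen effects
toy_long_table <- function(n_fish = 8,
                           conditions = c("Absent-vs-Absent", "A", "B", "C"),
                           intercept = 0, cond_p2_effects = NULL,
                           fish_sd = 0.1, resid_sd = 0.3,
                           period_slope_sd = 0, seed = 1) {
  set.seed(seed)
  if (is.null(cond_p2_effects)) {
    cond_p2_effects <- setNames(rep(0, length(conditions)), conditions)
  }
  fish <- sprintf("f%02d", seq_len(n_fish))
  b0 <- rnorm(n_fish, 0, fish_sd)
  slp <- matrix(rnorm(n_fish * 3, 0, period_slope_sd), n_fish, 3)
  rows <- expand.grid(fish = fish, condition = conditions, period = 1:3,
                      stringsAsFactors = FALSE)
  fi <- match(rows$fish, fish)
  eff <- ifelse(rows$period == 2, cond_p2_effects[rows$condition], 0)
  rows$log_ratio <- intercept + b0[fi] + slp[cbind(fi, rows$period)] +
    eff + rnorm(nrow(rows), 0, resid_sd)
  rows
}
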