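plan1 <- build_experiment1_plan(seed = 1)
plan2 <- build_experiment2_plan(seed = 1)

cond_sequence <- function(plan, fish) {
  s <- plan$sessions
  s <- s[s$fish == fish & s$condition != "Absent-vs-Absent", ]
  unique(s$condition[order(s$session)])
}

first_condition <- function(plan, fish) {
  s <- plan$sessions
  s <- s[s$fish == fish & s$condition != "Absent-vs-Absent", ]
  s[which.min(s$session), ]
}

test_that("Experiment 1 plan follows the published condition orders", {
  # fish 1M starts with Motionless-vs-Absent, motionless on the left
  f <- first_condition(plan1, "1M")
  expect_equal(f$condition, "Motionless-vs-Absent")
  expect_equal(f$left_mode, "motionless")
  # group structure: 1M/3F, 2M/4F share orders; 5M/7F start with chasing
  expect_equal(cond_sequence(plan1, "1M"), cond_sequence(plan1, "3F"))
  expect_equal(cond_sequence(plan1, "1M"),
               c("Motionless-vs-Absent", "Chasing-vs-Absent",
                 "Chasing-vs-Motionless"))
  expect_equal(cond_sequence(plan1, "5M"),
               c("Chasing-vs-Absent", "Motionless-vs-Absent",
                 "Chasing-vs-Motionless"))
  # 2M mirrors 1M's side order: motionless first on the right
  f2 <- first_condition(plan1, "2M")
  expect_equal(f2$condition, "Motionless-vs-Absent")
  expect_equal(f2$right_mode, "motionless")
  # 6M starts with chasing on the right
  f6 <- first_condition(plan1, "6M")
  expect_equal(f6$condition, "Chasing-vs-Absent")
  expect_equal(f6$right_mode, "chasing")
})

test_that("Experiment 2 plan follows the published condition orders", {
  f <- first_condition(plan2, "2M")
  expect_equal(f$condition, "Chasing-vs-Fleeing-1")
  expect_equal(f$right_mode, "chasing")   # chasing on the right first for 2M
  f1 <- first_condition(plan2, "1M")
  expect_equal(f1$condition, "Chasing-vs-Fleeing-1")
  expect_equal(f1$left_mode, "chasing")
  expect_equal(cond_sequence(plan2, "1M"),
               c("Chasing-vs-Fleeing-1", "Chasing-vs-Flipped",
                 "Chasing-vs-Independent", "Chasing-vs-Fleeing-2"))
  # chasing-vs-fleeing occurs twice per fish (8 + 8 sessions)
  s <- plan2$sessions
  for (fish in plan2$fish) {
    n_flee <- sum(s$fish == fish &
                    s$condition %in% c("Chasing-vs-Fleeing-1",
                                       "Chasing-vs-Fleeing-2"))
    expect_equal(n_flee, 16)
  }
})

test_that("both plans satisfy the design invariants", {
  for (plan in list(plan1, plan2)) {
    s <- plan$sessions
    for (fish in plan$fish) {
      sf <- s[s$fish == fish, ]
      # every condition has exactly 8 sessions
      expect_true(all(table(sf$condition) == 8))
      # 4/4 side balance within every condition (virtual for the control)
      for (cond in unique(sf$condition)) {
        expect_equal(sum(sf$a_side[sf$condition == cond] == "left"), 4)
      }
      # the control is 4 interspersed two-session sets, the first before any
      # condition
      ava <- sf[sf$condition == "Absent-vs-Absent", ]
      expect_equal(nrow(ava), 8)
      expect_equal(sort(unique(ava$ava_set)), 1:4)
      expect_equal(min(ava$session), 1)
      expect_true(all(diff(ava$session[order(ava$session)])[c(1, 3, 5, 7)] == 1))
      # session numbering is contiguous
      expect_equal(sort(sf$session), seq_len(nrow(sf)))
    }
    # per-session seeds are unique across the whole plan
    expect_equal(anyDuplicated(s$seed), 0)
  }
  # expected totals: 8 fish x (3 x 8 + 8) and 8 fish x (4 x 8 + 8)
  expect_equal(nrow(plan1$sessions), 8 * 32)
  expect_equal(nrow(plan2$sessions), 8 * 40)
})

test_that("running a plan yields one deterministic record per session", {
  mini <- build_experiment1_plan(fish_ids = c("1M", "2M"), seed = 3)
  res <- run_experiment(mini, agent = null_agent(), n_frames = 240)
  expect_equal(nrow(res$times), nrow(mini$sessions) * 3)   # 3 periods each
  expect_true(all(abs(res$times$left_s + res$times$center_s +
                        res$times$right_s - 2) < 1e-9))    # 60 frames = 2 s
  res2 <- run_experiment(mini, agent = null_agent(), n_frames = 240)
  expect_identical(res$times, res2$times)
  # Period-2 modes match the planned assignment
  withr::local_seed(1)
  r <- mini$sessions[mini$sessions$condition == "Chasing-vs-Absent", ][1, ]
  log <- simulate_session(r$left_mode, r$right_mode, seed = r$seed,
                          agent = null_agent(), n_frames = 240)
  expect_equal(unique(log$frames$left_mode), r$left_mode)
  expect_equal(unique(log$frames$right_mode), r$right_mode)
})

test_that("independent conditions replay the same fixed tracks for all fish", {
  mini <- build_experiment2_plan(fish_ids = c("1M", "2M"), seed = 5)
  keep <- mini$sessions$condition %in% c("Chasing-vs-Independent",
                                         "Absent-vs-Absent")
  mini$sessions <- mini$sessions[keep, ]
  tracks <- make_playback_tracks(4, seed = 11, n_frames = 240,
                                 agent = null_agent())
  res <- run_experiment(mini, agent = null_agent(), n_frames = 240,
                        tracks = tracks, keep_logs = TRUE)
  idx <- which(res$plan$sessions$condition == "Chasing-vs-Independent")
  sic <- res$plan$sessions$session_in_condition[idx]
  fish <- res$plan$sessions$fish[idx]
  stim_u <- lapply(idx, function(i) {
    lg <- res$logs[[i]]
    side <- if (res$plan$sessions$left_mode[i] == "independent") "left_u"
            else "right_u"
    lg$frames[[side]][lg$frames$period == 2]
  })
  # same position in the condition -> same track, for both fish
  for (k in 1:4) {
    same <- which(((sic - 1) %% 4) + 1 == k)
    expect_true(length(same) >= 2)
    expect_true(all(vapply(same[-1], function(j)
      identical(stim_u[[same[1]]], stim_u[[j]]), logical(1))))
  }
})
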