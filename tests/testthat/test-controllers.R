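g <- world_geometry()
p <- controller_params()

test_that("motionless is a bounded jitter off the monitor center, not a walk", {
  s <- stimulus_state("motionless", g = g)
  cu <- g$monitor_frame[1] / 2
  cv <- g$monitor_frame[2] / 2
  set.seed(1)
  offs <- replicate(5000, {
    s <<- update_motionless(s, p, g)
    s$u - cu
  })
  expect_true(all(offs %in% -2:2))
  expect_equal(sort(unique(abs(offs))), c(0, 1, 2))
  expect_equal(max(abs(offs)), 2)           # no drift ever
  expect_true(all(replicate(50, update_motionless(s, p, g)$v) == cv))
})

test_that("chasing holds inside the deadband and pursues outside it", {
  mk <- function(u, v) stimulus_state("chasing", u = u, v = v, g = g)
  s <- mk(500, 290)
  # d = 16 exactly: no motion (strict deadband)
  s16 <- update_chasing(s, c(500 + 16, 290), p, g)
  expect_equal(c(s16$u, s16$v), c(500, 290))
  # d slightly above 16: moves
  s17 <- update_chasing(s, c(500 + 16.5, 290), p, g)
  expect_gt(s17$u, 500)
  # target on the stimulus: fixed point
  sfix <- update_chasing(s, c(500, 290), p, g)
  expect_equal(c(sfix$u, sfix$v), c(500, 290))
})

test_that("step-simulated pursuit matches the geometric closed form", {
  # stationary target at distance 650: d_k = 650 (1 - dt*1000/650)^k
  alpha <- p$dt * 1000 / p$velocity_divisor
  s <- stimulus_state("chasing", u = 100, v = 290, g = g)
  target <- c(750, 290)
  d <- monitor_head_distance(c(s$u, s$v), target)
  expect_equal(d, 650)
  k <- 0
  first_step <- NULL
  while (d > p$deadband_px) {
    u0 <- s$u
    s <- update_chasing(s, target, p, g)
    if (is.null(first_step)) first_step <- s$u - u0
    k <- k + 1
    d <- monitor_head_distance(c(s$u, s$v), target)
    expect_equal(d, 650 * (1 - alpha)^k, tolerance = 1e-6)
    expect_true(k < 200)
  }
  expect_equal(first_step, 650 * alpha, tolerance = 1e-9)   # 33.33 px
  # monotone approach, never overshoots, halts at/below the deadband
  expect_lte(d, p$deadband_px)
  expect_gt(d, 0)
})

test_that("pursuit distance is non-increasing toward a stationary target", {
  set.seed(7)
  for (rep in 1:20) {
    s <- stimulus_state("chasing", u = runif(1, 0, 1024),
                        v = runif(1, 0, 580), g = g)
    target <- c(runif(1, 0, 1024), runif(1, 0, 580))
    d_prev <- monitor_head_distance(c(s$u, s$v), target)
    for (i in 1:60) {
      s <- update_chasing(s, target, p, g)
      d <- monitor_head_distance(c(s$u, s$v), target)
      expect_lte(d, d_prev + 1e-12)
      if (d_prev > p$deadband_px) expect_lt(d, d_prev)
      d_prev <- d
    }
  }
})

test_that("flipped is exactly u-mirrored chasing", {
  W <- g$monitor_frame[1]
  # mirror fixed line: target at u = W/2 behaves identically
  sc <- stimulus_state("chasing", u = W / 2, v = 100, g = g)
  sf <- stimulus_state("flipped", u = W / 2, v = 100, g = g)
  t0 <- c(W / 2, 400)
  sc <- update_chasing(sc, t0, p, g)
  sf <- update_flipped(sf, t0, p, g)
  expect_equal(c(sf$u, sf$v), c(sc$u, sc$v))
  # equivariance: the flipped trajectory is the u-mirror of the chasing
  # trajectory under the same fish path, frame-exactly (pursuit commutes
  # with mirroring)
  set.seed(11)
  path <- cbind(runif(120, 0, W), runif(120, 0, 580))
  sc <- stimulus_state("chasing", u = 200, v = 300, g = g)
  sf <- stimulus_state("flipped", u = W - 200, v = 300, g = g)
  for (i in seq_len(nrow(path))) {
    sc <- update_chasing(sc, path[i, ], p, g)
    sf <- update_flipped(sf, path[i, ], p, g)
    expect_equal(sf$u, W - sc$u, tolerance = 1e-9)
    expect_equal(sf$v, sc$v, tolerance = 1e-9)
  }
  # mirrored-target deadband inherited
  sf <- stimulus_state("flipped", u = 300, v = 290, g = g)
  sf2 <- update_flipped(sf, c(W - 300 - 16, 290), p, g)
  expect_equal(c(sf2$u, sf2$v), c(300, 290))
})

test_that("fleeing triggers inclusively and relocates to the opposite half", {
  s <- stimulus_state("fleeing", u = 200, v = 290, g = g)
  # |du| = 351: no trigger
  set.seed(3)
  s1 <- update_fleeing(s, c(200 + 351, 290), p, g)
  expect_null(s1$relocation_target)
  expect_equal(c(s1$u, s1$v), c(200, 290))
  # |du| = 350 and |dv| = 150 (both inclusive): trigger, target on right half
  s2 <- update_fleeing(s, c(200 + 350, 290 - 150), p, g)
  expect_false(is.null(s2$relocation_target))
  expect_gte(s2$relocation_target[1], g$monitor_frame[1] / 2)
  # triggers ignored while relocating: target unchanged under a new approach
  tgt <- s2$relocation_target
  s3 <- update_fleeing(s2, c(s2$u, s2$v), p, g)
  expect_equal(s3$relocation_target, tgt)
  # relocation completes and clears under the pursuit law
  s4 <- s2
  for (i in 1:500) {
    s4 <- update_fleeing(s4, c(0, 0), p, g)   # fish far away, no retrigger
    if (is.null(s4$relocation_target)) break
  }
  expect_null(s4$relocation_target)
  expect_equal(c(s4$u, s4$v), tgt, tolerance = p$flee_arrive_tol_px + 1)
})

test_that("fleeing relocation targets are uniform on the opposite half", {
  set.seed(5)
  W <- g$monitor_frame[1]; H <- g$monitor_frame[2]
  n <- 3000
  us <- numeric(n); vs <- numeric(n)
  for (i in seq_len(n)) {
    s <- stimulus_state("fleeing", u = 100, v = 290, g = g)
    s <- update_fleeing(s, c(120, 290), p, g)   # immediate trigger
    us[i] <- s$relocation_target[1]; vs[i] <- s$relocation_target[2]
  }
  expect_true(all(us >= W / 2 & us <= W))
  ks_u <- suppressWarnings(stats::ks.test(us, "punif", W / 2, W))
  ks_v <- suppressWarnings(stats::ks.test(vs, "punif", 0, H))
  expect_gt(ks_u$p.value, 0.01)
  expect_gt(ks_v$p.value, 0.01)
})

test_that("orientation snaps yaw to the target side and clamps pitch", {
  s <- stimulus_state("chasing", u = 500, v = 290, g = g)
  expect_equal(orient_toward(s, c(100, 290), p), c(0, 0))    # target left
  expect_equal(orient_toward(s, c(900, 290), p)[1], 180)     # target right
  # steep elevation clamps at the pitch limit
  expect_equal(orient_toward(s, c(510, 40), p)[2], 30)
  expect_equal(orient_toward(s, c(510, 560), p)[2], -30)
  # tie: orientation unchanged
  s$yaw <- 180; s$pitch <- 12
  expect_equal(orient_toward(s, c(500, 290), p), c(180, 12))
})

test_that("controllers always respect monitor bounds and rotation limits", {
  set.seed(13)
  W <- g$monitor_frame[1]; H <- g$monitor_frame[2]
  s <- stimulus_state("chasing", u = 5, v = 5, g = g)
  for (i in 1:300) {
    tgt <- c(runif(1, -50, W + 50), runif(1, -50, H + 50))
    tgt <- pmin(pmax(tgt, 0), c(W, H))
    s <- update_chasing(s, tgt, p, g)
    expect_true(s$u >= 0 && s$u <= W && s$v >= 0 && s$v <= H)
    expect_true(s$yaw >= 0 && s$yaw <= 180)
    expect_true(s$pitch >= -30 && s$pitch <= 30)
  }
})

test_that("playback tracks round-trip through the independent program", {
  donor <- simulate_session("chasing", "absent", seed = 42, n_frames = 1200)
  tr <- record_playback(donor, "left")
  expect_equal(nrow(tr$frames), 300)   # one full stimulus period
  expect_true(all(tr$frames$u >= 0 & tr$frames$u <= g$monitor_frame[1]))
  expect_true(all(tr$frames$v >= 0 & tr$frames$v <= g$monitor_frame[2]))
  # replay reproduces the logged stimulus positions exactly
  s <- stimulus_state("independent", g = g)
  vis <- which(donor$frames$left_visible)
  for (k in seq_len(50)) {
    s <- update_independent(s, tr, k - 1)
    expect_identical(s$u, donor$frames$left_u[vis[k]])
    expect_identical(s$v, donor$frames$left_v[vis[k]])
  }
  expect_error(update_independent(s, tr, 300), "scheduling")
  # a session shorter than a full period cannot donate a track
  short <- simulate_session("chasing", "absent", seed = 42, n_frames = 1200,
                            visible_frames = c(600L, 800L))
  expect_error(record_playback(short, "left"), "full stimulus period")
  # same track, two sessions: identical stimulus paths; different tracks:
  # different stimulus paths over identical fish trajectories (attraction
  # off, so the fish cannot feed back on the playback)
  a <- simulate_session("independent", "absent", seed = 9, n_frames = 1200,
                        left_track = tr, agent = null_agent())
  b <- simulate_session("independent", "absent", seed = 9, n_frames = 1200,
                        left_track = tr, agent = null_agent())
  expect_identical(a$frames$left_u, b$frames$left_u)
  tr2 <- record_playback(simulate_session("chasing", "absent", seed = 43,
                                          n_frames = 1200), "left")
  c2 <- simulate_session("independent", "absent", seed = 9, n_frames = 1200,
                         left_track = tr2, agent = null_agent())
  expect_false(identical(a$frames$left_u, c2$frames$left_u))
  expect_identical(a$frames$head_x, c2$frames$head_x)  # same fish trajectory
})

test_that("playback tracks persist as CSV with a JSON sidecar", {
  donor <- simulate_session("chasing", "absent", seed = 1, n_frames = 400)
  tr <- record_playback(donor, "left")
  path <- file.path(withr::local_tempdir(), "track.csv")
  write_playback_track(tr, path)
  back <- read_playback_track(path)
  expect_equal(back$frames, tr$frames)
  expect_equal(back$source$seed, 1)
})
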