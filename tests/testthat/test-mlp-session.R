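test_that("session config validates its structure", {
  cfg <- session_config()
  expect_equal(cfg$trials_per_hemifield, 160L)
  expect_equal(cfg$blocks, 5L)
  expect_error(session_config(trials_per_hemifield = 161), "divisible")
  expect_error(session_config(initial_level = 120))
  expect_error(session_config(p_target = 1.2))
})

test_that("stimulus placement follows the current hypothesis and clips to range", {
  cfg <- session_config(initial_level = 100)
  tr <- new_track("left")
  expect_equal(next_level(tr, cfg), 100)          # first trial
  tr30 <- update_track(tr, trial_record(31.3, TRUE, "left"))
  # force a known hypothesis and check the 70% placement
  tr30$mle_index <- which.min(abs(tr30$grid$alphas - 30))
  a <- tr30$grid$alphas[tr30$mle_index]
  expect_equal(next_level(tr30, cfg), a + 1.301175, tolerance = 1e-6)
  tr30$mle_index <- tr30$grid$count                # highest midpoint
  expect_lte(next_level(tr30, cfg), 100)
})

test_that("update_track keeps the selected hypothesis on the grid and rejects cross-talk", {
  tr <- new_track("left")
  expect_error(update_track(tr, trial_record(50, TRUE, "right")),
               "does not match")
  set.seed(5)
  for (i in 1:25) {
    tr <- update_track(tr, trial_record(runif(1, 0, 100),
                                        runif(1) < 0.6, "left",
                                        trial_index = i))
    expect_true(tr$mle_index >= 1L && tr$mle_index <= tr$grid$count)
    # incremental selection identical to full recomputation
    expect_identical(tr$mle_index,
                     attr(select_mle(tr$grid, tr$history), "index"))
  }
})

test_that("an all-correct history pins selection at the lowest midpoint", {
  tr <- new_track("left")
  cfg <- session_config()
  for (i in 1:10) {
    lvl <- next_level(tr, cfg)
    tr <- update_track(tr, trial_record(lvl, TRUE, "left", trial_index = i))
    expect_identical(tr$mle_index, 1L)
  }
})

test_that("sessions are bit-identical under a fixed seed", {
  obs <- sim_observer(psychfun(40))
  f1 <- mlp_session(obs, obs, session_config(seed = 3))
  f2 <- mlp_session(obs, obs, session_config(seed = 3))
  expect_identical(f1$trial_log, f2$trial_log)
  expect_identical(coef(f1), coef(f2))
})

test_that("all presented levels lie in [0, 100] and blocks are balanced", {
  obs <- sim_observer(psychfun(15), lapse = 0.05)
  fit <- mlp_session(obs, obs, session_config(seed = 9))
  log <- fit$trial_log
  expect_true(all(log$level >= 0 & log$level <= 100))
  expect_equal(unname(table(log$hemifield)), c(160L, 160L),
               ignore_attr = TRUE)
  counts <- table(log$hemifield, log$block_index)
  expect_true(all(counts == 32L))
})

test_that("replaying the logged responses reproduces the selection sequence", {
  obs <- sim_observer(psychfun(40))
  fit <- mlp_session(obs, obs, session_config(seed = 12))
  for (hf in c("left", "right")) {
    log_hf <- fit$trial_log[fit$trial_log$hemifield == hf, ]
    log_hf <- log_hf[order(log_hf$trial_index), ]
    seq_alpha <- replay_mle_sequence(fit$grid, log_hf)
    expect_equal(tail(seq_alpha, 1),
                 fit$grid$alphas[fit$tracks[[hf]]$mle_index])
    # the running threshold logged during the session matches the replay
    expect_equal(log_hf$threshold_est,
                 pmin(100, pmax(0, seq_alpha + 1.301175)),
                 tolerance = 1e-6)
  }
})

test_that("hemifield tracks never mix: each threshold is a function of its own track only", {
  obs_l <- sim_observer(psychfun(30))
  obs_r <- sim_observer(psychfun(60))
  fit <- mlp_session(obs_l, obs_r, session_config(seed = 4))
  expect_false(fit$threshold_left == fit$threshold_right)
  # rebuilding each track from its own log alone gives the session result
  for (hf in c("left", "right")) {
    log_hf <- fit$trial_log[fit$trial_log$hemifield == hf, ]
    log_hf <- log_hf[order(log_hf$trial_index), ]
    tr <- new_track(hf, fit$grid)
    for (i in seq_len(nrow(log_hf)))
      tr <- update_track(tr, log_hf[i, , drop = FALSE])
    expect_equal(track_threshold(tr, fit$config),
                 unname(coef(fit)[hf]))
  }
})

test_that("all-blocks and per-block-average read-outs differ on the same observer", {
  obs <- sim_observer(psychfun(45), lapse = 0.1)
  f_all <- mlp_session(obs, obs, session_config(seed = 2))
  f_avg <- mlp_session(obs, obs,
                       session_config(seed = 2,
                                      threshold_mode = "per-block-average"))
  expect_length(f_avg$block_thresholds$left, 5L)
  expect_equal(f_avg$threshold_left, mean(f_avg$block_thresholds$left))
  expect_false(isTRUE(all.equal(f_all$threshold_left,
                                f_avg$threshold_left)))
})

test_that("threshold recovery improves from 20 to 160 trials", {
  set.seed(77)
  errs <- function(n_trials, reps) {
    unlist(lapply(seq_len(reps), function(r) {
      tstar <- runif(1, 20, 80)
      run_recovery_track(tstar, n_trials, seed = r * 1000 + n_trials) - tstar
    }))
  }
  mad20 <- median(abs(errs(20, 25)))
  mad160 <- median(abs(errs(160, 25)))
  expect_lt(mad160, mad20)
  expect_lt(mad160, 2)
})
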