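cfg <- task_config()

# hand-built COD-6 session: 4 visits (3, 2, 4, 1 rewards), ending by time cap
toy_log <- local({
  ev <- rbind(
    data.frame(time_s = c(0, 0, 4, 8, 8),
               event_type = c("patch_entry", "reward", "reward", "reward", "leave"),
               patch_side = "left",
               volume_ul = c(NA, 150, 120, 96, NA)),
    data.frame(time_s = c(14, 14, 18, 18),
               event_type = c("patch_entry", "reward", "reward", "leave"),
               patch_side = "back",
               volume_ul = c(NA, 150, 120, NA)),
    data.frame(time_s = c(24, 24, 28, 32, 36, 36),
               event_type = c("patch_entry", "reward", "reward", "reward",
                              "reward", "leave"),
               patch_side = "left",
               volume_ul = c(NA, 150, 120, 96, 76.8, NA)),
    data.frame(time_s = c(42, 42, 600),
               event_type = c("patch_entry", "reward", "session_end"),
               patch_side = "back",
               volume_ul = c(NA, 150, NA))
  )
  ev$event_index <- seq_len(nrow(ev))
  patchforage:::new_session_log("toy", "male", 1L, 6, ev, "time_cap")
})

test_that("patch visits partition the log with first/last flagged incomplete", {
  v <- extract_patch_visits(toy_log, cfg)
  expect_identical(nrow(v), 4L)
  expect_identical(v$complete, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(v$n_rewards, c(3, 2, 4, 1))
  expect_equal(v$rejection_volume, reward_volume(c(4, 3, 5, 2), cfg))

  # a 5-leave simulated session gives 6 visits, 4 complete
  rat <- det_hyperbolic_rat(k = 0.02, b = 0.62)
  log <- simulate_session(rat, 18, cfg, seed = 2)
  v2 <- extract_patch_visits(log, cfg)
  n_leaves <- sum(log$events$event_type == "leave")
  expect_identical(nrow(v2), as.integer(n_leaves + 1))
  expect_identical(sum(v2$complete), as.integer(n_leaves - 1))
})

test_that("session metrics match hand-computed values on the toy log", {
  m <- session_metrics(toy_log, body_weight = 0.5, cfg)
  expect_equal(m$pc, 2)
  expect_equal(m$tip_s, (4 + 12) / 2)
  expect_equal(m$rejection_ul, (96 + 61.44) / 2)
  # 1228.8 uL over 42 s of earning, per 0.5 kg
  expect_equal(m$wr_ul_min_kg, 1228.8 / (42 / 60) / 0.5)
  # doubling body weight halves only the water rate
  m2 <- session_metrics(toy_log, body_weight = 1.0, cfg)
  expect_equal(m2$wr_ul_min_kg, m$wr_ul_min_kg / 2)
  expect_equal(m2[c("pc", "tip_s", "rejection_ul")],
               m[c("pc", "tip_s", "rejection_ul")])
})

test_that("a session without leaves yields missing metrics, not zeros", {
  rat <- rat_record("c", "male", 0.5,
                    agent_policy("volume_threshold", threshold = 0))
  log <- simulate_session(rat, 6, cfg, seed = 1)
  v <- extract_patch_visits(log, cfg)
  expect_identical(nrow(v), 1L)
  expect_identical(sum(v$complete), 0L)
  m <- session_metrics(log, 0.4, cfg)
  expect_true(is.na(m$pc))
  expect_true(is.na(m$tip_s))
  expect_true(is.na(m$rejection_ul))
})

test_that("percent deviations implement the signed formulas", {
  expect_equal(percent_volume_deviation(96, 96), 0)
  expect_equal(percent_volume_deviation(76.8, 96), 20)
  expect_equal(percent_volume_deviation(120, 96), -25)
  expect_error(percent_volume_deviation(96, 0), "optimal")

  expect_equal(percent_time_deviation(4, 4), 0)
  expect_equal(percent_time_deviation(5, 4), 25)
  expect_equal(percent_time_deviation(2, 4), -50)
  expect_true(is.na(percent_time_deviation(5, 0)))
  # bounds: VD <= 100, TD >= -100 for non-negative observations
  expect_lte(percent_volume_deviation(0, 96), 100)
  expect_gte(percent_time_deviation(0, 4), -100)
})

test_that("aggregation averages the last two cycles and skips weekly first sessions", {
  expect_identical(patchforage:::included_session_indices(cfg),
                   c(14L:18L, 20L:24L))
  rat <- det_hyperbolic_rat(k = 0.02, b = 0.7)
  rat$policy$choice_noise <- 6  # distinct per-session values
  logs <- simulate_protocol(rat, cfg, seed = 4)
  agg <- aggregate_rat(logs, rat, cfg)
  expect_equal(agg$cod_s, cfg$cod_set)
  # manual mean over the two included sessions at each COD
  per <- do.call(rbind, lapply(logs, session_metrics,
                               body_weight = rat$body_weight, config = cfg))
  for (cd in cfg$cod_set) {
    manual <- per[per$session_index %in% c(14:18, 20:24) & per$cod_s == cd, ]
    expect_equal(agg$rejection_ul[agg$cod_s == cd],
                 mean(manual$rejection_ul), label = sprintf("COD %g", cd))
    expect_equal(agg$pc[agg$cod_s == cd], mean(manual$pc))
  }
  expect_true(all(agg$n_sessions == 2))
  # a deterministic rat's two cycles are identical, so the aggregate
  # equals any single included session
  det <- det_hyperbolic_rat(k = 0.02, b = 0.7)
  agg_det <- aggregate_rat(simulate_protocol(det, cfg, seed = 4), det, cfg)
  per_det <- session_metrics(simulate_session(det, 12, cfg, seed = 1),
                             det$body_weight, cfg)
  expect_equal(agg_det$rejection_ul[agg_det$cod_s == 12],
               per_det$rejection_ul)
  expect_error(aggregate_rat(logs[-5], rat, cfg), "missing sessions")
})

test_that("deviation signs agree for deterministic agents", {
  rat <- det_hyperbolic_rat(k = 0.04, b = 0.65)
  agg <- aggregate_rat(simulate_protocol(rat, cfg, seed = 1), rat, cfg)
  ok <- !is.na(agg$vd_pct) & !is.na(agg$td_pct) &
    agg$vd_pct != 0 & agg$td_pct != 0
  expect_true(any(ok))
  expect_equal(sign(agg$vd_pct[ok]), sign(agg$td_pct[ok]))
})

test_that("harvest classification labels deviations and tabulates cohorts", {
  mvt <- rat_record("m", "male", 0.4, agent_policy("mvt_optimal"))
  agg <- aggregate_rat(simulate_protocol(mvt, cfg, seed = 1), mvt, cfg)
  cl <- harvest_classification(agg)
  lab <- cl$labels[cl$labels$cod_s > 0, "harvest"]
  expect_true(all(lab == "optimal"))

  # one over- and one under-harvester split 50/50
  over <- det_hyperbolic_rat("o", "male", k = 0.2, b = 0.5)
  under <- rat_record("u", "male", 0.4,
                      agent_policy("volume_threshold", threshold = 130))
  mm <- rbind(aggregate_rat(simulate_protocol(over, cfg, seed = 1), over, cfg),
              aggregate_rat(simulate_protocol(under, cfg, seed = 1), under, cfg))
  fr <- harvest_classification(mm)$frequencies
  at6 <- fr[fr$cod_s == 6, ]
  expect_equal(at6$pct_over, 50)
  expect_equal(at6$pct_under, 50)

  # threshold cohort percentages follow the closed-form oracle prediction
  ths <- c(45, 60, 85, 110)
  rats <- lapply(seq_along(ths), function(i)
    rat_record(paste0("t", i), "female", 0.3,
               agent_policy("volume_threshold", threshold = ths[i])))
  mt <- do.call(rbind, lapply(rats, function(r)
    aggregate_rat(simulate_protocol(r, cfg, seed = 1), r, cfg)))
  fr2 <- harvest_classification(mt)$frequencies
  opt12 <- solve_optimal_policy(12, cfg)$optimal_rejection_volume
  pred_over <- 100 * mean(sapply(ths, oracle_rejection) < opt12)
  expect_equal(fr2$pct_over[fr2$cod_s == 12], pred_over)
})
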