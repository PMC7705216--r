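test_that("the dynamic-range pre-phase recovers a scripted listener's range", {
  # audible from 20 dB, Too Loud above 90 dB; 10-dB steps from 60
  dr <- estimate_dynamic_range(scripted_responder(20, 90))
  expect_equal(dr$lower, 20)
  expect_equal(dr$upper, 90)
  # never Too Loud -> ascending runs to the 110 dB cap
  dr2 <- estimate_dynamic_range(scripted_responder(20, 200))
  expect_equal(dr2$upper, 110)
  # audible everywhere -> descending runs to the floor
  dr3 <- estimate_dynamic_range(scripted_responder(-10, 90))
  expect_equal(dr3$lower, 0)
  # inaudible start recovers via the ascending sequence
  dr4 <- estimate_dynamic_range(scripted_responder(75, 120))
  expect_equal(dr4$lower, 80)
  # nothing audible anywhere is degenerate
  expect_error(estimate_dynamic_range(function(level) 0L), "degenerate")
})

test_that("fixed-level sessions present each grid level ten times", {
  resp <- scripted_responder(5, 115)
  log <- run_fixed_level(resp, dynamic_range(50, 60), seed = 1)
  expect_equal(nrow(log$trials), 30L)
  expect_equal(sort(unique(log$trials$level)), c(50, 55, 60))
  expect_true(all(table(log$trials$level) == 10))
  # full-range listener: 22 levels, 220 trials
  log2 <- run_fixed_level(resp, dynamic_range(5, 110), seed = 2)
  expect_equal(length(unique(log2$trials$level)), 22L)
  expect_equal(nrow(log2$trials), 220L)
})

test_that("fixed-level orders satisfy both sequencing constraints", {
  resp <- scripted_responder(5, 115)
  dr <- dynamic_range(5, 110)
  for (seed in 1:25) {
    lv <- run_fixed_level(resp, dr, seed = seed)$trials$level
    d <- diff(lv)
    expect_true(all(abs(d) <= 45))
    expect_true(all(d != 0))
  }
  # determinism
  expect_identical(run_fixed_level(resp, dr, seed = 5)$trials,
                   run_fixed_level(resp, dr, seed = 5)$trials)
})

test_that("slope-adaptive runs evenly span the limits and move the upper limit", {
  # never Too Loud: upper limit escalates by 5 each run, capped at 110
  log <- run_slope_adaptive(scripted_responder(10, 200), dynamic_range(10, 90),
                            seed = 3)
  expect_equal(nrow(log$trials), 45L)
  expect_equal(log$run_limits$upper, c(90, 95, 100, 105, 110))
  r1 <- sort(log$trials$level[log$trials$run == 1])
  expect_equal(r1, seq(10, 90, by = 10))
  expect_true(all(log$trials$level <= 110))
  # always Too Loud at the top level: upper limit steps down
  log2 <- run_slope_adaptive(scripted_responder(10, 85), dynamic_range(10, 90),
                             seed = 4)
  expect_equal(log2$run_limits$upper[1:2], c(90, 85))
  expect_true(all(diff(log2$run_limits$upper) %in% c(-5, 5)))
  # levels never exceed their own run's limit
  for (run in 1:5) {
    expect_true(all(log2$trials$level[log2$trials$run == run] <=
                      log2$run_limits$upper[run] + 1e-9))
  }
})

test_that("the upper limit never exceeds 110 dB SPL under escalation", {
  log <- run_slope_adaptive(scripted_responder(5, 200), dynamic_range(5, 105),
                            seed = 5)
  expect_equal(max(log$run_limits$upper), 110)
  expect_lte(max(log$trials$level), 110)
  log2 <- run_urd(scripted_responder(5, 200), dynamic_range(5, 105), seed = 6)
  expect_lte(max(log2$run_limits$upper), 110)
  expect_lte(max(log2$trials$level), 110)
})

test_that("MEI-adaptive sessions run 45 trials with a persistent posterior", {
  cat <- small_catalog(n = 10, seed = 7)
  listener <- simulated_listener(cat$entries[[4]], seed = 9, mode = "modal")
  dr <- estimate_dynamic_range(listener)
  log <- run_mei_adaptive(listener, cat, dr, seed = 10)
  expect_equal(nrow(log$trials), 45L)
  expect_s3_class(log$posterior, "cls_posterior")
  expect_equal(log$posterior$n_trials_absorbed, 45L)
  # entropy recorded each trial and broadly decreasing for a modal listener
  expect_true(all(is.finite(log$trials$entropy_after)))
  expect_lt(log$trials$entropy_after[45], log2(10))
  # first level is the grid midpoint of the dynamic range
  expect_equal(log$trials$level[1],
               clsmei:::snap_to_grid((dr$lower + dr$upper) / 2))
  # consecutive levels obey the transition and repeat rules
  d <- diff(log$trials$level)
  expect_true(all(abs(d) <= 45 + 1e-9))
  expect_true(all(abs(d) > 1e-9))
})

test_that("MEI trajectory replays against the brute-force oracle", {
  cat <- clsmei:::new_catalog(list(uniform_mcpf(10, 90, 4, id = "a"),
                                   uniform_mcpf(30, 105, 6, id = "b")), 1000)
  listener <- simulated_listener(cat$entries[[2]], seed = 1, mode = "modal")
  dr <- dynamic_range(20, 100)
  log <- run_mei_adaptive(listener, cat, dr, seed = 2, n_runs = 2L)
  # replay: from trial 2 on, each level must equal the oracle's choice
  st <- init_posterior(cat)
  lower <- dr$lower; upper <- dr$upper
  t <- 0L
  for (run in 1:2) {
    resp <- integer(9)
    for (j in 1:9) {
      t <- t + 1L
      if (t > 1L) {
        cons <- selection_constraints(lower_limit = lower, upper_limit = upper,
                                      previous_level = log$trials$level[t - 1])
        expect_equal(log$trials$level[t],
                     brute_force_mei(st$probs, cat, cons)$level)
      }
      resp[j] <- log$trials$response_cu[t]
      st <- update_posterior(st, cat, log$trials$level[t], resp[j])
    }
    upper <- clsmei:::next_upper_limit(resp, lower, upper)
  }
})

test_that("URD levels stay on the in-limit grid and are seed-reproducible", {
  resp <- scripted_responder(10, 100)
  dr <- dynamic_range(10, 90)
  log <- run_urd(resp, dr, seed = 11)
  expect_equal(nrow(log$trials), 45L)
  for (run in 1:5) {
    lv <- log$trials$level[log$trials$run == run]
    expect_true(all(lv >= log$run_limits$lower[run]))
    expect_true(all(lv <= log$run_limits$upper[run]))
    expect_true(all(lv %% 5 == 0))
  }
  expect_identical(run_urd(resp, dr, seed = 11)$trials, log$trials)
  expect_false(identical(run_urd(resp, dr, seed = 12)$trials$level,
                         log$trials$level))
})

test_that("URD draws are uniform over the grid", {
  # pool first-run levels (fixed limits) across many seeded sessions
  resp <- scripted_responder(10, 200)
  dr <- dynamic_range(10, 90)
  lv <- unlist(lapply(1:120, function(s) {
    log <- run_urd(resp, dr, seed = s, n_runs = 1L)
    log$trials$level
  }))
  grid <- seq(10, 90, by = 5)
  tab <- table(factor(lv, levels = grid))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("session logs round-trip through CSV", {
  cat <- small_catalog(n = 5, seed = 13)
  listener <- simulated_listener(cat$entries[[2]], seed = 3)
  dr <- estimate_dynamic_range(listener)
  log <- run_mei_adaptive(listener, cat, dr, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$trials$level, log$trials$level)
  expect_equal(back$trials$response_cu, log$trials$response_cu)
  expect_equal(back$trials$entropy_after, log$trials$entropy_after,
               tolerance = 1e-12)
  expect_equal(back$procedure, "mei")
  expect_equal(back$dynamic_range$lower, dr$lower)
})
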